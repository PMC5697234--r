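#' Default figure configuration
#'
#' All graphical parameters driving the synteny figure. Colors are R color
#' names (the full `grDevices` vocabulary, so "azure4" or "darkgoldenrod1"
#' resolve) or #RRGGBB hex. Up to three gene-category highlight colors are
#' allowed.
#'
#' @param width,height Page size in plot units (inches at 72 dpi). `height`
#'   of NA means "2 + 1.5 per genome", computed at render time.
#' @param ribbon_color Fill for syntenic ribbons (default "azure4").
#' @param ribbon_alpha Ribbon opacity in [0, 1] (default 0.6).
#' @param gene_box_color Default gene rectangle color (default "black").
#' @param category_colors Up to three highlight colors for gene categories
#'   1-3.
#' @param scaffold_highlight Named character vector scaffold -> color;
#'   ribbons touching that scaffold take the color.
#' @param show_gene_boxes,show_scaffold_labels,show_genome_labels Visibility
#'   flags.
#' @param label_cex,genome_label_cex Font expansion for scaffold and genome
#'   labels.
#' @param scaffold_gap Horizontal gap between placed scaffolds, plot units.
#' @param genome_order Optional track order (permutation of the repository
#'   genomes); empty means Repo_spec order.
#' @param scaffold_overrides Named list (per genome) of data.frames
#'   `seq_id`, `orientation` fixing scaffold order/orientation verbatim.
#' @return list of class `figure_config`.
#' @export
default_figure_config <- function(width = 11, height = NA_real_,
                                  ribbon_color = "azure4",
                                  ribbon_alpha = 0.6,
                                  gene_box_color = "black",
                                  category_colors = c("cornflowerblue",
                                                      "coral3", "darkcyan"),
                                  scaffold_highlight = character(0),
                                  show_gene_boxes = TRUE,
                                  show_scaffold_labels = TRUE,
                                  show_genome_labels = TRUE,
                                  label_cex = 0.5, genome_label_cex = 0.8,
                                  scaffold_gap = 0.05,
                                  genome_order = character(0),
                                  scaffold_overrides = list()) {
  if (length(category_colors) > 3L)
    sv_abort("up to three gene-category colors are allowed (got %d)",
             length(category_colors))
  cfg <- list(width = width, height = height, ribbon_color = ribbon_color,
              ribbon_alpha = ribbon_alpha, gene_box_color = gene_box_color,
              category_colors = category_colors,
              scaffold_highlight = scaffold_highlight,
              show_gene_boxes = show_gene_boxes,
              show_scaffold_labels = show_scaffold_labels,
              show_genome_labels = show_genome_labels,
              label_cex = label_cex, genome_label_cex = genome_label_cex,
              scaffold_gap = scaffold_gap, genome_order = genome_order,
              scaffold_overrides = scaffold_overrides)
  class(cfg) <- "figure_config"
  validate_config_colors(cfg)
  cfg
}

#' Resolve a color name or hex string to RGB
#'
#' @param x Color name (R vocabulary) or #RRGGBB string.
#' @return Integer vector c(r, g, b) in 0-255.
#' @export
resolve_color <- function(x) {
  rgb <- tryCatch(grDevices::col2rgb(x), error = function(e) NULL)
  if (is.null(rgb)) sv_abort("unresolvable color: '%s'", x)
  as.integer(rgb[, 1])
}

validate_config_colors <- function(cfg) {
  for (col in c(cfg$ribbon_color, cfg$gene_box_color, cfg$category_colors,
                unname(cfg$scaffold_highlight)))
    resolve_color(col)
  invisible(cfg)
}

#' Generate the editable config file text
#'
#' Emits every graphical parameter with its current value plus the computed
#' scaffold order/orientation per genome, in a commented key-value format
#' with sections `[global]` and `[genome:<id>]`. Output is byte-
#' deterministic for a fixed plan and config, and
#' `generate -> parse -> generate` is a fixed point.
#'
#' @param plan A `layout_plan`.
#' @param config A `figure_config` (defaults used when omitted).
#' @return Character vector of config lines.
#' @export
generate_config <- function(plan, config = default_figure_config()) {
  cfg <- config
  num <- function(x) if (is.na(x)) "auto" else sv_num(x)
  lines <- c(
    "# synteny figure configuration",
    "# edit values and re-run the render stage; '#' lines are comments",
    "[global]",
    paste0("width = ", num(cfg$width)),
    paste0("height = ", num(cfg$height)),
    paste0("ribbon_color = ", cfg$ribbon_color),
    paste0("ribbon_alpha = ", sv_num(cfg$ribbon_alpha)),
    paste0("gene_box_color = ", cfg$gene_box_color),
    paste0("category_colors = ", paste(cfg$category_colors, collapse = ",")),
    paste0("scaffold_highlight = ",
           if (length(cfg$scaffold_highlight) == 0L) "" else
             paste(paste0(names(cfg$scaffold_highlight), ":",
                          cfg$scaffold_highlight), collapse = ",")),
    paste0("show_gene_boxes = ", tolower(cfg$show_gene_boxes)),
    paste0("show_scaffold_labels = ", tolower(cfg$show_scaffold_labels)),
    paste0("show_genome_labels = ", tolower(cfg$show_genome_labels)),
    paste0("label_cex = ", sv_num(cfg$label_cex)),
    paste0("genome_label_cex = ", sv_num(cfg$genome_label_cex)),
    paste0("scaffold_gap = ", sv_num(cfg$scaffold_gap)),
    paste0("genome_order = ", paste(plan$genomes, collapse = ",")))
  for (g in plan$genomes) {
    p <- plan$placements[[g]]
    lines <- c(lines, paste0("[genome:", g, "]"),
               paste0("order = ", paste(paste0(p$seq_id, ":", p$orientation),
                                        collapse = ",")))
  }
  lines
}

#' Write a config file
#'
#' @param plan A `layout_plan`.
#' @param path Output path.
#' @param config A `figure_config`.
#' @export
write_config <- function(plan, path, config = default_figure_config()) {
  writeLines(generate_config(plan, config), path)
  invisible(path)
}

#' Parse a (possibly hand-edited) config file
#'
#' Unknown keys produce a warning and are ignored; missing keys fall back
#' to defaults. Orientation values outside {+,-} and more than three
#' category colors are hard errors. When `db` is supplied, scaffold names
#' in order lines are validated against the repository.
#'
#' @param path Path to a config file, or a character vector of its lines
#'   via `lines`.
#' @param db Optional `repo_db` for scaffold-name validation.
#' @param lines Config text as a character vector (alternative to `path`).
#' @return A `figure_config` with `genome_order` and `scaffold_overrides`
#'   populated from the file.
#' @export
parse_config <- function(path = NULL, db = NULL, lines = NULL) {
  if (is.null(lines)) lines <- sv_read_lines(path)
  cfg <- default_figure_config()
  cfg$category_colors <- character(0)  # file contents replace defaults only if present
  seen_cat <- FALSE
  section <- "global"
  known <- c("width", "height", "ribbon_color", "ribbon_alpha",
             "gene_box_color", "category_colors", "scaffold_highlight",
             "show_gene_boxes", "show_scaffold_labels", "show_genome_labels",
             "label_cex", "genome_label_cex", "scaffold_gap", "genome_order")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    sec <- regmatches(ln, regexec("^\\[(.+)\\]$", ln))[[1]]
    if (length(sec) == 2L) { section <- sec[2]; next }
    kv <- regmatches(ln, regexec("^(\\w+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L)
      sv_abort("config line %d: expected 'key = value'", i)
    key <- kv[2]; val <- trimws(kv[3])
    if (startsWith(section, "genome:")) {
      g <- sub("^genome:", "", section)
      if (key != "order") { sv_warn("config line %d: unknown key '%s' in [%s]; ignored", i, key, section); next }
      items <- strsplit(val, ",", fixed = TRUE)[[1]]
      m <- regmatches(items, regexec("^\\s*(\\S+):([+-])\\s*$", items))
      bad <- which(lengths(m) != 3L)
      if (length(bad) > 0L)
        sv_abort("config line %d: orientation must be '+' or '-' in '%s'",
                 i, items[bad[1]])
      ov <- data.frame(seq_id = vapply(m, `[`, "", 2),
                       orientation = vapply(m, `[`, "", 3),
                       stringsAsFactors = FALSE)
      if (!is.null(db)) {
        sc <- db$scaffold_lengths$seq_id[db$scaffold_lengths$genome_id == g]
        unknown <- setdiff(ov$seq_id, sc)
        if (length(unknown) > 0L)
          sv_abort("config line %d: scaffold '%s' not in repository genome %s",
                   i, unknown[1], g)
      }
      cfg$scaffold_overrides[[g]] <- ov
      next
    }
    if (!(key %in% known)) {
      sv_warn("config line %d: unknown key '%s'; ignored", i, key)
      next
    }
    cfg[[key]] <- switch(
      key,
      width = , ribbon_alpha = , label_cex = , genome_label_cex = ,
      scaffold_gap = as.numeric(val),
      height = if (identical(val, "auto")) NA_real_ else as.numeric(val),
      show_gene_boxes = , show_scaffold_labels = ,
      show_genome_labels = identical(val, "true"),
      category_colors = {
        seen_cat <- TRUE
        cc <- if (nzchar(val)) trimws(strsplit(val, ",", fixed = TRUE)[[1]]) else character(0)
        if (length(cc) > 3L)
          sv_abort("config line %d: up to three gene-category colors are allowed (got %d)",
                   i, length(cc))
        cc
      },
      scaffold_highlight = {
        if (!nzchar(val)) character(0) else {
          items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
          mm <- regmatches(items, regexec("^(\\S+):(\\S+)$", items))
          bad <- which(lengths(mm) != 3L)
          if (length(bad) > 0L)
            sv_abort("config line %d: scaffold_highlight entries must be scaffold:color", i)
          stats::setNames(vapply(mm, `[`, "", 3), vapply(mm, `[`, "", 2))
        }
      },
      genome_order = if (nzchar(val)) trimws(strsplit(val, ",", fixed = TRUE)[[1]]) else character(0),
      val)
  }
  if (!seen_cat)
    cfg$category_colors <- c("cornflowerblue", "coral3", "darkcyan")
  if (!is.null(db) && length(cfg$genome_order) > 0L) {
    unknown <- setdiff(cfg$genome_order, db$spec$genome_id)
    if (length(unknown) > 0L)
      sv_abort("config genome_order names unknown genome: %s", unknown[1])
  }
  validate_config_colors(cfg)
  cfg
}

#' Rebuild a layout plan from a config's recorded order/orientation
#'
#' @param config A `figure_config` whose `scaffold_overrides` cover every
#'   genome (e.g. from [parse_config()] on a generated file).
#' @param db A `repo_db`.
#' @return A `layout_plan` honoring the config verbatim.
#' @export
plan_from_config <- function(config, db) {
  auto_layout(db, empty_spans(), config = config)
}
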