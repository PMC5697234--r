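#' Compute drawable geometry for the synteny figure
#'
#' Maps every track, placed scaffold, gene and span endpoint into plot
#' coordinates. The bp -> plot mapping is affine per scaffold (see
#' [bp_to_plot()]); on "-" scaffolds plotted positions are the mirror image
#' of bp positions. Ribbons are computed only between vertically adjacent
#' genome tracks.
#'
#' @param plan A `layout_plan`.
#' @param db A `repo_db`.
#' @param spans Span records.
#' @param config A `figure_config`.
#' @return list of class `track_geometry` with data.frames `tracks`,
#'   `scaffolds`, `genes`, `ribbons`, plus `width`, `height`.
#' @export
compute_geometry <- function(plan, db, spans = empty_spans(),
                             config = default_figure_config()) {
  n <- length(plan$genomes)
  height <- if (is.na(config$height)) 2 + 1.5 * n else config$height
  width <- config$width
  track_y <- stats::setNames(height - 1 - 1.5 * (seq_len(n) - 1), plan$genomes)

  scaffolds <- do.call(rbind, lapply(plan$genomes, function(g) {
    p <- plan$placements[[g]]
    data.frame(genome_id = g, seq_id = p$seq_id, orientation = p$orientation,
               x0 = p$offset, x1 = p$offset + p$length_bp / plan$scale,
               y = track_y[[g]], stringsAsFactors = FALSE)
  }))

  feats <- db$features
  genes <- NULL
  if (nrow(feats) > 0L) {
    key_sc <- paste(scaffolds$genome_id, scaffolds$seq_id)
    i <- match(paste(feats$genome_id, feats$seq_id), key_sc)
    if (anyNA(i))
      sv_abort("feature %s lies on unplaced scaffold %s",
               feats$gene_id[which(is.na(i))[1]], feats$seq_id[which(is.na(i))[1]])
    sc_len_key <- paste(db$scaffold_lengths$genome_id, db$scaffold_lengths$seq_id)
    sc_len <- db$scaffold_lengths$length_bp[match(paste(feats$genome_id, feats$seq_id), sc_len_key)]
    if (any(feats$end > sc_len | feats$start < 1))
      sv_abort("gene %s outside scaffold bounds",
               feats$gene_id[which(feats$end > sc_len | feats$start < 1)[1]])
    pl <- plan_row(plan, feats$genome_id, feats$seq_id)
    xs <- ifelse(pl$orientation == "+",
                 pl$offset + (feats$start - 1) / plan$scale,
                 pl$offset + (pl$length_bp - feats$start) / plan$scale)
    xe <- ifelse(pl$orientation == "+",
                 pl$offset + (feats$end - 1) / plan$scale,
                 pl$offset + (pl$length_bp - feats$end) / plan$scale)
    genes <- data.frame(genome_id = feats$genome_id, seq_id = feats$seq_id,
                        gene_id = feats$gene_id,
                        x0 = pmin(xs, xe), x1 = pmax(xs, xe),
                        y = track_y[feats$genome_id],
                        category = feats$category, stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(genome_id = character(0), seq_id = character(0),
                        gene_id = character(0), x0 = numeric(0),
                        x1 = numeric(0), y = numeric(0),
                        category = integer(0), stringsAsFactors = FALSE)
  }

  ribbons <- list()
  for (i in seq_len(n - 1L)) {
    top <- plan$genomes[i]; bottom <- plan$genomes[i + 1L]
    sp <- spans_between(spans, top, bottom)
    if (nrow(sp) == 0L) next
    pt <- plan$placements[[top]]; pb <- plan$placements[[bottom]]
    it <- match(sp$seq_a, pt$seq_id); ib <- match(sp$seq_b, pb$seq_id)
    if (anyNA(it) || anyNA(ib))
      sv_abort("span references unplaced scaffold")
    map <- function(p, idx, bp) ifelse(p$orientation[idx] == "+",
                                       p$offset[idx] + (bp - 1) / plan$scale,
                                       p$offset[idx] + (p$length_bp[idx] - bp) / plan$scale)
    tx0 <- map(pt, it, sp$span_a_start); tx1 <- map(pt, it, sp$span_a_end)
    bx0 <- map(pb, ib, sp$span_b_start); bx1 <- map(pb, ib, sp$span_b_end)
    ribbons[[length(ribbons) + 1L]] <- data.frame(
      chain_id = sp$chain_id, genome_top = top, seq_top = sp$seq_a,
      genome_bottom = bottom, seq_bottom = sp$seq_b,
      tx0 = pmin(tx0, tx1), tx1 = pmax(tx0, tx1), ty = track_y[[top]],
      bx0 = pmin(bx0, bx1), bx1 = pmax(bx0, bx1), by = track_y[[bottom]],
      stringsAsFactors = FALSE)
  }
  ribbons <- if (length(ribbons) > 0L) do.call(rbind, ribbons) else
    data.frame(chain_id = integer(0), genome_top = character(0),
               seq_top = character(0), genome_bottom = character(0),
               seq_bottom = character(0), tx0 = numeric(0), tx1 = numeric(0),
               ty = numeric(0), bx0 = numeric(0), bx1 = numeric(0),
               by = numeric(0), stringsAsFactors = FALSE)
  tracks <- data.frame(genome_id = plan$genomes,
                       x0 = vapply(plan$genomes, function(g) min(plan$placements[[g]]$offset), 0),
                       x1 = vapply(plan$genomes, function(g) {
                         p <- plan$placements[[g]]
                         max(p$offset + p$length_bp / plan$scale)
                       }, 0),
                       y = unname(track_y), stringsAsFactors = FALSE)
  structure(list(tracks = tracks, scaffolds = scaffolds, genes = genes,
                 ribbons = ribbons, width = width, height = height),
            class = "track_geometry")
}

plan_row <- function(plan, genome_id, seq_id) {
  all <- do.call(rbind, lapply(names(plan$placements), function(g)
    cbind(genome_id = g, plan$placements[[g]], stringsAsFactors = FALSE)))
  i <- match(paste(genome_id, seq_id), paste(all$genome_id, all$seq_id))
  all[i, , drop = FALSE]
}

#' Render the synteny overview figure to PDF
#'
#' Draws, per genome, a horizontal track line with vertical ticks at
#' scaffold borders, scaffold identifiers above each scaffold suffixed with
#' their +/- orientation, the isolate name to the right of the track, a
#' small rectangle above the line for every gene (black, or the category
#' color for categories 1-3; colored genes are drawn after black ones), and
#' one filled quadrilateral ribbon per span between adjacent tracks
#' (default fill "azure4", overridden by scaffold highlight colors for
#' ribbons touching a highlighted scaffold). The PDF is written
#' uncompressed so its drawing operators can be inventoried.
#'
#' @param geometry A `track_geometry` from [compute_geometry()].
#' @param config A `figure_config`.
#' @param out_path Output PDF path.
#' @return `out_path`, invisibly.
#' @export
render_figure <- function(geometry, config = default_figure_config(),
                          out_path = "synteny.pdf") {
  validate_config_colors(config)
  cat_cols <- config$category_colors
  ribbon_fill <- function(seq_top, seq_bottom) {
    hl <- config$scaffold_highlight
    col <- rep(config$ribbon_color, length(seq_top))
    if (length(hl) > 0L) {
      hit_b <- seq_bottom %in% names(hl)
      col[hit_b] <- hl[seq_bottom[hit_b]]
      hit_t <- seq_top %in% names(hl)
      col[hit_t] <- hl[seq_top[hit_t]]
    }
    col
  }

  grDevices::pdf(out_path, width = geometry$width, height = geometry$height,
                 compress = FALSE, useDingbats = FALSE,
                 title = "synteny overview")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.1, geometry$width),
                        ylim = c(0, geometry$height))

  rb <- geometry$ribbons
  if (nrow(rb) > 0L) {
    fill <- grDevices::adjustcolor(ribbon_fill(rb$seq_top, rb$seq_bottom),
                                   alpha.f = config$ribbon_alpha)
    for (i in seq_len(nrow(rb)))
      graphics::polygon(c(rb$tx0[i], rb$tx1[i], rb$bx1[i], rb$bx0[i]),
                        c(rb$ty[i], rb$ty[i], rb$by[i], rb$by[i]),
                        col = fill[i], border = NA)
  }

  tr <- geometry$tracks
  graphics::segments(tr$x0, tr$y, tr$x1, tr$y, lwd = 1.2)

  sc <- geometry$scaffolds
  tick <- 0.06
  graphics::segments(c(sc$x0, sc$x1), c(sc$y - tick, sc$y - tick),
                     c(sc$x0, sc$x1), c(sc$y + tick, sc$y + tick), lwd = 0.8)

  gn <- geometry$genes
  if (config$show_gene_boxes && nrow(gn) > 0L) {
    box_h <- 0.08
    black <- is.na(gn$category) | gn$category < 1 | gn$category > length(cat_cols)
    if (any(black))
      graphics::rect(gn$x0[black], gn$y[black] + 0.02,
                     pmax(gn$x1[black], gn$x0[black] + 0.004),
                     gn$y[black] + 0.02 + box_h,
                     col = config$gene_box_color, border = NA)
    if (any(!black)) {
      g2 <- gn[!black, , drop = FALSE]
      graphics::rect(g2$x0, g2$y + 0.02, pmax(g2$x1, g2$x0 + 0.004),
                     g2$y + 0.02 + box_h,
                     col = cat_cols[g2$category], border = NA)
    }
  }

  if (config$show_scaffold_labels) {
    labels <- paste0(abbreviate_scaffolds(sc$seq_id), sc$orientation)
    graphics::text((sc$x0 + sc$x1) / 2, sc$y + 0.28, labels,
                   cex = config$label_cex)
  }
  if (config$show_genome_labels)
    graphics::text(tr$x1 + 0.15, tr$y, tr$genome_id, adj = c(0, 0.5),
                   cex = config$genome_label_cex)
  invisible(out_path)
}

#' Abbreviate scaffold identifiers for labels
#'
#' Long shared prefixes are compressed (e.g. "supercontig_5" -> "sc5",
#' "scaffold_12" -> "sc12"); short names pass through.
#'
#' @param ids Character vector of scaffold names.
#' @return Abbreviated labels.
#' @export
abbreviate_scaffolds <- function(ids) {
  out <- sub("^supercontig[_.]?", "sc", ids)
  out <- sub("^scaffold[_.]?", "sc", out)
  out <- sub("^contig[_.]?", "ctg", out)
  out
}

#' Inventory drawing operators of an uncompressed PDF
#'
#' Parses the content streams of a PDF written with `compress = FALSE` and
#' counts the primitive drawing operations: filled rectangles (`re` + `f`),
#' filled polygons (paths closed with `h f`), stroked segments
#' (`m ... l S`) and text runs (`Tj`).
#'
#' @param path Path to the PDF.
#' @return list with `n_rect`, `n_polygon`, `n_segment`, `n_text`, and
#'   `valid` (TRUE when the file starts with a PDF header and contains an
#'   EOF marker).
#' @export
pdf_inventory <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(raw[raw != as.raw(0)])
  lines <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  valid <- startsWith(lines[1], "%PDF") &&
    any(grepl("%%EOF", lines, fixed = TRUE, useBytes = TRUE))
  n_rect <- sum(grepl(" re$", lines, useBytes = TRUE))
  n_polygon <- sum(grepl("^h f\\*?$", lines, useBytes = TRUE))
  n_segment <- sum(grepl(" m .* l  ?S$", lines, useBytes = TRUE))
  n_text <- sum(grepl(" Tj$", lines, useBytes = TRUE))
  list(n_rect = n_rect, n_polygon = n_polygon, n_segment = n_segment,
       n_text = n_text, valid = valid)
}
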