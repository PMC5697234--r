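#' Plot coordinate of a base-pair position on a placed scaffold
#'
#' The bp -> plot mapping is affine per scaffold: `offset + (bp - 1)/scale`
#' for "+" placements and `offset + (length - bp)/scale` for "-" (mirror).
#'
#' @param placement One-row data.frame (`seq_id`, `orientation`, `offset`,
#'   `length_bp`).
#' @param bp 1-based base-pair position(s).
#' @param scale bp per plot unit.
#' @return Numeric plot coordinate(s).
#' @export
bp_to_plot <- function(placement, bp, scale) {
  if (placement$orientation == "+") placement$offset + (bp - 1) / scale
  else placement$offset + (placement$length_bp - bp) / scale
}

# Midpoint plot coordinate of a bp interval on a named scaffold of one
# placed track. placements: data.frame(seq_id, orientation, offset, length_bp)
track_midpoint <- function(placements, seq_id, start, end, scale) {
  i <- match(seq_id, placements$seq_id)
  if (anyNA(i))
    sv_abort("span references unplaced scaffold: %s", seq_id[which(is.na(i))[1]])
  mid <- (start + end) / 2
  ifelse(placements$orientation[i] == "+",
         placements$offset[i] + (mid - 1) / scale,
         placements$offset[i] + (placements$length_bp[i] - mid) / scale)
}

#' Count ribbon crossings between two adjacent tracks
#'
#' Each span is projected to its midpoint plot coordinate on both tracks;
#' the crossing count is the number of span pairs whose order on the top
#' track disagrees with their order on the bottom track (a strict inversion
#' count, computed by merge sort).
#'
#' @param placed_top,placed_bottom data.frames (`seq_id`, `orientation`,
#'   `offset`, `length_bp`) for the two tracks.
#' @param spans Span records whose A side lies on the top track and B side
#'   on the bottom track.
#' @param scale bp per plot unit (default 1; any positive value gives the
#'   same count).
#' @return Integer crossing count.
#' @export
count_crossings <- function(placed_top, placed_bottom, spans, scale = 1) {
  if (nrow(spans) == 0L) return(0L)
  xt <- track_midpoint(placed_top, spans$seq_a, spans$span_a_start,
                       spans$span_a_end, scale)
  xb <- track_midpoint(placed_bottom, spans$seq_b, spans$span_b_start,
                       spans$span_b_end, scale)
  o <- order(xt, xb)
  count_inversions(xb[o])
}

# strict inversion count (pairs i<j with x[i] > x[j]) via merge sort
count_inversions <- function(x) {
  n <- length(x)
  if (n < 2L) return(0L)
  rec <- function(v) {
    n <- length(v)
    if (n < 2L) return(list(v = v, inv = 0))
    h <- n %/% 2L
    L <- rec(v[seq_len(h)]); R <- rec(v[(h + 1L):n])
    merged <- numeric(n); inv <- L$inv + R$inv
    i <- j <- 1L
    for (k in seq_len(n)) {
      if (i <= length(L$v) && (j > length(R$v) || L$v[i] <= R$v[j])) {
        merged[k] <- L$v[i]; i <- i + 1L
      } else {
        merged[k] <- R$v[j]; j <- j + 1L
        inv <- inv + (length(L$v) - i + 1L)
      }
    }
    list(v = merged, inv = inv)
  }
  as.integer(rec(x)$inv)
}

# weighted median: smallest value at which cumulative weight reaches half
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' Automatic scaffold ordering and orientation
#'
#' Genome (track) order is the Repo_spec order unless overridden. The top
#' genome's scaffolds are placed by descending length, all "+". Each
#' subsequent genome is laid out against the already-placed track above it
#' by the barycenter heuristic: a scaffold's sort key is the
#' span-length-weighted median of its partner spans' midpoints on the upper
#' track. A scaffold is flipped to "-" when its spans' anchor pairs are
#' more often discordant than concordant with the upper track (each span
#' votes with weight `n_pairs`; a reverse-orientation span against a "+"
#' upper scaffold is discordant, and votes flip when the upper scaffold is
#' itself placed "-"). Ties resolve to "+". Scaffolds without spans are
#' appended after anchored ones by descending length. Config-specified
#' order/orientation overrides are applied last, verbatim.
#'
#' @param db A `repo_db`.
#' @param spans Span records for each vertically adjacent genome pair (any
#'   orientation of the pair; other rows are ignored).
#' @param config Optional `figure_config` carrying overrides.
#' @return Object of class `layout_plan`: list with `genomes`, `placements`
#'   (named list of data.frames `seq_id`, `orientation`, `offset`,
#'   `length_bp`), `scale`, `scaffold_gap`.
#' @export
auto_layout <- function(db, spans = empty_spans(), config = NULL) {
  layout_engine(db, spans, config)
}

layout_engine <- function(db, spans = empty_spans(), config = NULL) {
  cfg <- config %||% default_figure_config()
  genomes <- db$spec$genome_id
  if (length(cfg$genome_order) > 0L) {
    if (!setequal(cfg$genome_order, genomes))
      sv_abort("config genome order is not a permutation of the repository genomes")
    genomes <- cfg$genome_order
  }
  scl <- db$scaffold_lengths
  scaffold_gap <- cfg$scaffold_gap
  content_width <- cfg$width - 1.5  # room for isolate labels at the right

  # scale: bp per plot unit so the widest genome (incl. gaps) fits
  per_genome_bp <- tapply(scl$length_bp, scl$genome_id, sum)
  per_genome_n <- tapply(scl$length_bp, scl$genome_id, length)
  avail <- content_width - (per_genome_n - 1) * scaffold_gap
  scale <- max(per_genome_bp / pmax(avail, 1e-6))

  placements <- list()
  for (gi in seq_along(genomes)) {
    g <- genomes[gi]
    sc <- scl[scl$genome_id == g, , drop = FALSE]
    if (gi == 1L) {
      ord <- sc$seq_id[order(-sc$length_bp, sc$seq_id)]
      orient <- stats::setNames(rep("+", nrow(sc)), ord)
    } else {
      upper <- placements[[genomes[gi - 1L]]]
      sp <- spans_between(spans, genomes[gi - 1L], g)
      if (nrow(sp) == 0L) {
        if (nrow(spans) > 0L)
          sv_warn("genome %s has no spans to its upper neighbour %s; using descending-length order",
                  g, genomes[gi - 1L])
        ord <- sc$seq_id[order(-sc$length_bp, sc$seq_id)]
        orient <- stats::setNames(rep("+", nrow(sc)), ord)
      } else {
        up_mid <- track_midpoint(upper, sp$seq_a, sp$span_a_start,
                                 sp$span_a_end, scale)
        sp_len <- abs(sp$span_a_end - sp$span_a_start) + 1
        up_orient <- upper$orientation[match(sp$seq_a, upper$seq_id)]
        key <- rep(NA_real_, nrow(sc)); names(key) <- sc$seq_id
        orient <- stats::setNames(rep("+", nrow(sc)), sc$seq_id)
        for (s in sc$seq_id) {
          rows <- which(sp$seq_b == s)
          if (length(rows) == 0L) next
          key[s] <- weighted_median(up_mid[rows], sp_len[rows])
          concord <- ifelse(sp$orientation[rows] == "forward", 1L, -1L) *
            ifelse(up_orient[rows] == "+", 1L, -1L)
          votes <- sum(sp$n_pairs[rows] * concord)
          if (votes < 0) orient[s] <- "-"
        }
        anchored <- names(key)[!is.na(key)]
        anchored <- anchored[order(key[anchored], anchored)]
        rest <- setdiff(sc$seq_id, anchored)
        rest <- rest[order(-sc$length_bp[match(rest, sc$seq_id)], rest)]
        ord <- c(anchored, rest)
        orient <- orient[ord]
      }
    }
    # config overrides, applied verbatim
    ov <- cfg$scaffold_overrides[[g]]
    if (!is.null(ov)) {
      if (!setequal(ov$seq_id, sc$seq_id))
        sv_abort("config scaffold order for genome %s does not cover its scaffolds", g)
      ord <- ov$seq_id
      orient <- stats::setNames(ov$orientation, ov$seq_id)
    }
    len <- sc$length_bp[match(ord, sc$seq_id)]
    offset <- cumsum(c(0, head(len, -1) / scale + scaffold_gap))
    placements[[g]] <- data.frame(seq_id = ord, orientation = unname(orient[ord]),
                                  offset = offset, length_bp = len,
                                  stringsAsFactors = FALSE)
  }
  structure(list(genomes = genomes, placements = placements, scale = scale,
                 scaffold_gap = scaffold_gap), class = "layout_plan")
}

# Subset spans to one genome pair, normalized so the A side is `top`.
spans_between <- function(spans, top, bottom) {
  if (nrow(spans) == 0L) return(empty_spans())
  fwd <- spans[spans$genome_a == top & spans$genome_b == bottom, , drop = FALSE]
  rev <- spans[spans$genome_a == bottom & spans$genome_b == top, , drop = FALSE]
  if (nrow(rev) > 0L) {
    rev <- data.frame(chain_id = rev$chain_id, genome_a = rev$genome_b,
                      seq_a = rev$seq_b, span_a_start = rev$span_b_start,
                      span_a_end = rev$span_b_end, genome_b = rev$genome_a,
                      seq_b = rev$seq_a, span_b_start = rev$span_a_start,
                      span_b_end = rev$span_a_end, n_pairs = rev$n_pairs,
                      orientation = rev$orientation, stringsAsFactors = FALSE)
  }
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  out
}

#' Descending-length default layout (no crossing minimization)
#'
#' The baseline [auto_layout()] is compared against: every genome's
#' scaffolds by descending length, all "+".
#'
#' @param db A `repo_db`.
#' @param config Optional `figure_config` (for width/gap/scale handling).
#' @return A `layout_plan`.
#' @export
default_layout <- function(db, config = NULL) {
  layout_engine(db, empty_spans(), config = strip_overrides(config))
}

strip_overrides <- function(config) {
  if (is.null(config)) return(NULL)
  config$scaffold_overrides <- list()
  config
}

#' Total adjacent-track crossings of a layout plan
#'
#' @param plan A `layout_plan`.
#' @param spans Span records.
#' @return Integer: sum of crossing counts over all adjacent track pairs.
#' @export
plan_crossings <- function(plan, spans) {
  total <- 0L
  for (i in seq_len(length(plan$genomes) - 1L)) {
    top <- plan$genomes[i]; bottom <- plan$genomes[i + 1L]
    sp <- spans_between(spans, top, bottom)
    if (nrow(sp) == 0L) next
    total <- total + count_crossings(plan$placements[[top]],
                                     plan$placements[[bottom]], sp, plan$scale)
  }
  total
}

#' @export
print.layout_plan <- function(x, ...) {
  cat(sprintf("<layout_plan: %d genomes, scale %.4g bp/unit>\n",
              length(x$genomes), x$scale))
  for (g in x$genomes) {
    p <- x$placements[[g]]
    cat(sprintf("  %s: %s\n", g,
                paste(paste0(p$seq_id, ":", p$orientation), collapse = ",")))
  }
  invisible(x)
}
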