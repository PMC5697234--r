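#' Construct a syntenic chain object
#'
#' A chain is a scored collinear run of ortholog pairs between one scaffold
#' of genome A and one scaffold of genome B. `pairs` rows are ordered by
#' position along the A scaffold; on a reverse-orientation chain the B genes
#' run in descending order.
#'
#' @param chain_id Integer id (assigned globally by [partition_and_chain()]).
#' @param genome_a,genome_b Genome tokens.
#' @param seq_a,seq_b Scaffold tokens.
#' @param orientation `"forward"` or `"reverse"`.
#' @param pairs data.frame with columns `gene_a`, `start_a`, `end_a`,
#'   `gene_b`, `start_b`, `end_b`, `pair_score`.
#' @param total_score Chain DP score.
#' @return Object of class `synteny_chain`.
#' @export
synteny_chain <- function(chain_id, genome_a, genome_b, seq_a, seq_b, orientation,
                  pairs, total_score) {
  stopifnot(orientation %in% c("forward", "reverse"),
            is.data.frame(pairs),
            all(c("gene_a", "start_a", "end_a", "gene_b", "start_b", "end_b",
                  "pair_score") %in% names(pairs)))
  structure(list(chain_id = as.integer(chain_id), genome_a = genome_a,
                 genome_b = genome_b, seq_a = seq_a, seq_b = seq_b,
                 orientation = orientation, pairs = pairs,
                 total_score = as.numeric(total_score)),
            class = "synteny_chain")
}

#' @export
print.synteny_chain <- function(x, ...) {
  cat(sprintf("<synteny_chain #%d %s:%s vs %s:%s, %s, %d pairs, score %.4g>\n",
              x$chain_id, x$genome_a, x$seq_a, x$genome_b, x$seq_b,
              x$orientation, nrow(x$pairs), x$total_score))
  invisible(x)
}

#' Write chains in aligncoords format
#'
#' Per chain a header line
#' \code{## alignment <genome_a>:<seq_a> vs <genome_b>:<seq_b> Alignment
#' #<chain_id> score = <total_score> (<orientation>)} followed by one
#' tab-separated line per pair: seq_a, gene_a, start_a, end_a, seq_b,
#' gene_b, start_b, end_b, pair_score.
#'
#' @param chains List of `synteny_chain` objects.
#' @param path Output path.
#' @export
write_aligncoords <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("## alignment %s:%s vs %s:%s Alignment #%d score = %s (%s)",
                       ch$genome_a, ch$seq_a, ch$genome_b, ch$seq_b,
                       ch$chain_id, sv_num(ch$total_score), ch$orientation), con)
    p <- ch$pairs
    writeLines(paste(ch$seq_a, p$gene_a, p$start_a, p$end_a,
                     ch$seq_b, p$gene_b, p$start_b, p$end_b,
                     sv_num(p$pair_score), sep = "\t"), con)
  }
  invisible(path)
}

#' Read an aligncoords file
#'
#' Exact inverse of [write_aligncoords()]. Blank lines and trailing
#' whitespace are tolerated.
#'
#' @param path Path to an aligncoords file.
#' @return List of `synteny_chain` objects.
#' @export
read_aligncoords <- function(path) {
  lines <- sv_read_lines(path)
  chains <- list()
  hdr <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(hdr)) return()
    p <- do.call(rbind, rows)
    pairs <- data.frame(gene_a = p[, 2], start_a = as.integer(p[, 3]),
                        end_a = as.integer(p[, 4]), gene_b = p[, 6],
                        start_b = as.integer(p[, 7]), end_b = as.integer(p[, 8]),
                        pair_score = as.numeric(p[, 9]),
                        stringsAsFactors = FALSE)
    chains[[length(chains) + 1L]] <<- synteny_chain(
      hdr$chain_id, hdr$genome_a, hdr$genome_b, hdr$seq_a, hdr$seq_b,
      hdr$orientation, pairs, hdr$total_score)
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "## alignment ")) {
      flush()
      m <- regmatches(ln, regexec(
        "^## alignment (\\S+):(\\S+) vs (\\S+):(\\S+) Alignment #(\\d+) score = (\\S+) \\((forward|reverse)\\)$",
        ln))[[1]]
      if (length(m) != 8L)
        sv_abort("aligncoords %s line %d: malformed chain header", path, i)
      hdr <- list(genome_a = m[2], seq_a = m[3], genome_b = m[4], seq_b = m[5],
                  chain_id = as.integer(m[6]), total_score = as.numeric(m[7]),
                  orientation = m[8])
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      sv_abort("aligncoords %s line %d: expected 9 tab-separated columns, got %d",
               path, i, length(f))
    if (is.null(hdr))
      sv_abort("aligncoords %s line %d: pair line before any chain header", path, i)
    rows[[length(rows) + 1L]] <- f
  }
  flush()
  chains
}

#' Aggregate chains into span records
#'
#' One row per chain; span bounds are the min start / max end over member
#' gene coordinates on each genome.
#'
#' @param chains List of `synteny_chain` objects.
#' @return data.frame with columns `chain_id`, `genome_a`, `seq_a`,
#'   `span_a_start`, `span_a_end`, `genome_b`, `seq_b`, `span_b_start`,
#'   `span_b_end`, `n_pairs`, `orientation`.
#' @export
chains_to_spans <- function(chains) {
  if (length(chains) == 0L) return(empty_spans())
  do.call(rbind, lapply(chains, function(ch) {
    data.frame(chain_id = ch$chain_id, genome_a = ch$genome_a, seq_a = ch$seq_a,
               span_a_start = min(ch$pairs$start_a), span_a_end = max(ch$pairs$end_a),
               genome_b = ch$genome_b, seq_b = ch$seq_b,
               span_b_start = min(ch$pairs$start_b), span_b_end = max(ch$pairs$end_b),
               n_pairs = nrow(ch$pairs), orientation = ch$orientation,
               stringsAsFactors = FALSE)
  }))
}

empty_spans <- function() {
  data.frame(chain_id = integer(0), genome_a = character(0), seq_a = character(0),
             span_a_start = integer(0), span_a_end = integer(0),
             genome_b = character(0), seq_b = character(0),
             span_b_start = integer(0), span_b_end = integer(0),
             n_pairs = integer(0), orientation = character(0),
             stringsAsFactors = FALSE)
}

#' Write span records (aligncoords.spans format)
#'
#' One tab-separated line per span: chain_id, genome_a, seq_a, span_a_start,
#' span_a_end, genome_b, seq_b, span_b_start, span_b_end, n_pairs,
#' orientation.
#'
#' @param spans data.frame as returned by [chains_to_spans()].
#' @param path Output path.
#' @export
write_spans <- function(spans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(spans) > 0L)
    writeLines(paste(spans$chain_id, spans$genome_a, spans$seq_a,
                     spans$span_a_start, spans$span_a_end, spans$genome_b,
                     spans$seq_b, spans$span_b_start, spans$span_b_end,
                     spans$n_pairs, spans$orientation, sep = "\t"), con)
  invisible(path)
}

#' Read a spans file
#'
#' @param path Path to an aligncoords.spans file.
#' @return data.frame in the layout of [chains_to_spans()].
#' @export
read_spans <- function(path) {
  lines <- sv_read_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) return(empty_spans())
  parts <- strsplit(sub("\\s+$", "", lines[keep]), "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 11L)
  if (length(bad) > 0L)
    sv_abort("spans %s line %d: expected 11 tab-separated columns, got %d",
             path, keep[bad[1]], lengths(parts)[bad[1]])
  m <- matrix(unlist(parts), ncol = 11L, byrow = TRUE)
  data.frame(chain_id = as.integer(m[, 1]), genome_a = m[, 2], seq_a = m[, 3],
             span_a_start = as.integer(m[, 4]), span_a_end = as.integer(m[, 5]),
             genome_b = m[, 6], seq_b = m[, 7],
             span_b_start = as.integer(m[, 8]), span_b_end = as.integer(m[, 9]),
             n_pairs = as.integer(m[, 10]), orientation = m[, 11],
             stringsAsFactors = FALSE)
}
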