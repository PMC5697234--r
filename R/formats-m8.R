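m8_cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
             "mismatches", "gap_openings", "q_start", "q_end", "s_start",
             "s_end", "evalue", "bitscore")

#' Read a 12-column tabular similarity file (BLAST "m8"/outfmt 6)
#'
#' @param path Path to an m8 file.
#' @return data.frame with the 12 standard columns (`query_id`, `subject_id`,
#'   `percent_identity`, `aln_length`, `mismatches`, `gap_openings`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`).
#' @export
read_m8 <- function(path) {
  lines <- sv_read_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) return(empty_m8())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad) > 0L)
    sv_abort("m8 line %d of %s: expected 12 tab-separated columns, got %d",
             keep[bad[1]], path, lengths(parts)[bad[1]])
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_openings = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (anyNA(out$evalue) || any(out$evalue < 0))
    sv_abort("m8 %s: invalid e-value on line %d", path,
             keep[which(is.na(out$evalue) | out$evalue < 0)[1]])
  out
}

empty_m8 <- function() {
  out <- data.frame(query_id = character(0), subject_id = character(0),
                    percent_identity = numeric(0), aln_length = integer(0),
                    mismatches = integer(0), gap_openings = integer(0),
                    q_start = integer(0), q_end = integer(0),
                    s_start = integer(0), s_end = integer(0),
                    evalue = numeric(0), bitscore = numeric(0),
                    stringsAsFactors = FALSE)
  out
}

#' Write hit records in m8 format
#'
#' @param records data.frame as returned by [read_m8()].
#' @param path Output path.
#' @export
write_m8 <- function(records, path) {
  stopifnot(all(m8_cols %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records) > 0L) {
    lines <- paste(records$query_id, records$subject_id,
                   sv_num(records$percent_identity), records$aln_length,
                   records$mismatches, records$gap_openings,
                   records$q_start, records$q_end, records$s_start,
                   records$s_end, format_evalue(records$evalue),
                   sv_num(records$bitscore), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

format_evalue <- function(e) {
  vapply(e, function(v) {
    if (v == 0) "0" else format(v, scientific = TRUE, digits = 10)
  }, character(1))
}
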