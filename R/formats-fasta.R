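#' Read a FASTA file into a sequence record table
#'
#' Records are returned as a data.frame with one row per sequence. The record
#' id is the header token up to the first whitespace; the remainder of the
#' header line is kept as the description. Wrapped residue lines are
#' concatenated.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  lines <- sv_read_lines(path)
  body <- lines[nzchar(trimws(lines))]
  if (length(body) == 0L) sv_abort("empty FASTA file: %s", path)
  if (!startsWith(trimws(body[1]), ">"))
    sv_abort("not a FASTA file (first non-blank character is not '>'): %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) sv_abort("empty FASTA file: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    sv_abort("duplicate FASTA id(s) in %s: %s", path, paste(unique(dup), collapse = ", "))
  res <- as.character(set)
  if (any(nchar(res) == 0L))
    sv_abort("zero-length sequence for id %s in %s", ids[which(nchar(res) == 0L)[1]], path)
  data.frame(id = ids, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @param width Residue line wrap width (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
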