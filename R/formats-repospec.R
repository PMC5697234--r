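#' Read a repository specification file
#'
#' The Repo_spec lists, per genome, the four files the pipeline needs:
#' genome FASTA, cds FASTA, pep FASTA and GFF3 annotation. The dialect is a
#' flat key-value block per genome, blocks introduced by a line starting
#' with \code{//}:
#'
#' \preformatted{
#' //
#' id = genomeA
#' genome = genomeA.genome.fasta
#' cds = genomeA.cds.fasta
#' pep = genomeA.pep.fasta
#' gff = genomeA.gff3
#' }
#'
#' Relative paths are resolved against the Repo_spec's own directory. File
#' order defines the default top-to-bottom track order of the figure.
#'
#' @param path Path to the Repo_spec file.
#' @param check_files Verify all referenced files exist (default TRUE).
#' @return data.frame of class `repo_spec` with columns `genome_id`,
#'   `genome_fasta`, `cds_fasta`, `pep_fasta`, `gff`.
#' @export
read_repo_spec <- function(path, check_files = TRUE) {
  lines <- sv_read_lines(path)
  dir <- dirname(normalizePath(path, mustWork = TRUE))
  entries <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    need <- c("id", "genome", "cds", "pep", "gff")
    miss <- setdiff(need, names(cur))
    if (length(miss) > 0L)
      sv_abort("Repo_spec %s: entry '%s' missing key(s): %s", path,
               cur[["id"]] %||% "?", paste(miss, collapse = ", "))
    cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "//")) {
      e <- flush(cur); if (!is.null(e)) entries[[length(entries) + 1L]] <- e
      cur <- list()
      next
    }
    if (is.null(cur))
      sv_abort("Repo_spec %s line %d: key-value line before first '//' separator", path, i)
    kv <- regmatches(ln, regexec("^(\\w+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(kv) != 3L)
      sv_abort("Repo_spec %s line %d: expected 'key = value'", path, i)
    cur[[kv[2]]] <- trimws(kv[3])
  }
  e <- flush(cur); if (!is.null(e)) entries[[length(entries) + 1L]] <- e
  if (length(entries) == 0L) sv_abort("Repo_spec %s: no entries", path)

  resolve <- function(p) ifelse(grepl("^(/|~)", p), p, file.path(dir, p))
  spec <- data.frame(
    genome_id = vapply(entries, `[[`, "", "id"),
    genome_fasta = resolve(vapply(entries, `[[`, "", "genome")),
    cds_fasta = resolve(vapply(entries, `[[`, "", "cds")),
    pep_fasta = resolve(vapply(entries, `[[`, "", "pep")),
    gff = resolve(vapply(entries, `[[`, "", "gff")),
    stringsAsFactors = FALSE)
  dup <- spec$genome_id[duplicated(spec$genome_id)]
  if (length(dup) > 0L)
    sv_abort("Repo_spec %s: duplicate genome id(s): %s", path,
             paste(unique(dup), collapse = ", "))
  if (check_files) {
    paths <- c(spec$genome_fasta, spec$cds_fasta, spec$pep_fasta, spec$gff)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L)
      sv_abort("Repo_spec %s: missing file(s):\n  %s", path,
               paste(missing, collapse = "\n  "))
  }
  class(spec) <- c("repo_spec", "data.frame")
  spec
}

#' Write a repository specification file
#'
#' @param spec A `repo_spec` data.frame (see [read_repo_spec()]).
#' @param path Output path; file paths are written relative to its directory
#'   when possible.
#' @export
write_repo_spec <- function(spec, path) {
  dir <- normalizePath(dirname(path), mustWork = FALSE)
  rel <- function(p) {
    ap <- normalizePath(p, mustWork = FALSE)
    pre <- paste0(dir, "/")
    ifelse(startsWith(ap, pre), substring(ap, nchar(pre) + 1L), ap)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(spec))) {
    writeLines(c("//",
                 paste0("id = ", spec$genome_id[i]),
                 paste0("genome = ", rel(spec$genome_fasta[i])),
                 paste0("cds = ", rel(spec$cds_fasta[i])),
                 paste0("pep = ", rel(spec$pep_fasta[i])),
                 paste0("gff = ", rel(spec$gff[i]))), con)
  }
  invisible(path)
}
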