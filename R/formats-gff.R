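#' Read gene features from a GFF3 annotation
#'
#' Extracts one feature per gene locus. Rows of type \code{gene} are used
#' directly; \code{mRNA} and \code{CDS} rows are resolved to their parent
#' gene through the ID/Parent attribute chain, so the emitted \code{gene_id}
#' matches the parent ID shared with the pep/cds FASTA. Only the ID and
#' Parent attributes are interpreted; everything else is ignored. Comment
#' and directive lines are skipped. Coordinates are 1-based inclusive and
#' kept that way throughout the package.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Token identifying the genome the annotation belongs to.
#' @return data.frame with columns `genome_id`, `seq_id`, `gene_id`,
#'   `start`, `end`, `strand`, `category` (NA unless set later).
#' @export
read_gff3 <- function(path, genome_id) {
  lines <- sv_read_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (length(keep) == 0L)
    return(empty_features(genome_id))

  n <- length(keep)
  seqid <- type <- id <- parent <- strand <- character(n)
  start <- end <- integer(n)
  for (k in seq_len(n)) {
    ln <- keep[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      sv_abort("GFF3 line %d of %s: expected 9 tab-separated columns, got %d",
               ln, path, length(f))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      sv_abort("GFF3 line %d of %s: non-numeric coordinates", ln, path)
    if (e < s)
      sv_abort("GFF3 line %d of %s: end (%d) < start (%d)", ln, path, e, s)
    seqid[k] <- f[1]; type[k] <- f[3]; start[k] <- s; end[k] <- e; strand[k] <- f[7]
    id[k] <- gff_attr(f[9], "ID")
    parent[k] <- gff_attr(f[9], "Parent")
  }

  is_gene <- type == "gene"
  parent_of <- parent; names(parent_of) <- id
  type_of <- type; names(type_of) <- id

  # every CDS must resolve to a gene row through its Parent chain
  for (k in which(type == "CDS")) {
    p <- if (nzchar(parent[k])) parent[k] else id[k]
    seen <- character(0)
    repeat {
      if (!nzchar(p) || !(p %in% names(type_of)) || p %in% seen)
        sv_abort("GFF3 line %d of %s: CDS Parent chain resolves to no gene",
                 keep[k], path)
      if (type_of[[p]] == "gene") break
      seen <- c(seen, p)
      p <- parent_of[[p]]
    }
  }

  g <- which(is_gene)
  gid <- id[g]
  if (any(!nzchar(gid)))
    sv_abort("GFF3 %s: gene row without an ID attribute (line %d)",
             path, keep[g[which(!nzchar(gid))[1]]])
  dup <- gid[duplicated(gid)]
  if (length(dup) > 0L)
    sv_abort("GFF3 %s: duplicate gene id(s): %s", path,
             paste(unique(dup), collapse = ", "))
  if (any(!strand[g] %in% c("+", "-")))
    sv_abort("GFF3 %s: gene strand must be '+' or '-' (line %d)",
             path, keep[g[which(!strand[g] %in% c("+", "-"))[1]]])
  data.frame(genome_id = genome_id, seq_id = seqid[g], gene_id = gid,
             start = start[g], end = end[g], strand = strand[g],
             category = NA_integer_, stringsAsFactors = FALSE)
}

empty_features <- function(genome_id = character(0)) {
  data.frame(genome_id = character(0), seq_id = character(0),
             gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), category = integer(0),
             stringsAsFactors = FALSE)
}

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))[[1]]
  if (length(m) == 2L) trimws(m[2]) else ""
}

#' Write gene features as a minimal GFF3 file
#'
#' Emits, per gene, a \code{gene} row, one \code{mRNA} row (ID
#' \code{<gene>.t1}) and one \code{CDS} row, reproducing the layout the
#' simulator and tests rely on.
#'
#' @param features data.frame as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    t1 <- paste0(f$gene_id, ".t1")
    writeLines(c(
      paste(f$seq_id, "synviz", "gene", f$start, f$end, ".", f$strand, ".",
            paste0("ID=", f$gene_id), sep = "\t"),
      paste(f$seq_id, "synviz", "mRNA", f$start, f$end, ".", f$strand, ".",
            paste0("ID=", t1, ";Parent=", f$gene_id), sep = "\t"),
      paste(f$seq_id, "synviz", "CDS", f$start, f$end, ".", f$strand, "0",
            paste0("ID=", t1, ".cds;Parent=", t1), sep = "\t")), con)
  }
  invisible(path)
}
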