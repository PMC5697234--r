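#' Validate a repository's four-file set per genome
#'
#' Checks, per genome: (a) every pep FASTA id resolves to a GFF gene
#' feature and every gene is covered by at least one peptide, (b) same for
#' cds, (c) every feature's scaffold exists in the genome FASTA, (d) every
#' feature ends within its scaffold, (e) no duplicate gene ids.
#' Transcript-style ids (`<gene>.t<N>`) in the pep/cds
#' FASTA are matched to their gene by stripping the final `.t<N>` suffix.
#'
#' No condition raises an error: every problem becomes a report row and an
#' empty report means the repository is valid.
#'
#' @param spec A `repo_spec` (see [read_repo_spec()]).
#' @return data.frame with columns `genome_id`, `check`, `status`,
#'   `detail`; one row per failure.
#' @export
validate_repository <- function(spec) {
  fails <- list()
  add <- function(genome, check, detail)
    fails[[length(fails) + 1L]] <<- data.frame(
      genome_id = genome, check = check, status = "fail", detail = detail,
      stringsAsFactors = FALSE)

  for (i in seq_len(nrow(spec))) {
    g <- spec$genome_id[i]
    feats <- tryCatch(read_gff3(spec$gff[i], g), error = function(e) e)
    if (inherits(feats, "error")) {
      add(g, "gff_parse", conditionMessage(feats)); next
    }
    genome <- read_fasta(spec$genome_fasta[i])
    pep <- read_fasta(spec$pep_fasta[i])
    cds <- read_fasta(spec$cds_fasta[i])

    gene_ids <- feats$gene_id
    dup <- gene_ids[duplicated(gene_ids)]
    for (d in unique(dup)) add(g, "duplicate_gene_id", d)

    for (which_f in c("pep", "cds")) {
      ids <- if (which_f == "pep") pep$id else cds$id
      resolved <- strip_transcript_suffix(ids)
      miss <- ids[!(resolved %in% gene_ids)]
      for (m in miss) add(g, paste0(which_f, "_id_in_gff"), m)
      uncovered <- gene_ids[!(gene_ids %in% resolved)]
      for (m in uncovered) add(g, paste0("gene_has_", which_f), m)
    }

    sc_len <- nchar(genome$residues)
    names(sc_len) <- genome$id
    unknown <- unique(feats$seq_id[!(feats$seq_id %in% genome$id)])
    for (u in unknown) add(g, "seq_id_in_genome", u)
    known <- feats$seq_id %in% genome$id
    over <- which(known & feats$end > sc_len[feats$seq_id])
    for (o in over)
      add(g, "feature_within_scaffold",
          sprintf("%s end %d > scaffold %s length %d", feats$gene_id[o],
                  feats$end[o], feats$seq_id[o], sc_len[[feats$seq_id[o]]]))
  }
  if (length(fails) == 0L)
    return(data.frame(genome_id = character(0), check = character(0),
                      status = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, fails)
}

strip_transcript_suffix <- function(ids) sub("\\.t\\d+$", "", ids)

#' Build the repository sequence database
#'
#' Loads every genome's features and scaffold lengths and computes the
#' per-genome summary the downstream stages consume. The repository must
#' first pass [validate_repository()] with zero failures.
#'
#' When a gene has multiple transcripts, the longest peptide is retained as
#' the gene's representative for all similarity work.
#'
#' @param spec A `repo_spec`.
#' @param validate Run [validate_repository()] first (default TRUE).
#' @return Object of class `repo_db`: list with `spec`, `features` (all
#'   genomes), `scaffold_lengths`, `summary`, `gene_genome` (named vector
#'   gene_id -> genome_id).
#' @export
build_repository_db <- function(spec, validate = TRUE) {
  if (validate) {
    rep <- validate_repository(spec)
    if (nrow(rep) > 0L)
      sv_abort("repository is invalid; first failure: genome %s, check %s, %s",
               rep$genome_id[1], rep$check[1], rep$detail[1])
  }
  feats <- list(); scl <- list(); summ <- list()
  for (i in seq_len(nrow(spec))) {
    g <- spec$genome_id[i]
    f <- read_gff3(spec$gff[i], g)
    genome <- read_fasta(spec$genome_fasta[i])
    feats[[i]] <- f
    scl[[i]] <- data.frame(genome_id = g, seq_id = genome$id,
                           length_bp = nchar(genome$residues),
                           stringsAsFactors = FALSE)
    summ[[i]] <- data.frame(genome_id = g, n_scaffolds = nrow(genome),
                            n_genes = nrow(f),
                            total_bp = sum(nchar(genome$residues)),
                            stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  gene_genome <- features$genome_id
  names(gene_genome) <- features$gene_id
  # gene ids colliding across genomes make bare m8 ids ambiguous; tolerated
  # here (summaries are still well defined) but similarity ops will refuse them
  ambiguous <- unique(features$gene_id[duplicated(features$gene_id)])
  structure(list(spec = spec, features = features,
                 scaffold_lengths = do.call(rbind, scl),
                 summary = do.call(rbind, summ),
                 gene_genome = gene_genome,
                 ambiguous_gene_ids = ambiguous),
            class = "repo_db")
}

#' @export
print.repo_db <- function(x, ...) {
  cat(sprintf("<repo_db: %d genomes, %d genes, %d scaffolds>\n",
              nrow(x$spec), nrow(x$features), nrow(x$scaffold_lengths)))
  print(x$summary)
  invisible(x)
}

#' Write the repository summary (.db_summary file)
#'
#' Tab-separated: genome_id, n_scaffolds, n_genes, total_bp.
#'
#' @param db A `repo_db`.
#' @param path Output path.
#' @export
write_db_summary <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("genome_id", "n_scaffolds", "n_genes", "total_bp", sep = "\t"), con)
  writeLines(paste(db$summary$genome_id, db$summary$n_scaffolds,
                   db$summary$n_genes, db$summary$total_bp, sep = "\t"), con)
  invisible(path)
}

#' Representative peptides, one per gene
#'
#' Reads every pep FASTA and keeps, per gene (after transcript-suffix
#' stripping), the single longest peptide.
#'
#' @param db A `repo_db`.
#' @return data.frame with columns `genome_id`, `gene_id`, `pep_id`,
#'   `residues`.
#' @export
representative_peptides <- function(db) {
  out <- list()
  for (i in seq_len(nrow(db$spec))) {
    pep <- read_fasta(db$spec$pep_fasta[i])
    pep$gene_id <- strip_transcript_suffix(pep$id)
    pep <- pep[order(pep$gene_id, -nchar(pep$residues), pep$id), ]
    pep <- pep[!duplicated(pep$gene_id), ]
    out[[i]] <- data.frame(genome_id = db$spec$genome_id[i],
                           gene_id = pep$gene_id, pep_id = pep$id,
                           residues = pep$residues, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
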