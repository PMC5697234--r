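#' Simulation parameters
#'
#' The generator's stated world: a set of related annotated genomes derived
#' from a common ancestor by inversions, translocations, gene loss and
#' duplication, plus all-vs-all hit tables consistent with the known truth.
#' Inversion/translocation/duplication rates are expected event counts per
#' lineage (Poisson-sampled); `gene_loss` is a per-gene loss probability.
#'
#' @param n_genomes Number of genomes, 2-12 (default 4).
#' @param n_scaffolds Scaffolds per genome (default 3).
#' @param n_genes Genes in the ancestor (default 300).
#' @param inversions Expected inversions per lineage (default 2).
#' @param translocations Expected translocations per lineage (default 1).
#' @param gene_loss Per-gene loss probability (default 0.05).
#' @param gene_duplication Expected tandem duplications per lineage
#'   (default 0).
#' @param spurious_hit_rate Spurious cross-family hits per true hit
#'   (default 0).
#' @param missing_hit_rate Probability a true similarity match is dropped
#'   (both reciprocal records together; default 0).
#' @param bitscore_sd Gaussian noise on emitted bitscores (default 0).
#' @param whole_scaffold_prob Probability an inversion flips a whole
#'   scaffold rather than an internal block (default 0.25).
#' @param seed Integer master seed (default 1).
#' @return list of class `sim_params`.
#' @export
simulation_params <- function(n_genomes = 4L, n_scaffolds = 3L,
                              n_genes = 300L, inversions = 2,
                              translocations = 1, gene_loss = 0.05,
                              gene_duplication = 0,
                              spurious_hit_rate = 0, missing_hit_rate = 0,
                              bitscore_sd = 0, whole_scaffold_prob = 0.25,
                              seed = 1L) {
  stopifnot(n_genomes >= 2L, n_genomes <= 12L, n_scaffolds >= 1L,
            n_genes >= n_scaffolds, inversions >= 0, translocations >= 0,
            gene_loss >= 0, gene_loss <= 1, gene_duplication >= 0,
            spurious_hit_rate >= 0, missing_hit_rate >= 0,
            missing_hit_rate <= 1, bitscore_sd >= 0)
  structure(list(n_genomes = as.integer(n_genomes),
                 n_scaffolds = as.integer(n_scaffolds),
                 n_genes = as.integer(n_genes), inversions = inversions,
                 translocations = translocations, gene_loss = gene_loss,
                 gene_duplication = gene_duplication,
                 spurious_hit_rate = spurious_hit_rate,
                 missing_hit_rate = missing_hit_rate,
                 bitscore_sd = bitscore_sd,
                 whole_scaffold_prob = whole_scaffold_prob,
                 seed = as.integer(seed)), class = "sim_params")
}

rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate a repository of related annotated genomes
#'
#' Builds an ancestor of `n_genes` genes laid uniformly over `n_scaffolds`
#' scaffolds with random intergenic gaps, then derives each genome by
#' applying gene loss, tandem duplications, inversions (gene block
#' reversed, strands flipped) and translocations (block moved between
#' scaffolds). Genome, cds and pep FASTA plus GFF3 are written per genome,
#' with a Repo_spec and a truth ledger (`truth.tsv`, `truth_events.tsv`).
#' Descendants of one ancestral gene share that family's cds/pep sequence,
#' so similarity between them is meaningful. All randomness flows from
#' `params$seed`; two runs with equal params produce byte-identical files.
#'
#' @param params A `sim_params`.
#' @param out_dir Output directory (created if needed).
#' @return list with `spec` (a `repo_spec`), `spec_path`, and `ledger`
#'   (class `truth_ledger`: `families`, `events`, `params`).
#' @export
simulate_repository <- function(params = simulation_params(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)
  nf <- params$n_genes
  nsc <- params$n_scaffolds

  # ancestor: families dealt in order onto scaffolds, lengths and sequences
  fam_len_cds <- 3L * sample(100:300, nf, replace = TRUE)
  fam_cds <- vapply(fam_len_cds, rand_seq, "", alphabet = c("A", "C", "G", "T"))
  fam_pep <- vapply(fam_len_cds %/% 3L, rand_seq, "",
                    alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  per_sc <- rep(nf %/% nsc, nsc)
  if (nf %% nsc > 0) per_sc[seq_len(nf %% nsc)] <- per_sc[seq_len(nf %% nsc)] + 1L
  anc <- split(seq_len(nf), rep(seq_len(nsc), per_sc))

  genomes <- sprintf("G%d", seq_len(params$n_genomes))
  spec_rows <- list(); fam_rows <- list(); ev_rows <- list()

  for (g in genomes) {
    sc_genes <- lapply(anc, function(fams)
      data.frame(family = fams, strand = "+", stringsAsFactors = FALSE))
    events <- list()
    record_event <- function(type, scaffold, from, to, dest_scaffold = NA,
                             dest_pos = NA, whole = NA) {
      events[[length(events) + 1L]] <<- data.frame(
        genome_id = g, type = type, scaffold = scaffold,
        from_index = from, to_index = to, dest_scaffold = dest_scaffold,
        dest_pos = dest_pos, whole_scaffold = whole, stringsAsFactors = FALSE)
    }

    # gene loss
    if (params$gene_loss > 0) {
      for (s in seq_len(nsc)) {
        keep <- stats::runif(nrow(sc_genes[[s]])) >= params$gene_loss
        lost <- sc_genes[[s]]$family[!keep]
        for (fam in lost) record_event("loss", s, NA, NA)
        sc_genes[[s]] <- sc_genes[[s]][keep, , drop = FALSE]
      }
    }

    # tandem duplications
    n_dup <- stats::rpois(1, params$gene_duplication)
    for (k in seq_len(n_dup)) {
      sizes <- vapply(sc_genes, nrow, 0L)
      if (sum(sizes) == 0L) break
      s <- sample(rep(seq_len(nsc), sizes), 1)
      i <- sample(nrow(sc_genes[[s]]), 1)
      row <- sc_genes[[s]][i, , drop = FALSE]
      sc_genes[[s]] <- rbind(sc_genes[[s]][seq_len(i), , drop = FALSE], row,
                             if (i < nrow(sc_genes[[s]]))
                               sc_genes[[s]][(i + 1):nrow(sc_genes[[s]]), , drop = FALSE])
      record_event("duplication", s, i, i)
    }

    # inversions: reverse a gene block and flip strands
    n_inv <- stats::rpois(1, params$inversions)
    for (k in seq_len(n_inv)) {
      eligible <- which(vapply(sc_genes, nrow, 0L) >= 2L)
      if (length(eligible) == 0L) break
      s <- if (length(eligible) == 1L) eligible else sample(eligible, 1)
      n <- nrow(sc_genes[[s]])
      if (stats::runif(1) < params$whole_scaffold_prob) {
        i <- 1L; j <- n; whole <- TRUE
      } else {
        ij <- sort(sample(n, 2))
        i <- ij[1]; j <- ij[2]; whole <- (i == 1L && j == n)
      }
      blk <- sc_genes[[s]][i:j, , drop = FALSE]
      blk <- blk[rev(seq_len(nrow(blk))), , drop = FALSE]
      blk$strand <- ifelse(blk$strand == "+", "-", "+")
      sc_genes[[s]][i:j, ] <- blk
      record_event("inversion", s, i, j, whole = whole)
    }

    # translocations: move a block to another scaffold
    n_tr <- if (nsc >= 2L) stats::rpois(1, params$translocations) else 0L
    for (k in seq_len(n_tr)) {
      eligible <- which(vapply(sc_genes, nrow, 0L) >= 2L)
      if (length(eligible) == 0L || nsc < 2L) break
      s <- if (length(eligible) == 1L) eligible else sample(eligible, 1)
      n <- nrow(sc_genes[[s]])
      w <- sample(seq_len(max(1L, n %/% 5L)), 1)  # block of up to ~20% of genes
      i <- sample(n - w + 1L, 1); j <- i + w - 1L
      blk <- sc_genes[[s]][i:j, , drop = FALSE]
      sc_genes[[s]] <- sc_genes[[s]][-(i:j), , drop = FALSE]
      dest <- sample(setdiff(seq_len(nsc), s), 1)
      pos <- sample(0:nrow(sc_genes[[dest]]), 1)
      sc_genes[[dest]] <- rbind(
        if (pos > 0) sc_genes[[dest]][seq_len(pos), , drop = FALSE], blk,
        if (pos < nrow(sc_genes[[dest]]))
          sc_genes[[dest]][(pos + 1):nrow(sc_genes[[dest]]), , drop = FALSE])
      record_event("translocation", s, i, j, dest_scaffold = dest, dest_pos = pos)
    }

    # coordinates, ids, files
    feats <- list(); counter <- 0L
    sc_seqs <- character(nsc)
    sc_names <- sprintf("sc%d", seq_len(nsc))
    for (s in seq_len(nsc)) {
      genes <- sc_genes[[s]]
      pos <- 0L
      rows <- vector("list", nrow(genes))
      for (i in seq_len(nrow(genes))) {
        gap <- sample(100:400, 1)
        start <- pos + gap
        end <- start + fam_len_cds[genes$family[i]] - 1L
        pos <- end
        counter <- counter + 1L
        gid <- sprintf("%s_g%05d", g, counter)
        rows[[i]] <- data.frame(genome_id = g, seq_id = sc_names[s],
                                gene_id = gid, start = start, end = end,
                                strand = genes$strand[i],
                                category = NA_integer_,
                                family = genes$family[i],
                                position = i, stringsAsFactors = FALSE)
      }
      sc_len <- pos + sample(100:400, 1)
      sc_seqs[s] <- rand_seq(sc_len, c("A", "C", "G", "T"))
      feats[[s]] <- do.call(rbind, rows)
    }
    feats <- do.call(rbind, feats)

    genome_fa <- file.path(out_dir, paste0(g, ".genome.fasta"))
    cds_fa <- file.path(out_dir, paste0(g, ".cds.fasta"))
    pep_fa <- file.path(out_dir, paste0(g, ".pep.fasta"))
    gff <- file.path(out_dir, paste0(g, ".gff3"))
    write_fasta(data.frame(id = sc_names, description = "",
                           residues = sc_seqs, stringsAsFactors = FALSE),
                genome_fa)
    tids <- paste0(feats$gene_id, ".t1")
    write_fasta(data.frame(id = tids, description = "",
                           residues = fam_cds[feats$family],
                           stringsAsFactors = FALSE), cds_fa)
    write_fasta(data.frame(id = tids, description = "",
                           residues = fam_pep[feats$family],
                           stringsAsFactors = FALSE), pep_fa)
    write_gff3(feats[, c("genome_id", "seq_id", "gene_id", "start", "end",
                         "strand", "category")], gff)
    spec_rows[[g]] <- data.frame(genome_id = g, genome_fasta = genome_fa,
                                 cds_fasta = cds_fa, pep_fasta = pep_fa,
                                 gff = gff, stringsAsFactors = FALSE)
    fam_rows[[g]] <- feats[, c("family", "genome_id", "gene_id", "seq_id",
                               "position", "strand", "start", "end")]
    if (length(events) > 0L) ev_rows[[g]] <- do.call(rbind, events)
  }

  spec <- do.call(rbind, spec_rows)
  rownames(spec) <- NULL
  class(spec) <- c("repo_spec", "data.frame")
  spec_path <- file.path(out_dir, "repo_spec.txt")
  write_repo_spec(spec, spec_path)

  families <- do.call(rbind, fam_rows)
  rownames(families) <- NULL
  events <- if (length(ev_rows) > 0L) do.call(rbind, ev_rows) else
    data.frame(genome_id = character(0), type = character(0),
               scaffold = integer(0), from_index = integer(0),
               to_index = integer(0), dest_scaffold = integer(0),
               dest_pos = integer(0), whole_scaffold = logical(0),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  ledger <- structure(list(families = families, events = events,
                           fam_len_pep = fam_len_cds %/% 3L,
                           params = params), class = "truth_ledger")
  utils::write.table(families, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(events, file.path(out_dir, "truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(spec = spec, spec_path = spec_path, ledger = ledger)
}

#' True homolog pairs implied by a truth ledger
#'
#' All unordered pairs of genes sharing an ancestral family. With
#' `cross_genome_only = TRUE` (the default) only ortholog pairs (members in
#' different genomes) are returned; otherwise within-genome paralog pairs
#' from duplications are included.
#'
#' @param ledger A `truth_ledger`.
#' @param cross_genome_only Drop within-genome pairs (default TRUE).
#' @return data.frame `gene_a`, `gene_b` (gene_a < gene_b), `family`,
#'   `genome_a`, `genome_b`.
#' @export
true_pairs <- function(ledger, cross_genome_only = TRUE) {
  fam <- ledger$families
  out <- list()
  for (members in split(seq_len(nrow(fam)), fam$family)) {
    if (length(members) < 2L) next
    idx <- utils::combn(members, 2)
    out[[length(out) + 1L]] <- data.frame(
      gene_a = fam$gene_id[idx[1, ]], gene_b = fam$gene_id[idx[2, ]],
      family = fam$family[members[1]],
      genome_a = fam$genome_id[idx[1, ]], genome_b = fam$genome_id[idx[2, ]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      family = integer(0), genome_a = character(0),
                      genome_b = character(0), stringsAsFactors = FALSE))
  p <- do.call(rbind, out)
  if (cross_genome_only) p <- p[p$genome_a != p$genome_b, , drop = FALSE]
  swap <- p$gene_a > p$gene_b
  tmp <- p$gene_a[swap]; p$gene_a[swap] <- p$gene_b[swap]; p$gene_b[swap] <- tmp
  tmpg <- p$genome_a[swap]; p$genome_a[swap] <- p$genome_b[swap]; p$genome_b[swap] <- tmpg
  rownames(p) <- NULL
  p[order(p$gene_a, p$gene_b), , drop = FALSE]
}

#' Simulate all-vs-all hit tables consistent with a truth ledger
#'
#' For every true homolog pair a reciprocal pair of hit records is emitted
#' with bitscore 400 minus a per-family divergence offset (drawn once per
#' family from Uniform(0, 100)) plus Gaussian noise of sd `bitscore_sd` per
#' record; the e-value is `10^(-bitscore/2)` floored at 1e-250. A true
#' match is dropped entirely (both directions) with probability
#' `missing_hit_rate`. Spurious cross-family hits (uniform random gene
#' pairs, bitscore Uniform(50, 80)) are added at `spurious_hit_rate` per
#' true match. One m8 file is written per genome pair (both directions in
#' the same file); within-genome files appear only when paralog or spurious
#' within-genome hits exist.
#'
#' @param ledger A `truth_ledger` from [simulate_repository()].
#' @param out_dir Directory for the m8 files.
#' @param params A `sim_params` (defaults to the ledger's own).
#' @return list with `hits` (the full hit data.frame) and `files` (named
#'   character vector of m8 paths).
#' @export
simulate_hits <- function(ledger, out_dir, params = ledger$params) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(sv_child_seed(params$seed, 7L))
  fam <- ledger$families
  n_fam <- max(fam$family)
  offset <- stats::runif(n_fam, 0, 100)
  pep_len <- ledger$fam_len_pep

  pairs <- true_pairs(ledger, cross_genome_only = FALSE)
  if (nrow(pairs) > 0L && params$missing_hit_rate > 0) {
    keep <- stats::runif(nrow(pairs)) >= params$missing_hit_rate
    pairs <- pairs[keep, , drop = FALSE]
  }
  make_records <- function(q, s, fam_id, bits) {
    len <- pep_len[fam_id]
    pid <- pmax(35, 100 - offset[fam_id] / 3)
    ev <- pmax(10^(-bits / 2), 1e-250)
    data.frame(query_id = q, subject_id = s, percent_identity = round(pid, 2),
               aln_length = len, mismatches = as.integer(round(len * (1 - pid / 100))),
               gap_openings = 0L, q_start = 1L, q_end = len, s_start = 1L,
               s_end = len, evalue = ev, bitscore = round(bits, 1),
               stringsAsFactors = FALSE)
  }
  hits <- empty_m8()
  if (nrow(pairs) > 0L) {
    base <- 400 - offset[pairs$family]
    b_ab <- base + stats::rnorm(nrow(pairs), 0, params$bitscore_sd)
    b_ba <- base + stats::rnorm(nrow(pairs), 0, params$bitscore_sd)
    hits <- rbind(make_records(pairs$gene_a, pairs$gene_b, pairs$family, b_ab),
                  make_records(pairs$gene_b, pairs$gene_a, pairs$family, b_ba))
  }
  if (params$spurious_hit_rate > 0 && nrow(pairs) > 0L) {
    n_spur <- stats::rpois(1, params$spurious_hit_rate * nrow(pairs))
    got <- 0L; spur <- list()
    while (got < n_spur) {
      i <- sample(nrow(fam), 2)
      if (fam$family[i[1]] == fam$family[i[2]]) next
      got <- got + 1L
      bits <- stats::runif(1, 50, 80)
      len <- min(pep_len[fam$family[i[1]]], pep_len[fam$family[i[2]]])
      ev <- pmax(10^(-bits / 2), 1e-250)
      spur[[got]] <- data.frame(
        query_id = fam$gene_id[i[1]], subject_id = fam$gene_id[i[2]],
        percent_identity = round(stats::runif(1, 25, 40), 2), aln_length = len,
        mismatches = as.integer(round(len * 0.6)), gap_openings = 1L,
        q_start = 1L, q_end = len, s_start = 1L, s_end = len,
        evalue = ev, bitscore = round(bits, 1), stringsAsFactors = FALSE)
    }
    if (length(spur) > 0L) hits <- rbind(hits, do.call(rbind, spur))
  }

  gene_genome <- fam$genome_id
  names(gene_genome) <- fam$gene_id
  files <- character(0)
  if (nrow(hits) > 0L) {
    qg <- gene_genome[hits$query_id]; sg <- gene_genome[hits$subject_id]
    key <- ifelse(qg < sg, paste0(qg, "_vs_", sg), paste0(sg, "_vs_", qg))
    ord <- order(key, hits$query_id, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    key <- key[ord]
    for (k in unique(key)) {
      path <- file.path(out_dir, paste0(k, ".m8"))
      write_m8(hits[key == k, , drop = FALSE], path)
      files[k] <- path
    }
  }
  rownames(hits) <- NULL
  list(hits = hits, files = files)
}
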