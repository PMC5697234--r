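# Independent oracles and fixture generators. These deliberately avoid the
# package's own code paths.

# ---- union-find (oracle for single-linkage components) ----------------------
uf_components <- function(pairs) {
  nodes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$gene_a[i]); rb <- find(pairs$gene_b[i])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# ---- brute-force best hits / RBH -------------------------------------------
oracle_best_hits <- function(hits, gene_genome) {
  hits$qg <- gene_genome[hits$query_id]
  hits$sg <- gene_genome[hits$subject_id]
  hits <- hits[hits$qg != hits$sg & hits$query_id != hits$subject_id, ]
  out <- list()
  for (q in unique(hits$query_id)) {
    for (tg in unique(hits$sg[hits$query_id == q])) {
      h <- hits[hits$query_id == q & hits$sg == tg, ]
      h <- h[order(-h$bitscore, h$evalue, h$subject_id), ]
      out[[paste(q, tg)]] <- h[1, ]
    }
  }
  do.call(rbind, out)
}

oracle_rbh <- function(hits, gene_genome) {
  best <- oracle_best_hits(hits, gene_genome)
  bsub <- stats::setNames(best$subject_id, paste(best$query_id, best$sg))
  pairs <- list()
  genes <- unique(c(best$query_id, best$subject_id))
  for (a in genes) for (b in genes) {
    if (a >= b) next
    if (gene_genome[[a]] == gene_genome[[b]]) next
    ab <- bsub[paste(a, gene_genome[[b]])]
    ba <- bsub[paste(b, gene_genome[[a]])]
    if (!is.na(ab) && !is.na(ba) && ab == b && ba == a)
      pairs[[length(pairs) + 1]] <- c(a, b)
  }
  if (length(pairs) == 0) return(data.frame(gene_a = character(0),
                                            gene_b = character(0)))
  m <- do.call(rbind, pairs)
  out <- data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), ]
}

# ---- exhaustive collinear-subset chain oracle ------------------------------
# best score over every subset forming a valid chain (strictly increasing
# rank_a; rank_b strictly increasing for forward / decreasing for reverse;
# consecutive rank gaps <= max_gap on both axes), scored as the DP does.
oracle_best_chain_score <- function(matches, params) {
  n <- nrow(matches)
  best <- max(matches$match_score)  # single-match chains always valid
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2) next
    for (rev in c(FALSE, TRUE)) {
      ra <- matches$rank_a[idx]
      rb <- if (rev) -matches$rank_b[idx] else matches$rank_b[idx]
      o <- order(ra)
      ra <- ra[o]; rb <- rb[o]
      da <- diff(ra); db <- diff(rb)
      if (any(da <= 0) || any(db <= 0)) next
      if (any(da > params$max_gap) || any(db > params$max_gap)) next
      score <- sum(matches$match_score[idx]) +
        params$gap_penalty * sum(da - 1 + db - 1)
      if (score > best) best <- score
    }
  }
  best
}

# ---- brute-force crossing count --------------------------------------------
oracle_crossings <- function(xt, xb) {
  n <- length(xt)
  cnt <- 0L
  if (n < 2) return(0L)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if ((xt[i] - xt[j]) * (xb[i] - xb[j]) < 0) cnt <- cnt + 1L
  cnt
}

# ---- fixture generators ----------------------------------------------------
random_seq_records <- function(n, min_len = 10, max_len = 1000) {
  data.frame(
    id = sprintf("seq%03d", seq_len(n)),
    description = ifelse(runif(n) < 0.5, "", sprintf("desc %d", seq_len(n))),
    residues = vapply(sample(min_len:max_len, n, replace = TRUE), function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""),
    stringsAsFactors = FALSE)
}

random_m8 <- function(n) {
  bits <- round(runif(n, 30, 500), 1)
  data.frame(
    query_id = sprintf("q%04d", sample(9999, n)),
    subject_id = sprintf("s%04d", sample(9999, n)),
    percent_identity = round(runif(n, 20, 100), 2),
    aln_length = sample(50:2000, n, replace = TRUE),
    mismatches = sample(0:500, n, replace = TRUE),
    gap_openings = sample(0:20, n, replace = TRUE),
    q_start = sample(1000, n, replace = TRUE),
    q_end = sample(1000, n, replace = TRUE) + 1000L,
    s_start = sample(1000, n, replace = TRUE),
    s_end = sample(1000, n, replace = TRUE) + 1000L,
    evalue = 10^(-runif(n, 0, 180)),
    bitscore = bits, stringsAsFactors = FALSE)
}

random_chain <- function(id, n_pairs = sample(2:8, 1)) {
  sa <- sample(2000, n_pairs)
  sb <- sample(2000, n_pairs)
  synviz::synteny_chain(
    id, paste0("gnm", sample(9, 1)), paste0("gnm", 9 + sample(9, 1)),
    paste0("scA", sample(99, 1)), paste0("scB", sample(99, 1)),
    sample(c("forward", "reverse"), 1),
    data.frame(gene_a = sprintf("a%03d", seq_len(n_pairs)),
               start_a = sa, end_a = sa + sample(500, n_pairs),
               gene_b = sprintf("b%03d", seq_len(n_pairs)),
               start_b = sb, end_b = sb + sample(500, n_pairs),
               pair_score = round(runif(n_pairs, 1, 50), 4),
               stringsAsFactors = FALSE),
    round(runif(1, 10, 400), 4))
}

random_matches <- function(n, max_rank = 15, score_range = c(5, 50)) {
  ra <- sample(0:max_rank, n)
  rb <- sample(0:max_rank, n)
  data.frame(seq_a = "scA", rank_a = ra,
             gene_a = sprintf("a%02d", seq_len(n)),
             start_a = (ra + 1L) * 1000L, end_a = (ra + 1L) * 1000L + 500L,
             seq_b = "scB", rank_b = rb,
             gene_b = sprintf("b%02d", seq_len(n)),
             start_b = (rb + 1L) * 1000L, end_b = (rb + 1L) * 1000L + 500L,
             match_score = round(runif(n, score_range[1], score_range[2]), 3),
             stringsAsFactors = FALSE)
}

# hits table over k genomes with g genes each, random cross-genome hits
random_hit_world <- function(n_genomes = 3, genes_per_genome = 20,
                             n_hits = 200) {
  genomes <- sprintf("G%d", seq_len(n_genomes))
  genes <- unlist(lapply(genomes, function(g)
    sprintf("%s_x%03d", g, seq_len(genes_per_genome))))
  gene_genome <- stats::setNames(rep(genomes, each = genes_per_genome), genes)
  q <- sample(genes, n_hits, replace = TRUE)
  s <- sample(genes, n_hits, replace = TRUE)
  keep <- q != s
  h <- random_m8(sum(keep))
  h$query_id <- q[keep]
  h$subject_id <- s[keep]
  list(hits = h, gene_genome = gene_genome)
}

# minimal in-memory repo_db for layout/render unit tests (no files)
toy_db <- function(genomes, scaffolds) {
  # scaffolds: data.frame(genome_id, seq_id, length_bp)
  spec <- data.frame(genome_id = genomes, genome_fasta = "", cds_fasta = "",
                     pep_fasta = "", gff = "", stringsAsFactors = FALSE)
  class(spec) <- c("repo_spec", "data.frame")
  structure(list(spec = spec,
                 features = synviz:::empty_features(),
                 scaffold_lengths = scaffolds,
                 summary = NULL, gene_genome = character(0),
                 ambiguous_gene_ids = character(0)),
            class = "repo_db")
}

# simulated repository in a fresh temp dir; returns everything tests need
sim_world <- function(params) {
  td <- tempfile("simworld")
  sim <- simulate_repository(params, td)
  hits <- simulate_hits(sim$ledger, file.path(td, "m8"))
  list(dir = td, m8_dir = file.path(td, "m8"), sim = sim,
       spec = sim$spec, spec_path = sim$spec_path, ledger = sim$ledger,
       hits = hits$hits, files = hits$files)
}

rbh_precision_recall <- function(rbh_pairs, ledger) {
  truth <- true_pairs(ledger)
  truth_key <- paste(truth$gene_a, truth$gene_b)
  got_key <- paste(rbh_pairs$gene_a, rbh_pairs$gene_b)
  list(precision = if (length(got_key)) mean(got_key %in% truth_key) else NA,
       recall = if (length(truth_key)) mean(truth_key %in% got_key) else NA)
}
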