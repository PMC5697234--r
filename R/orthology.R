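#' Best hit per (query gene, target genome)
#'
#' For every query gene, keeps the single best cross-genome hit into each
#' target genome: maximal bitscore, ties broken by smaller e-value, then by
#' lexicographically smaller subject id. Hits whose query and subject share
#' a genome, and self hits, are excluded.
#'
#' @param hits data.frame of hit records (see [read_m8()]).
#' @param gene_genome Named character vector mapping gene id -> genome id.
#' @return data.frame of retained hit rows plus `q_genome`, `s_genome`.
#' @export
best_hits <- function(hits, gene_genome) {
  if (nrow(hits) == 0L)
    return(cbind(empty_m8(), data.frame(q_genome = character(0),
                                        s_genome = character(0))))
  unmapped <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                      names(gene_genome))
  if (length(unmapped) > 0L)
    sv_abort("gene id(s) not mapped to any genome: %s",
             paste(head(unmapped, 5), collapse = ", "))
  dt <- data.table::as.data.table(hits)
  dt[, q_genome := gene_genome[query_id]]
  dt[, s_genome := gene_genome[subject_id]]
  dt <- dt[q_genome != s_genome & query_id != subject_id]
  if (nrow(dt) == 0L)
    return(cbind(empty_m8(), data.frame(q_genome = character(0),
                                        s_genome = character(0))))
  data.table::setorder(dt, query_id, s_genome, -bitscore, evalue, subject_id)
  best <- dt[, .SD[1L], by = .(query_id, s_genome)]
  data.table::setcolorder(best, c(m8_cols, "q_genome", "s_genome"))
  as.data.frame(best)
}

#' Reciprocal best hits
#'
#' Emits the pair (a, b) iff a's best hit into b's genome is b and b's best
#' hit into a's genome is a. Pairs are canonicalized so `gene_a` is the
#' lexicographically smaller id; the two supporting bitscores/e-values are
#' kept as evidence.
#'
#' @param best data.frame from [best_hits()].
#' @return data.frame with columns `gene_a`, `genome_a`, `gene_b`,
#'   `genome_b`, `bitscore_ab`, `evalue_ab`, `bitscore_ba`, `evalue_ba`.
#' @export
reciprocal_best_hits <- function(best) {
  empty <- data.frame(gene_a = character(0), genome_a = character(0),
                      gene_b = character(0), genome_b = character(0),
                      bitscore_ab = numeric(0), evalue_ab = numeric(0),
                      bitscore_ba = numeric(0), evalue_ba = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(best) == 0L) return(empty)
  dt <- data.table::as.data.table(best)
  fwd <- dt[, .(query_id, subject_id, q_genome, s_genome, bitscore, evalue)]
  rev <- dt[, .(query_id = subject_id, subject_id = query_id,
                bitscore_ba = bitscore, evalue_ba = evalue)]
  merged <- merge(fwd, rev, by = c("query_id", "subject_id"))
  if (nrow(merged) == 0L) return(empty)
  merged <- merged[query_id < subject_id]
  if (nrow(merged) == 0L) return(empty)
  out <- data.frame(gene_a = merged$query_id, genome_a = merged$q_genome,
                    gene_b = merged$subject_id, genome_b = merged$s_genome,
                    bitscore_ab = merged$bitscore, evalue_ab = merged$evalue,
                    bitscore_ba = merged$bitscore_ba,
                    evalue_ba = merged$evalue_ba, stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Single-linkage ortholog clusters
#'
#' Clusters are the connected components of the undirected ortholog-pair
#' graph. Cluster ids are assigned in order of each component's
#' lexicographically smallest member. Singleton components cannot arise
#' from pairs and are never emitted.
#'
#' @param pairs data.frame from [reciprocal_best_hits()] (columns `gene_a`,
#'   `genome_a`, `gene_b`, `genome_b`).
#' @return data.frame with columns `cluster_id`, `genome_id`, `gene_id`,
#'   one row per member.
#' @export
single_linkage_clusters <- function(pairs) {
  if (nrow(pairs) == 0L) return(empty_clusters())
  g <- igraph::graph_from_data_frame(
    pairs[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  genome_of <- c(pairs$genome_a, pairs$genome_b)
  names(genome_of) <- c(pairs$gene_a, pairs$gene_b)
  members <- split(names(comp$membership), comp$membership)
  smallest <- vapply(members, function(m) min(m), character(1))
  members <- members[order(smallest)]
  do.call(rbind, lapply(seq_along(members), function(k) {
    m <- sort(members[[k]])
    data.frame(cluster_id = k, genome_id = unname(genome_of[m]), gene_id = m,
               stringsAsFactors = FALSE)
  }))
}

empty_clusters <- function() {
  data.frame(cluster_id = integer(0), genome_id = character(0),
             gene_id = character(0), stringsAsFactors = FALSE)
}

#' Build the weighted hit graph for Markov clustering
#'
#' Nodes are genes; an undirected edge connects every hit pair with weight
#' -log10(evalue), e-values floored at 1e-250. Self hits are discarded;
#' within-genome hits are kept (they let MCL group in-paralogs). Parallel
#' edges (reciprocal hits) collapse to their maximum weight.
#'
#' @param hits data.frame of hit records.
#' @return igraph undirected weighted graph.
#' @export
build_hit_graph <- function(hits) {
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  w <- -log10(pmax(hits$evalue, 1e-250))
  keep <- w > 0 & is.finite(w)
  hits <- hits[keep, , drop = FALSE]; w <- w[keep]
  g <- igraph::graph_from_data_frame(
    data.frame(from = hits$query_id, to = hits$subject_id, weight = w,
               stringsAsFactors = FALSE), directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Markov clustering (MCL) of the hit graph
#'
#' Classic MCL: self loops are added with weight equal to each node's
#' maximum incident weight, columns are normalized to stochastic, then the
#' loop alternates expansion (matrix self-product), inflation (entry-wise
#' power and column renormalization) and pruning of entries below
#' `prune` (followed by renormalization), until the largest entry change
#' falls below `tol` or `max_iter` is reached (the latter emits a warning
#' and clusters the current state). Clusters are the connected components
#' of the converged nonzero structure; singletons are dropped.
#'
#' @param graph igraph object from [build_hit_graph()].
#' @param gene_genome Named vector gene id -> genome id (for the output).
#' @param inflation Inflation exponent, must be > 1 (default 1.5).
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence threshold on the max entry change (default 1e-6).
#' @param prune Entries below this are zeroed each iteration (default 1e-5).
#' @param trace If TRUE, attach an attribute `mcl_trace` (data.frame with
#'   per-iteration max change and worst column-sum deviation).
#' @return data.frame with columns `cluster_id`, `genome_id`, `gene_id`.
#' @export
mcl_clusters <- function(graph, gene_genome, inflation = 1.5,
                         max_iter = 100L, tol = 1e-6, prune = 1e-5,
                         trace = FALSE) {
  if (inflation <= 1) sv_abort("MCL inflation must be > 1 (got %g)", inflation)
  n <- igraph::vcount(graph)
  if (n == 0L) return(empty_clusters())
  ids <- igraph::V(graph)$name
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(A)
  tr <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2@x <- M2@x^inflation              # inflation
    M2 <- normalize(M2)
    M2@x[M2@x < prune] <- 0             # prune
    M2 <- Matrix::drop0(M2)
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    if (trace) {
      dev <- max(abs(Matrix::colSums(M2) - 1))
      tr[[it]] <- data.frame(iter = it, max_change = delta, col_sum_dev = dev)
    }
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    sv_warn("MCL did not converge in %d iterations; clustering current state",
            max_iter)
  S <- M + Matrix::t(M)
  gm <- igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gm)
  members <- split(ids, comp$membership)
  members <- members[lengths(members) >= 2L]
  if (length(members) == 0L) return(empty_clusters())
  smallest <- vapply(members, function(m) min(m), character(1))
  members <- members[order(smallest)]
  out <- do.call(rbind, lapply(seq_along(members), function(k) {
    m <- sort(members[[k]])
    data.frame(cluster_id = k,
               genome_id = unname(gene_genome[m]),
               gene_id = m, stringsAsFactors = FALSE)
  }))
  if (trace) attr(out, "mcl_trace") <- do.call(rbind, tr)
  out
}

#' Summarize ortholog clusters against a repository
#'
#' @param clusters data.frame (`cluster_id`, `genome_id`, `gene_id`).
#' @param db A `repo_db`.
#' @return list with `per_cluster` (data.frame: cluster_id, size, one count
#'   column per genome, members) and `global` (n_clusters,
#'   n_clustered_genes, n_unclustered_genes).
#' @export
summarize_clusters <- function(clusters, db) {
  genomes <- db$spec$genome_id
  total_genes <- nrow(db$features)
  if (nrow(clusters) > 0L) {
    key_repo <- paste(db$features$genome_id, db$features$gene_id)
    key_cl <- paste(clusters$genome_id, clusters$gene_id)
    missing <- setdiff(key_cl, key_repo)
    if (length(missing) > 0L)
      sv_abort("cluster member(s) absent from repository: %s",
               paste(head(missing, 5), collapse = ", "))
  }
  if (nrow(clusters) == 0L) {
    per <- data.frame(cluster_id = integer(0), size = integer(0))
    for (g in genomes) per[[g]] <- integer(0)
    per$members <- character(0)
    return(list(per_cluster = per,
                global = list(n_clusters = 0L, n_clustered_genes = 0L,
                              n_unclustered_genes = total_genes)))
  }
  split_cl <- split(clusters, clusters$cluster_id)
  per <- do.call(rbind, lapply(split_cl, function(cl) {
    row <- data.frame(cluster_id = cl$cluster_id[1], size = nrow(cl))
    for (g in genomes) row[[g]] <- sum(cl$genome_id == g)
    row$members <- paste(paste0(cl$genome_id, ":", cl$gene_id), collapse = ",")
    row
  }))
  rownames(per) <- NULL
  list(per_cluster = per,
       global = list(n_clusters = length(split_cl),
                     n_clustered_genes = nrow(clusters),
                     n_unclustered_genes = total_genes - nrow(clusters)))
}

#' Write / read the cluster membership file
#'
#' Tab-separated: cluster_id, genome_id, gene_id; one line per member.
#'
#' @param clusters data.frame (`cluster_id`, `genome_id`, `gene_id`).
#' @param path File path.
#' @export
write_clusters <- function(clusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(clusters) > 0L)
    writeLines(paste(clusters$cluster_id, clusters$genome_id,
                     clusters$gene_id, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- sv_read_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) return(empty_clusters())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L)
    sv_abort("clusters %s line %d: expected 3 columns", path, keep[bad[1]])
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  data.frame(cluster_id = as.integer(m[, 1]), genome_id = m[, 2],
             gene_id = m[, 3], stringsAsFactors = FALSE)
}

#' Write the cluster summary file
#'
#' Per-cluster lines (cluster_id, size, per-genome counts, members) then a
#' global line: n_clusters, n_clustered_genes, n_unclustered_genes.
#'
#' @param summary List from [summarize_clusters()].
#' @param path Output path.
#' @export
write_cluster_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  per <- summary$per_cluster
  writeLines(paste0("# ", paste(names(per), collapse = "\t")), con)
  for (i in seq_len(nrow(per)))
    writeLines(paste(unlist(per[i, ]), collapse = "\t"), con)
  g <- summary$global
  writeLines(sprintf("# global\tn_clusters=%d\tn_clustered_genes=%d\tn_unclustered_genes=%d",
                     g$n_clusters, g$n_clustered_genes, g$n_unclustered_genes), con)
  invisible(path)
}
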