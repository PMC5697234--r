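#' Chaining parameters
#'
#' @param min_pairs Minimum ortholog pairs per emitted chain (default 5).
#' @param max_gap Maximum rank gap between consecutive chain members on
#'   either genome, in gene-rank units (default 20).
#' @param gap_penalty Penalty per skipped rank unit, negative (default -3).
#' @param max_match_score Cap on a single pair's score (default 50).
#' @param max_evalue Ceiling for pair inclusion when hit evidence exists
#'   (default 1e-5).
#' @return list of class `chain_params`.
#' @export
chain_params <- function(min_pairs = 5L, max_gap = 20L, gap_penalty = -3,
                         max_match_score = 50, max_evalue = 1e-5) {
  stopifnot(min_pairs >= 2L, max_gap >= 1L, gap_penalty < 0)
  structure(list(min_pairs = as.integer(min_pairs),
                 max_gap = as.integer(max_gap),
                 gap_penalty = as.numeric(gap_penalty),
                 max_match_score = as.numeric(max_match_score),
                 max_evalue = as.numeric(max_evalue)),
            class = "chain_params")
}

#' Build matches between two genomes from ortholog clusters
#'
#' Every cross-genome member pair within a cluster yields one match. Gene
#' ranks are 0-based order indices along each scaffold, computed over all
#' annotated genes of the scaffold by ascending start coordinate. The match
#' score is `min(max_match_score, -log10(evalue))` when hit evidence for
#' the pair exists (best e-value over either direction), otherwise
#' `max_match_score`; pairs whose best e-value exceeds `max_evalue` are
#' dropped.
#'
#' @param clusters data.frame (`cluster_id`, `genome_id`, `gene_id`).
#' @param db A `repo_db`.
#' @param genome_a,genome_b The two genomes (order defines the A/B sides).
#' @param params A `chain_params`.
#' @param hits Optional hit data.frame providing e-value evidence.
#' @return data.frame of matches: `seq_a`, `rank_a`, `gene_a`, `start_a`,
#'   `end_a`, `seq_b`, `rank_b`, `gene_b`, `start_b`, `end_b`,
#'   `match_score`.
#' @export
build_matches <- function(clusters, db, genome_a, genome_b,
                          params = chain_params(), hits = NULL) {
  stopifnot(genome_a %in% db$spec$genome_id, genome_b %in% db$spec$genome_id)
  feats <- db$features
  rank_tbl <- gene_ranks(feats)
  fa <- feats[feats$genome_id == genome_a, , drop = FALSE]
  fb <- feats[feats$genome_id == genome_b, , drop = FALSE]
  ca <- clusters[clusters$genome_id == genome_a, , drop = FALSE]
  cb <- clusters[clusters$genome_id == genome_b, , drop = FALSE]
  if (nrow(ca) == 0L || nrow(cb) == 0L) return(empty_matches())
  pairs <- merge(ca[, c("cluster_id", "gene_id")],
                 cb[, c("cluster_id", "gene_id")],
                 by = "cluster_id", suffixes = c("_a", "_b"))
  if (nrow(pairs) == 0L) return(empty_matches())

  ev <- pair_evalues(hits, pairs$gene_id_a, pairs$gene_id_b)
  score <- ifelse(is.na(ev), params$max_match_score,
                  pmin(params$max_match_score, -log10(pmax(ev, 1e-250))))
  keep <- is.na(ev) | ev <= params$max_evalue
  pairs <- pairs[keep, , drop = FALSE]; score <- score[keep]
  if (nrow(pairs) == 0L) return(empty_matches())

  ia <- match(pairs$gene_id_a, fa$gene_id)
  ib <- match(pairs$gene_id_b, fb$gene_id)
  if (anyNA(ia) || anyNA(ib))
    sv_abort("gene missing coordinates: %s",
             c(pairs$gene_id_a[is.na(ia)], pairs$gene_id_b[is.na(ib)])[1])
  ka <- paste(genome_a, pairs$gene_id_a)
  kb <- paste(genome_b, pairs$gene_id_b)
  out <- data.frame(seq_a = fa$seq_id[ia], rank_a = rank_tbl[ka],
                    gene_a = pairs$gene_id_a, start_a = fa$start[ia],
                    end_a = fa$end[ia],
                    seq_b = fb$seq_id[ib], rank_b = rank_tbl[kb],
                    gene_b = pairs$gene_id_b, start_b = fb$start[ib],
                    end_b = fb$end[ib],
                    match_score = score, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$seq_a, out$seq_b, out$rank_a, out$rank_b), , drop = FALSE]
}

# Dense 0-based gene order index per (genome, scaffold), by ascending start.
# Returns a vector named "<genome_id> <gene_id>".
gene_ranks <- function(features) {
  o <- order(features$genome_id, features$seq_id, features$start,
             features$gene_id)
  f <- features[o, ]
  grp <- paste(f$genome_id, f$seq_id)
  out <- integer(nrow(f))
  for (ix in split(seq_along(grp), factor(grp, unique(grp))))
    out[ix] <- seq_along(ix) - 1L
  names(out) <- paste(f$genome_id, f$gene_id)
  out
}

pair_evalues <- function(hits, gene_a, gene_b) {
  if (is.null(hits) || nrow(hits) == 0L) return(rep(NA_real_, length(gene_a)))
  key <- ifelse(hits$query_id < hits$subject_id,
                paste(hits$query_id, hits$subject_id),
                paste(hits$subject_id, hits$query_id))
  best <- tapply(hits$evalue, key, min)
  want <- ifelse(gene_a < gene_b, paste(gene_a, gene_b), paste(gene_b, gene_a))
  unname(best[want])
}

empty_matches <- function() {
  data.frame(seq_a = character(0), rank_a = integer(0), gene_a = character(0),
             start_a = integer(0), end_a = integer(0), seq_b = character(0),
             rank_b = integer(0), gene_b = character(0), start_b = integer(0),
             end_b = integer(0), match_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Chain matches on one scaffold pair
#'
#' DAGchainer-style dynamic program in gene-rank space. Forward pass: sort
#' by (rank_a, rank_b); a predecessor j of i must satisfy rank_a[j] <
#' rank_a[i], rank_b[j] < rank_b[i], with both rank gaps at most `max_gap`;
#' score(i) = match_score(i) + max(0, best over j of score(j) +
#' gap_penalty * (rank_a gap - 1 + rank_b gap - 1)). The reverse pass
#' negates rank_b and emits orientation "reverse". Chains are extracted
#' greedily: best unused endpoint first (forward and reverse passes
#' compete), each match consumed by at most one chain, and the DP is
#' recomputed on the remaining matches after each extraction. Chains with
#' fewer than `min_pairs` members or non-positive score are discarded
#' (their matches stay consumed).
#'
#' @param matches data.frame from [build_matches()], all on one
#'   (seq_a, seq_b) scaffold pair.
#' @param params A `chain_params`.
#' @param genome_a,genome_b Genome tokens recorded in the chains.
#' @return list of `synteny_chain` (chain_id = NA; assigned by
#'   [partition_and_chain()]).
#' @export
chain_matches <- function(matches, params = chain_params(),
                          genome_a = "A", genome_b = "B") {
  if (nrow(matches) == 0L) return(list())
  if (length(unique(matches$seq_a)) > 1L || length(unique(matches$seq_b)) > 1L)
    sv_abort("chain_matches requires matches from a single scaffold pair; got %d x %d",
             length(unique(matches$seq_a)), length(unique(matches$seq_b)))
  # canonical order makes extraction deterministic regardless of input order
  matches <- matches[order(matches$rank_a, matches$rank_b, matches$gene_a,
                           matches$gene_b), , drop = FALSE]
  rownames(matches) <- NULL
  used <- rep(FALSE, nrow(matches))
  chains <- list()
  repeat {
    avail <- which(!used)
    if (length(avail) == 0L) break
    fwd <- chain_dp(matches[avail, , drop = FALSE], params, reverse = FALSE)
    rev <- chain_dp(matches[avail, , drop = FALSE], params, reverse = TRUE)
    pick <- if (rev$best_score > fwd$best_score) rev else fwd
    if (pick$best_score <= 0) break
    member_idx <- avail[pick$members]
    used[member_idx] <- TRUE
    if (length(member_idx) >= params$min_pairs) {
      mm <- matches[member_idx, , drop = FALSE]
      mm <- mm[order(mm$rank_a), , drop = FALSE]
      pairs <- data.frame(gene_a = mm$gene_a, start_a = mm$start_a,
                          end_a = mm$end_a, gene_b = mm$gene_b,
                          start_b = mm$start_b, end_b = mm$end_b,
                          pair_score = mm$match_score,
                          stringsAsFactors = FALSE)
      chains[[length(chains) + 1L]] <- synteny_chain(
        NA_integer_, genome_a, genome_b, matches$seq_a[1], matches$seq_b[1],
        if (pick$reverse) "reverse" else "forward", pairs, pick$best_score)
    }
  }
  chains
}

# One DP pass. Returns best endpoint score and the member indices (relative
# to the supplied matches) of its backtracked chain.
chain_dp <- function(m, params, reverse = FALSE) {
  rb <- if (reverse) -m$rank_b else m$rank_b
  ord <- order(m$rank_a, rb)
  ra <- m$rank_a[ord]; rbo <- rb[ord]; ms <- m$match_score[ord]
  n <- length(ord)
  score <- ms
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    da <- ra[i] - ra[seq_len(i - 1L)]
    db <- rbo[i] - rbo[seq_len(i - 1L)]
    ok <- which(da > 0 & db > 0 & da <= params$max_gap & db <= params$max_gap)
    if (length(ok) > 0L) {
      cand <- score[ok] + params$gap_penalty * (da[ok] - 1 + db[ok] - 1)
      j <- ok[which.max(cand)]
      if (cand[which.max(cand)] > 0) {
        score[i] <- ms[i] + max(cand)
        prev[i] <- j
      }
    }
  }
  best <- which.max(score)
  members <- integer(0)
  k <- best
  while (!is.na(k)) { members <- c(k, members); k <- prev[k] }
  list(best_score = score[best], members = ord[members], reverse = reverse)
}

#' Chain matches across all scaffold pairs of a genome pair
#'
#' Groups matches by (seq_a, seq_b), chains each group, and assigns chain
#' ids deterministically: scaffold pairs in lexicographic order, chains
#' within a pair by descending score.
#'
#' @param matches data.frame from [build_matches()] (any scaffold pairs).
#' @param params A `chain_params`.
#' @param genome_a,genome_b Genome tokens.
#' @param first_id Starting chain id (default 1).
#' @param threads Worker processes for per-scaffold-pair chaining
#'   (default 1; results are identical for any value).
#' @return list of `synteny_chain` with global ids assigned.
#' @export
partition_and_chain <- function(matches, params = chain_params(),
                                genome_a = "A", genome_b = "B",
                                first_id = 1L, threads = 1L) {
  if (nrow(matches) == 0L) return(list())
  key <- paste(matches$seq_a, matches$seq_b, sep = "\r")
  groups <- split(seq_len(nrow(matches)), key)
  groups <- groups[order(names(groups))]
  worker <- function(ix) {
    cs <- chain_matches(matches[ix, , drop = FALSE], params, genome_a, genome_b)
    cs[order(-vapply(cs, `[[`, 0, "total_score"))]
  }
  per_group <- if (threads > 1L) {
    parallel::mclapply(groups, worker, mc.cores = threads)
  } else {
    lapply(groups, worker)
  }
  chains <- unlist(per_group, recursive = FALSE, use.names = FALSE)
  if (is.null(chains)) chains <- list()
  for (i in seq_along(chains)) chains[[i]]$chain_id <- first_id + i - 1L
  chains
}
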