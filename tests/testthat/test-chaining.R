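test_that("build_matches ranks genes per scaffold and cross-products clusters", {
  w <- sim_world(simulation_params(n_genomes = 2, n_genes = 12,
                                   n_scaffolds = 1, inversions = 0,
                                   translocations = 0, gene_loss = 0, seed = 41))
  db <- build_repository_db(w$spec, validate = FALSE)
  fam <- w$ledger$families
  # single ortholog pair
  f1 <- fam[fam$family == 1, ]
  cl <- data.frame(cluster_id = 1L, genome_id = f1$genome_id,
                   gene_id = f1$gene_id, stringsAsFactors = FALSE)
  m <- build_matches(cl, db, "G1", "G2")
  expect_equal(nrow(m), 1L)
  expect_equal(m$rank_a, m$rank_b)     # identical genomes, same order
  expect_equal(m$match_score, 50)      # no hit evidence -> capped score

  # cluster {G1:g1, G1:g2, G2:g3} -> two matches
  g1 <- fam$gene_id[fam$genome_id == "G1"][1:2]
  g3 <- fam$gene_id[fam$genome_id == "G2"][3]
  cl2 <- data.frame(cluster_id = 1L, genome_id = c("G1", "G1", "G2"),
                    gene_id = c(g1, g3), stringsAsFactors = FALSE)
  m2 <- build_matches(cl2, db, "G1", "G2")
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$gene_a, g1)
  expect_equal(unique(m2$gene_b), g3)

  # full one-to-one truth: 12 matches, ranks consistent with gene order
  clT <- data.frame(cluster_id = fam$family, genome_id = fam$genome_id,
                    gene_id = fam$gene_id, stringsAsFactors = FALSE)
  mT <- build_matches(clT, db, "G1", "G2", hits = w$hits)
  expect_equal(nrow(mT), 12L)
  expect_equal(mT$rank_a, sort(mT$rank_a))
  expect_equal(mT$rank_a, mT$rank_b)
  pos <- fam$position[match(mT$gene_a, fam$gene_id)]
  expect_equal(mT$rank_a, pos - 1L)
})

test_that("perfect collinear and anti-collinear runs give one chain each", {
  mk <- function(rb) data.frame(
    seq_a = "s1", rank_a = 0:5, gene_a = sprintf("a%d", 0:5),
    start_a = 0:5 * 1000L + 1L, end_a = 0:5 * 1000L + 500L,
    seq_b = "s2", rank_b = rb, gene_b = sprintf("b%d", rb),
    start_b = rb * 1000L + 1L, end_b = rb * 1000L + 500L,
    match_score = 50, stringsAsFactors = FALSE)
  fwd <- chain_matches(mk(0:5), chain_params(), "A", "B")
  expect_equal(length(fwd), 1L)
  expect_equal(fwd[[1]]$orientation, "forward")
  expect_equal(nrow(fwd[[1]]$pairs), 6L)
  expect_equal(fwd[[1]]$total_score, 300)

  rev <- chain_matches(mk(5:0), chain_params(), "A", "B")
  expect_equal(length(rev), 1L)
  expect_equal(rev[[1]]$orientation, "reverse")
  expect_equal(nrow(rev[[1]]$pairs), 6L)
  expect_equal(rev[[1]]$total_score, 300)
  # b ranks strictly decreasing along the reverse chain
  expect_true(all(diff(rev[[1]]$pairs$start_b) < 0))

  two_pairs <- mk(0:5)[1:2, ]
  expect_equal(length(chain_matches(two_pairs, chain_params(min_pairs = 5))), 0L)
  expect_error(chain_matches(transform(mk(0:5), seq_a = c("s1", "s9")[1 + (0:5) %% 2]),
                             chain_params()), "single scaffold pair")
})

test_that("DP best score equals the exhaustive subset oracle (<= 12 matches)", {
  set.seed(43)
  params <- chain_params(min_pairs = 2)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    m <- random_matches(n)
    fwd <- synviz:::chain_dp(m, params, reverse = FALSE)
    rev <- synviz:::chain_dp(m, params, reverse = TRUE)
    got <- max(fwd$best_score, rev$best_score)
    want <- oracle_best_chain_score(m, params)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("chain scores scale equivariantly and ignore input order", {
  set.seed(44)
  m <- random_matches(12)
  p1 <- chain_params(min_pairs = 2, gap_penalty = -3)
  p2 <- chain_params(min_pairs = 2, gap_penalty = -6)
  m2 <- m; m2$match_score <- m$match_score * 2
  c1 <- chain_matches(m, p1, "A", "B")
  c2 <- chain_matches(m2, p2, "A", "B")
  expect_equal(length(c1), length(c2))
  expect_equal(vapply(c2, `[[`, 0, "total_score"),
               2 * vapply(c1, `[[`, 0, "total_score"))

  shuf <- m[sample(nrow(m)), ]
  c3 <- chain_matches(shuf, p1, "A", "B")
  expect_equal(c3, c1)
})

test_that("chains are rank-monotonic per orientation", {
  set.seed(45)
  for (rep in 1:10) {
    m <- random_matches(12)
    for (ch in chain_matches(m, chain_params(min_pairs = 2), "A", "B")) {
      ra <- m$rank_a[match(ch$pairs$gene_a, m$gene_a)]
      rb <- m$rank_b[match(ch$pairs$gene_b, m$gene_b)]
      expect_true(all(diff(ra) > 0))
      if (ch$orientation == "forward") expect_true(all(diff(rb) > 0))
      else expect_true(all(diff(rb) < 0))
    }
  }
})

test_that("partition_and_chain assigns deterministic global ids per scaffold pair", {
  mk <- function(sa, sb, n = 6L) data.frame(
    seq_a = sa, rank_a = 0:(n - 1), gene_a = sprintf("%s_a%d", sa, 1:n),
    start_a = 1:n * 100L, end_a = 1:n * 100L + 50L,
    seq_b = sb, rank_b = 0:(n - 1), gene_b = sprintf("%s_b%d", sb, 1:n),
    start_b = 1:n * 100L, end_b = 1:n * 100L + 50L,
    match_score = 50, stringsAsFactors = FALSE)
  m <- rbind(mk("s2", "t2"), mk("s1", "t1"))
  chains <- partition_and_chain(m, chain_params(), "A", "B")
  expect_equal(vapply(chains, `[[`, 0L, "chain_id"), 1:2)
  expect_equal(chains[[1]]$seq_a, "s1")   # lexicographic scaffold-pair order
  expect_equal(chains[[2]]$seq_a, "s2")
  expect_equal(length(partition_and_chain(synviz:::empty_matches())), 0L)
})

test_that("a simulated translocation splits one scaffold's chains at the breakpoint", {
  p <- simulation_params(n_genomes = 2, n_scaffolds = 2, n_genes = 80,
                         inversions = 0, translocations = 1, gene_loss = 0,
                         seed = 47)
  w <- sim_world(p)
  ev <- w$ledger$events
  tr <- ev[ev$type == "translocation" & ev$genome_id == "G2", ]
  # the simulator is deterministic: seed 47 draws exactly one translocation
  # in G2 moving a block of >= 2 genes (asserted so a seed change is loud)
  expect_equal(nrow(tr), 1L)
  block_size <- tr$to_index - tr$from_index + 1L
  db <- build_repository_db(w$spec, validate = FALSE)
  cl <- single_linkage_clusters(reciprocal_best_hits(best_hits(w$hits, db$gene_genome)))
  params <- chain_params(min_pairs = 2)
  matches <- build_matches(cl, db, "G1", "G2", hits = w$hits)
  chains <- partition_and_chain(matches, params, "G1", "G2")
  spans <- chains_to_spans(chains)
  # the moved block appears as a chain between the source scaffold of G1 and
  # the destination scaffold of G2
  src <- sprintf("sc%d", tr$scaffold[1])
  dst <- sprintf("sc%d", tr$dest_scaffold[1])
  cross <- spans[spans$seq_a == src & spans$seq_b == dst, ]
  if (block_size >= params$min_pairs) {
    expect_true(nrow(cross) >= 1)
    expect_true(any(cross$n_pairs == block_size))
  }
  # and every gene interval is contained in its span
  for (ch in chains) {
    sp <- spans[spans$chain_id == ch$chain_id, ]
    expect_true(all(ch$pairs$start_a >= sp$span_a_start &
                      ch$pairs$end_a <= sp$span_a_end))
    expect_true(all(ch$pairs$start_b >= sp$span_b_start &
                      ch$pairs$end_b <= sp$span_b_end))
  }
})
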