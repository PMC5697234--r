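place <- function(seq_id, orientation, offset, length_bp)
  data.frame(seq_id = seq_id, orientation = orientation, offset = offset,
             length_bp = length_bp, stringsAsFactors = FALSE)

span_row <- function(id, seq_a, a0, a1, seq_b, b0, b1, n = 5,
                     orientation = "forward")
  data.frame(chain_id = id, genome_a = "T", seq_a = seq_a, span_a_start = a0,
             span_a_end = a1, genome_b = "B", seq_b = seq_b,
             span_b_start = b0, span_b_end = b1, n_pairs = n,
             orientation = orientation, stringsAsFactors = FALSE)

test_that("count_crossings: parallel 0, crossed 1, random equals brute force", {
  top <- place("s1", "+", 0, 10000)
  bot <- place("s1", "+", 0, 10000)
  parallel <- rbind(span_row(1, "s1", 100, 200, "s1", 100, 200),
                    span_row(2, "s1", 5000, 6000, "s1", 5000, 6000))
  expect_equal(count_crossings(top, bot, parallel), 0L)
  crossed <- rbind(span_row(1, "s1", 100, 200, "s1", 5000, 6000),
                   span_row(2, "s1", 5000, 6000, "s1", 100, 200))
  expect_equal(count_crossings(top, bot, crossed), 1L)

  set.seed(51)
  for (rep in 1:5) {
    n <- 50
    sp <- do.call(rbind, lapply(seq_len(n), function(i) {
      a <- sample(9000, 1); b <- sample(9000, 1)
      span_row(i, "s1", a, a + 500, "s1", b, b + 500)
    }))
    got <- count_crossings(top, bot, sp)
    xt <- (sp$span_a_start + sp$span_a_end) / 2
    xb <- (sp$span_b_start + sp$span_b_end) / 2
    expect_equal(got, oracle_crossings(xt, xb))
  }
  # unplaced scaffold is a hard error
  expect_error(count_crossings(top, bot, span_row(1, "zz", 1, 2, "s1", 1, 2)),
               "unplaced")
})

test_that("identical genomes get the identity layout with zero crossings", {
  db <- toy_db(c("T", "B"), data.frame(
    genome_id = rep(c("T", "B"), each = 3), seq_id = rep(c("s1", "s2", "s3"), 2),
    length_bp = rep(c(30000L, 20000L, 10000L), 2), stringsAsFactors = FALSE))
  spans <- do.call(rbind, lapply(1:9, function(i) {
    sc <- c("s1", "s2", "s3")[(i - 1) %/% 3 + 1]
    a <- (i %% 3) * 3000 + 100
    span_row(i, sc, a, a + 1000, sc, a, a + 1000)
  }))
  plan <- auto_layout(db, spans)
  expect_equal(plan$placements$T$seq_id, plan$placements$B$seq_id)
  expect_true(all(plan$placements$B$orientation == "+"))
  expect_equal(plan_crossings(plan, spans), 0L)
})

test_that("a fully inverted scaffold is recovered as '-'", {
  db <- toy_db(c("T", "B"), data.frame(
    genome_id = rep(c("T", "B"), each = 2), seq_id = rep(c("s1", "s2"), 2),
    length_bp = rep(c(30000L, 20000L), 2), stringsAsFactors = FALSE))
  # s2 of B is wholly inverted: one reverse-orientation span with many pairs
  spans <- rbind(
    span_row(1, "s1", 100, 25000, "s1", 100, 25000, n = 20, "forward"),
    span_row(2, "s2", 100, 18000, "s2", 100, 18000, n = 12, "reverse"))
  plan <- auto_layout(db, spans)
  expect_equal(plan$placements$B$orientation[plan$placements$B$seq_id == "s2"], "-")
  expect_equal(plan$placements$B$orientation[plan$placements$B$seq_id == "s1"], "+")
  # orientation tie resolves to "+"
  tie <- rbind(span_row(1, "s1", 100, 2000, "s2", 100, 2000, n = 5, "forward"),
               span_row(2, "s1", 3000, 5000, "s2", 3000, 5000, n = 5, "reverse"))
  plan2 <- auto_layout(db, tie)
  expect_equal(plan2$placements$B$orientation[plan2$placements$B$seq_id == "s2"], "+")
})

test_that("auto_layout is deterministic and never beaten by the default layout", {
  set.seed(52)
  for (rep in 1:3) {
    p <- simulation_params(n_genomes = 3, n_scaffolds = 3, n_genes = 90,
                           inversions = 2, translocations = 1,
                           gene_loss = 0.05, seed = 520 + rep)
    w <- sim_world(p)
    db <- build_repository_db(w$spec, validate = FALSE)
    cl <- single_linkage_clusters(
      reciprocal_best_hits(best_hits(w$hits, db$gene_genome)))
    chains <- synviz:::chain_all_pairs(cl, db, chain_params(), w$hits)
    spans <- chains_to_spans(chains)
    auto <- auto_layout(db, spans)
    auto2 <- auto_layout(db, spans)
    expect_identical(auto, auto2)
    expect_lte(plan_crossings(auto, spans),
               plan_crossings(default_layout(db), spans))
  }
})

test_that("config overrides are honored even when they worsen crossings", {
  db <- toy_db(c("T", "B"), data.frame(
    genome_id = rep(c("T", "B"), each = 2), seq_id = rep(c("s1", "s2"), 2),
    length_bp = rep(c(30000L, 20000L), 2), stringsAsFactors = FALSE))
  spans <- rbind(span_row(1, "s1", 100, 25000, "s1", 100, 25000, n = 10),
                 span_row(2, "s2", 100, 15000, "s2", 100, 15000, n = 10))
  cfg <- default_figure_config()
  cfg$scaffold_overrides$B <- data.frame(seq_id = c("s2", "s1"),
                                         orientation = c("-", "+"),
                                         stringsAsFactors = FALSE)
  plan <- auto_layout(db, spans, cfg)
  expect_equal(plan$placements$B$seq_id, c("s2", "s1"))
  expect_equal(plan$placements$B$orientation, c("-", "+"))
  expect_gt(plan_crossings(plan, spans),
            plan_crossings(auto_layout(db, spans), spans))
})

test_that("config generate -> parse -> generate is a byte-identical fixed point", {
  db <- toy_db(c("T", "B"), data.frame(
    genome_id = rep(c("T", "B"), each = 2), seq_id = rep(c("s1", "s2"), 2),
    length_bp = rep(c(30000L, 20000L), 2), stringsAsFactors = FALSE))
  spans <- rbind(span_row(1, "s1", 1, 25000, "s2", 1, 15000, n = 7, "reverse"))
  plan <- auto_layout(db, spans)
  cfg <- default_figure_config(scaffold_highlight = c(s2 = "darkgoldenrod1"))
  text1 <- generate_config(plan, cfg)
  cfg2 <- parse_config(lines = text1, db = db)
  plan2 <- plan_from_config(cfg2, db)
  text2 <- generate_config(plan2, cfg2)
  expect_identical(text2, text1)
  # plan-relevant fields reconstructed exactly
  expect_equal(plan2$placements, plan$placements)
  expect_equal(plan2$genomes, plan$genomes)
})

test_that("parse_config applies defaults, warns on unknown keys, validates hard", {
  cfg <- parse_config(lines = character(0))
  expect_equal(cfg$ribbon_color, "azure4")
  expect_equal(cfg$width, 11)
  expect_equal(cfg$category_colors, c("cornflowerblue", "coral3", "darkcyan"))

  expect_warning(parse_config(lines = "wibble = 3"), "unknown key")
  expect_error(parse_config(lines = "category_colors = red,green,blue,yellow"),
               "up to three")
  expect_error(
    parse_config(lines = c("[genome:G1]", "order = s1:+,s2:*")),
    "orientation")
  db <- toy_db("G1", data.frame(genome_id = "G1", seq_id = "s1",
                                length_bp = 100L, stringsAsFactors = FALSE))
  expect_error(
    parse_config(lines = c("[genome:G1]", "order = sX:+"), db = db),
    "not in repository")
  # three category colors resolve to RGB
  cc <- parse_config(lines = "category_colors = cornflowerblue,coral3,darkcyan")
  expect_equal(length(cc$category_colors), 3L)
  expect_equal(resolve_color("cornflowerblue"), c(100L, 149L, 237L))
})
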