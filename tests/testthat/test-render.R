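test_that("bp -> plot mapping anchors at scaffold edges and mirrors on '-'", {
  p <- data.frame(seq_id = "s1", orientation = "+", offset = 2,
                  length_bp = 1000L, stringsAsFactors = FALSE)
  expect_equal(bp_to_plot(p, 1, scale = 100), 2)
  expect_equal(bp_to_plot(p, 1000, scale = 100), 2 + 999 / 100)
  p$orientation <- "-"
  expect_equal(bp_to_plot(p, 1, scale = 100), 2 + 999 / 100)
  expect_equal(bp_to_plot(p, 1000, scale = 100), 2)
})

test_that("geometry preserves gene order per scaffold (reversed on '-')", {
  w <- sim_world(simulation_params(n_genomes = 2, n_genes = 60,
                                   n_scaffolds = 2, inversions = 2,
                                   translocations = 0, gene_loss = 0,
                                   seed = 61))
  db <- build_repository_db(w$spec, validate = FALSE)
  cfg <- default_figure_config()
  cfg$scaffold_overrides$G2 <- data.frame(seq_id = c("sc1", "sc2"),
                                          orientation = c("+", "-"),
                                          stringsAsFactors = FALSE)
  plan <- auto_layout(db, config = cfg)
  geom <- compute_geometry(plan, db, config = cfg)
  for (g in plan$genomes) for (s in c("sc1", "sc2")) {
    gn <- geom$genes[geom$genes$genome_id == g & geom$genes$seq_id == s, ]
    feats <- db$features[db$features$genome_id == g & db$features$seq_id == s, ]
    o <- order(feats$start)
    x <- gn$x0[match(feats$gene_id[o], gn$gene_id)]
    orient <- plan$placements[[g]]$orientation[plan$placements[[g]]$seq_id == s]
    if (orient == "+") expect_true(all(diff(x) > 0))
    else expect_true(all(diff(x) < 0))
    # genes stay inside their scaffold's interval
    sc <- geom$scaffolds[geom$scaffolds$genome_id == g &
                           geom$scaffolds$seq_id == s, ]
    expect_true(all(gn$x0 >= sc$x0 - 1e-9 & gn$x1 <= sc$x1 + 1e-9))
  }
  # no NaN and nothing outside the page
  for (col in c("x0", "x1", "y"))
    expect_true(all(is.finite(geom$genes[[col]])))
  expect_true(all(geom$genes$x0 >= -0.1 & geom$genes$x1 <= geom$width))
})

test_that("rendered element counts equal the inputs' counts", {
  w <- sim_world(simulation_params(n_genomes = 4, n_genes = 80,
                                   n_scaffolds = 2, inversions = 1,
                                   translocations = 0, gene_loss = 0,
                                   seed = 62))
  wd <- tempfile()
  res <- run_pipeline(w$spec_path, w$m8_dir, wd)
  inv <- pdf_inventory(res$files$pdf)
  expect_true(inv$valid)
  db <- res$db
  expect_equal(inv$n_rect, nrow(db$features))
  spans <- read_spans(res$files$spans)
  n_adj <- sum(vapply(seq_len(3), function(i)
    nrow(synviz:::spans_between(spans, res$plan$genomes[i],
                                res$plan$genomes[i + 1])), 0L))
  expect_equal(inv$n_polygon, n_adj)
  n_scaffolds <- nrow(db$scaffold_lengths)
  expect_equal(inv$n_segment, 4L + 2L * n_scaffolds)  # tracks + border ticks
  expect_equal(inv$n_text, n_scaffolds + 4L)          # scaffold + isolate labels

  # zero spans: tracks and genes, no ribbons
  geom0 <- compute_geometry(res$plan, db, synviz:::empty_spans())
  f0 <- file.path(wd, "nospans.pdf")
  render_figure(geom0, out_path = f0)
  inv0 <- pdf_inventory(f0)
  expect_true(inv0$valid)
  expect_equal(inv0$n_polygon, 0L)
  expect_equal(inv0$n_rect, nrow(db$features))

  # rendering twice gives the identical element inventory
  f1 <- file.path(wd, "again.pdf")
  geom <- compute_geometry(res$plan, db, spans)
  render_figure(geom, out_path = f1)
  inv1 <- pdf_inventory(f1)
  expect_equal(inv1[c("n_rect", "n_polygon", "n_segment", "n_text")],
               inv[c("n_rect", "n_polygon", "n_segment", "n_text")])
})

test_that("category colors and highlights are validated before drawing", {
  w <- sim_world(simulation_params(n_genomes = 2, n_genes = 10,
                                   n_scaffolds = 1, inversions = 0,
                                   translocations = 0, gene_loss = 0,
                                   seed = 63))
  db <- build_repository_db(w$spec, validate = FALSE)
  plan <- auto_layout(db)
  geom <- compute_geometry(plan, db)
  cfg <- default_figure_config()
  cfg$ribbon_color <- "no-such-color"
  out <- tempfile(fileext = ".pdf")
  expect_error(render_figure(geom, cfg, out), "unresolvable color")
  expect_false(file.exists(out))
})

test_that("scaffold labels carry +/- orientation suffixes and are abbreviated", {
  expect_equal(abbreviate_scaffolds(c("supercontig_5", "scaffold_12", "chr1")),
               c("sc5", "sc12", "chr1"))
  w <- sim_world(simulation_params(n_genomes = 2, n_genes = 12,
                                   n_scaffolds = 2, inversions = 0,
                                   translocations = 0, gene_loss = 0,
                                   seed = 64))
  db <- build_repository_db(w$spec, validate = FALSE)
  cfg <- default_figure_config()
  cfg$scaffold_overrides$G2 <- data.frame(seq_id = c("sc1", "sc2"),
                                          orientation = c("+", "-"),
                                          stringsAsFactors = FALSE)
  plan <- auto_layout(db, config = cfg)
  geom <- compute_geometry(plan, db, config = cfg)
  out <- tempfile(fileext = ".pdf")
  render_figure(geom, cfg, out)
  raw <- readBin(out, "raw", file.info(out)$size)
  txt <- rawToChar(raw[raw != as.raw(0)])
  expect_true(grepl("(sc1+) Tj", txt, fixed = TRUE, useBytes = TRUE))
  expect_true(grepl("(sc2-) Tj", txt, fixed = TRUE, useBytes = TRUE))
})
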