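test_that("read_fasta concatenates wrapped lines and splits header tokens", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "ACGT", "AC"), f)
  rec <- read_fasta(f)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$id, "g1")
  expect_equal(rec$description, "some description")
  expect_equal(rec$residues, "ACGTAC")
})

test_that("read_fasta rejects duplicates, empty files and non-FASTA input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGTT"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c("ACGT"), f)
  expect_error(read_fasta(f), "FASTA")
})

test_that("FASTA round-trips 100 random wrapped records", {
  set.seed(101)
  recs <- random_seq_records(100)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f, width = 60L)
  back <- read_fasta(f)
  expect_equal(back, recs)
})

test_that("read_gff3 maps gene rows and resolves CDS parent chains", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\tsrc\tgene\t100\t400\t.\t+\t.\tID=GA",
    "sc1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=GA.t1;Parent=GA",
    "sc1\tsrc\tCDS\t100\t180\t.\t+\t0\tID=c1;Parent=GA.t1",
    "sc1\tsrc\tCDS\t200\t300\t.\t+\t0\tID=c2;Parent=GA.t1",
    "sc1\tsrc\tCDS\t350\t400\t.\t+\t0\tID=c3;Parent=GA.t1"), f)
  feats <- read_gff3(f, "gnm")
  expect_equal(nrow(feats), 1L)
  expect_equal(feats$gene_id, "GA")
  expect_equal(feats$seq_id, "sc1")
  expect_equal(c(feats$start, feats$end), c(100L, 400L))
  expect_equal(feats$strand, "+")
  expect_equal(feats$genome_id, "gnm")
})

test_that("read_gff3 hard-errors carry line numbers", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("sc1\tsrc\tgene\t500\t400\t.\t+\t.\tID=GA"), f)
  expect_error(read_gff3(f, "g"), "line 1.*end \\(400\\) < start \\(500\\)")
  writeLines(c("sc1\tsrc\tgene\t1\t10\t.\t+\t.\tID=GA", "sc1\tgene\t1\t10"), f)
  expect_error(read_gff3(f, "g"), "line 2.*9 tab-separated")
  writeLines(c("sc1\tsrc\tCDS\t1\t9\t.\t+\t0\tID=c;Parent=nowhere"), f)
  expect_error(read_gff3(f, "g"), "CDS Parent chain")
  writeLines(c("sc1\tsrc\tgene\t1\t9\t.\t+\t.\tID=GA",
               "sc1\tsrc\tgene\t20\t29\t.\t-\t.\tID=GA"), f)
  expect_error(read_gff3(f, "g"), "duplicate gene id")
})

test_that("write_gff3/read_gff3 round-trip equals the simulator truth", {
  w <- sim_world(simulation_params(n_genomes = 2, n_genes = 200,
                                   n_scaffolds = 2, inversions = 1,
                                   translocations = 1, gene_loss = 0.02,
                                   seed = 42))
  fam <- w$ledger$families
  for (i in seq_len(nrow(w$spec))) {
    g <- w$spec$genome_id[i]
    feats <- read_gff3(w$spec$gff[i], g)
    truth <- fam[fam$genome_id == g, ]
    expect_setequal(feats$gene_id, truth$gene_id)
    m <- match(truth$gene_id, feats$gene_id)
    expect_equal(feats$start[m], truth$start)
    expect_equal(feats$end[m], truth$end)
    expect_equal(feats$strand[m], truth$strand)
    expect_equal(feats$seq_id[m], truth$seq_id)
  }
})

test_that("m8 parses scientific e-values and errors on bad column counts", {
  f <- withr::local_tempfile(fileext = ".m8")
  writeLines("gA\tgB\t98.5\t200\t3\t0\t1\t200\t1\t200\t1e-100\t350.0", f)
  h <- read_m8(f)
  expect_equal(h$evalue, 1e-100)
  expect_equal(h$bitscore, 350)
  expect_equal(h$query_id, "gA")
  writeLines(c("a\tb\t1\t1\t1\t1\t1\t1\t1\t1\t1e-5\t50",
               "a\tb\tmissing-columns"), f)
  expect_error(read_m8(f), "line 2.*12 tab-separated")
})

test_that("m8 round-trips 1000 generated records numerically", {
  set.seed(7)
  recs <- random_m8(1000)
  f <- withr::local_tempfile(fileext = ".m8")
  write_m8(recs, f)
  back <- read_m8(f)
  expect_equal(back$query_id, recs$query_id)
  expect_equal(back$evalue, recs$evalue, tolerance = 1e-9)
  expect_equal(back$bitscore, recs$bitscore, tolerance = 1e-9)
  for (col in c("percent_identity", "aln_length", "mismatches", "q_start",
                "q_end", "s_start", "s_end"))
    expect_equal(back[[col]], recs[[col]], tolerance = 1e-9)
  # e-value of 0 survives parse unfloored
  recs0 <- recs[1, ]; recs0$evalue <- 0
  write_m8(recs0, f)
  expect_identical(read_m8(f)$evalue, 0)
})

test_that("Repo_spec preserves entry order and reports missing paths", {
  w <- sim_world(simulation_params(n_genomes = 4, n_genes = 40,
                                   n_scaffolds = 2, inversions = 0,
                                   translocations = 0, gene_loss = 0,
                                   seed = 3))
  spec <- read_repo_spec(w$spec_path)
  expect_s3_class(spec, "repo_spec")
  expect_equal(spec$genome_id, sprintf("G%d", 1:4))

  # single entry parses; the pipeline refuses it
  one <- w$spec[1, ]
  p1 <- file.path(w$dir, "one.txt")
  write_repo_spec(one, p1)
  expect_equal(nrow(read_repo_spec(p1)), 1L)
  expect_error(run_pipeline(p1, w$m8_dir, tempfile()), "at least 2 genomes")

  # a missing pep file is named in the error
  broken <- w$spec
  broken$pep_fasta[2] <- file.path(w$dir, "no-such.pep.fasta")
  pb <- file.path(w$dir, "broken.txt")
  write_repo_spec(broken, pb)
  expect_error(read_repo_spec(pb), "no-such.pep.fasta")

  # duplicate ids rejected
  dup <- rbind(w$spec, w$spec[1, ])
  pd <- file.path(w$dir, "dup.txt")
  write_repo_spec(dup, pd)
  expect_error(read_repo_spec(pd), "duplicate genome id")
})

test_that("aligncoords round-trips: empty, single chain, 20 random chains", {
  f <- withr::local_tempfile()
  write_aligncoords(list(), f)
  expect_equal(read_aligncoords(f), list())

  set.seed(11)
  one <- random_chain(1, n_pairs = 5)
  write_aligncoords(list(one), f)
  expect_equal(length(readLines(f)), 6L)
  back <- read_aligncoords(f)[[1]]
  expect_equal(back$pairs, one$pairs, tolerance = 1e-9)
  for (fld in c("chain_id", "genome_a", "genome_b", "seq_a", "seq_b",
                "orientation"))
    expect_identical(back[[fld]], one[[fld]])
  expect_equal(back$total_score, one$total_score, tolerance = 1e-9)

  chains <- lapply(1:20, random_chain)
  write_aligncoords(chains, f)
  back <- read_aligncoords(f)
  expect_equal(length(back), 20L)
  for (k in seq_along(chains)) {
    expect_equal(back[[k]]$pairs, chains[[k]]$pairs, tolerance = 1e-9)
    expect_equal(back[[k]]$total_score, chains[[k]]$total_score,
                 tolerance = 1e-9)
  }
  # malformed body line
  writeLines(c("## alignment a:s1 vs b:s2 Alignment #1 score = 10 (forward)",
               "s1\tg1\t1"), f)
  expect_error(read_aligncoords(f), "line 2.*9 tab-separated")
})

test_that("spans aggregate min/max bounds and round-trip", {
  p <- data.frame(gene_a = c("a1", "a2"), start_a = c(100L, 900L),
                  end_a = c(400L, 1200L), gene_b = c("b1", "b2"),
                  start_b = c(10L, 60L), end_b = c(50L, 90L),
                  pair_score = c(1, 2))
  ch <- synteny_chain(7L, "A", "B", "s1", "s2", "forward", p, 3)
  sp <- chains_to_spans(list(ch))
  expect_equal(sp$span_a_start, 100L)
  expect_equal(sp$span_a_end, 1200L)
  expect_equal(sp$n_pairs, 2L)

  f <- withr::local_tempfile()
  write_spans(sp, f)
  expect_equal(read_spans(f), sp)
  write_spans(synviz:::empty_spans(), f)
  expect_equal(nrow(read_spans(f)), 0L)
})
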