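# Fixed intermediate file names inside the working directory.
pipeline_files <- function(work_dir) {
  list(validation = file.path(work_dir, "validation.tsv"),
       db_summary = file.path(work_dir, "repo.db_summary"),
       clusters = file.path(work_dir, "clusters.tsv"),
       cluster_summary = file.path(work_dir, "cluster_summary.txt"),
       aligncoords = file.path(work_dir, "aligncoords"),
       spans = file.path(work_dir, "aligncoords.spans"),
       config = file.path(work_dir, "synteny.config"),
       pdf = file.path(work_dir, "synteny.pdf"),
       cache = file.path(work_dir, ".stage_hashes.tsv"))
}

# md5 of a character vector (content hash for cache keys)
sv_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}

stage_hash <- function(input_files, params_string) {
  fh <- vapply(input_files, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else "missing", character(1))
  sv_hash(c(fh, params_string))
}

cache_read <- function(path) {
  if (!file.exists(path)) return(character(0))
  lines <- sv_read_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}

cache_write <- function(path, cache) {
  writeLines(paste(names(cache), cache, sep = "\t"), path)
}

# cached if the recorded hash matches and every output exists
stage_cached <- function(cache, stage, hash, outputs) {
  identical(unname(cache[stage]), unname(hash)) && all(file.exists(outputs))
}

#' Run the full synteny pipeline
#'
#' Executes validate -> build repository db -> cluster (rbh or mcl) ->
#' summarize -> chain -> spans -> auto-layout -> config (generated on the
#' first run, or parsed when one exists) -> render. Every intermediate is
#' written under `work_dir` with a fixed name; clustering and chaining are
#' cached by input-content and parameter hash, so editing the config and
#' re-running only re-renders.
#'
#' @param repo_spec Path to a Repo_spec file, or a `repo_spec` data.frame.
#' @param m8_dir Directory containing the all-vs-all `*.m8` hit tables.
#' @param work_dir Working directory for all outputs.
#' @param clusterer `"rbh"` (reciprocal best hits + single linkage) or
#'   `"mcl"` (Markov clustering of the hit graph).
#' @param inflation MCL inflation (default 1.5; ignored for rbh).
#' @param max_evalue_filter Optional e-value ceiling applied to hits before
#'   RBH best-hit selection (default NULL: no filter).
#' @param params A `chain_params`.
#' @param config Optional path to an edited config file; defaults to
#'   `work_dir/synteny.config` when that exists.
#' @param skip_validate Skip repository validation.
#' @param threads Worker processes for chaining (results identical for any
#'   value).
#' @return list with `files` (all output paths), `stages_run` (names of
#'   stages actually executed), `db`, `plan`, `n_clusters`, `n_chains`.
#' @export
run_pipeline <- function(repo_spec, m8_dir, work_dir,
                         clusterer = c("rbh", "mcl"), inflation = 1.5,
                         max_evalue_filter = NULL,
                         params = chain_params(), config = NULL,
                         skip_validate = FALSE, threads = 1L) {
  clusterer <- match.arg(clusterer)
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_files(work_dir)
  cache <- cache_read(paths$cache)
  stages_run <- character(0)

  spec <- if (is.character(repo_spec)) read_repo_spec(repo_spec) else repo_spec
  if (nrow(spec) < 2L)
    sv_abort("cross-genome pipeline requires at least 2 genomes (got %d)", nrow(spec))

  # --- validate ---------------------------------------------------------
  if (!skip_validate) {
    report <- validate_repository(spec)
    utils::write.table(report, paths$validation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (nrow(report) > 0L) {
      sv_abort("repository validation failed with %d problem(s); see %s (first: genome %s, %s, %s)",
               nrow(report), paths$validation, report$genome_id[1],
               report$check[1], report$detail[1])
    }
    stages_run <- c(stages_run, "validate")
  }

  # --- repository db ----------------------------------------------------
  db <- build_repository_db(spec, validate = FALSE)
  write_db_summary(db, paths$db_summary)
  stages_run <- c(stages_run, "build_db")

  # --- cluster ----------------------------------------------------------
  m8_files <- sort(list.files(m8_dir, pattern = "\\.m8$", full.names = TRUE))
  if (length(m8_files) == 0L)
    sv_abort("no .m8 hit tables found in %s", m8_dir)
  cl_hash <- stage_hash(m8_files, paste(clusterer, inflation,
                                        max_evalue_filter %||% "none"))
  cl_out <- c(paths$clusters, paths$cluster_summary)
  if (stage_cached(cache, "cluster", cl_hash, cl_out)) {
    clusters <- read_clusters(paths$clusters)
    hits <- do.call(rbind, lapply(m8_files, read_m8))
  } else {
    hits <- do.call(rbind, lapply(m8_files, read_m8))
    clusters <- with_cleanup(cl_out, {
      cl <- cluster_hits(hits, db, clusterer, inflation, max_evalue_filter)
      write_clusters(cl, paths$clusters)
      write_cluster_summary(summarize_clusters(cl, db), paths$cluster_summary)
      cl
    })
    cache["cluster"] <- cl_hash
    cache_write(paths$cache, cache)
    stages_run <- c(stages_run, "cluster")
  }

  # --- chain + spans ----------------------------------------------------
  ch_hash <- stage_hash(paths$clusters,
                        paste(params$min_pairs, params$max_gap,
                              params$gap_penalty, params$max_match_score,
                              params$max_evalue))
  ch_out <- c(paths$aligncoords, paths$spans)
  if (stage_cached(cache, "chain", ch_hash, ch_out)) {
    spans <- read_spans(paths$spans)
  } else {
    spans <- with_cleanup(ch_out, {
      chains <- chain_all_pairs(clusters, db, params, hits, threads)
      write_aligncoords(chains, paths$aligncoords)
      sp <- chains_to_spans(chains)
      write_spans(sp, paths$spans)
      sp
    })
    cache["chain"] <- ch_hash
    cache_write(paths$cache, cache)
    stages_run <- c(stages_run, "chain")
  }

  # --- layout + config --------------------------------------------------
  config_path <- config %||% (if (file.exists(paths$config)) paths$config else NULL)
  if (!is.null(config_path)) {
    cfg <- parse_config(config_path, db = db)
    plan <- auto_layout(db, spans, config = cfg)
    stages_run <- c(stages_run, "layout")
  } else {
    cfg <- default_figure_config()
    plan <- auto_layout(db, spans, config = cfg)
    write_config(plan, paths$config, cfg)
    stages_run <- c(stages_run, "layout", "generate_config")
  }

  # --- render -----------------------------------------------------------
  with_cleanup(paths$pdf, {
    geom <- compute_geometry(plan, db, spans, cfg)
    render_figure(geom, cfg, paths$pdf)
  })
  stages_run <- c(stages_run, "render")

  list(files = paths, stages_run = stages_run, db = db, plan = plan,
       n_clusters = if (nrow(clusters) > 0) length(unique(clusters$cluster_id)) else 0L,
       n_chains = nrow(spans))
}

# run expr; on error remove the stage's partially written outputs and re-raise
with_cleanup <- function(outputs, expr) {
  tryCatch(expr, error = function(e) {
    unlink(outputs[file.exists(outputs)])
    stop(e)
  })
}

cluster_hits <- function(hits, db, clusterer, inflation = 1.5,
                         max_evalue_filter = NULL) {
  if (identical(clusterer, "rbh")) {
    if (!is.null(max_evalue_filter))
      hits <- hits[hits$evalue <= max_evalue_filter, , drop = FALSE]
    best <- best_hits(hits, db$gene_genome)
    single_linkage_clusters(reciprocal_best_hits(best))
  } else {
    mcl_clusters(build_hit_graph(hits), db$gene_genome, inflation = inflation)
  }
}

# chain every unordered genome pair in Repo_spec order; global chain ids
chain_all_pairs <- function(clusters, db, params, hits, threads = 1L) {
  genomes <- db$spec$genome_id
  chains <- list()
  next_id <- 1L
  for (i in seq_len(length(genomes) - 1L)) {
    for (j in (i + 1L):length(genomes)) {
      matches <- build_matches(clusters, db, genomes[i], genomes[j],
                               params, hits)
      cs <- partition_and_chain(matches, params, genomes[i], genomes[j],
                                first_id = next_id, threads = threads)
      next_id <- next_id + length(cs)
      chains <- c(chains, cs)
    }
  }
  chains
}

#' Run one pipeline stage in isolation
#'
#' Each stage consumes the previous stage's file outputs, so externally
#' produced files (for instance hand-written aligncoords) can enter the
#' pipeline at any point.
#'
#' @param name One of `"validate"`, `"simulate"`, `"cluster"`, `"chain"`,
#'   `"layout"`, `"render"`.
#' @param repo_spec Path to a Repo_spec (all stages except simulate).
#' @param work_dir Working directory holding the fixed-name intermediates.
#' @param m8_dir Hit-table directory (cluster stage; chain uses it for
#'   e-value evidence when present).
#' @param sim_params A `sim_params` (simulate stage).
#' @param clusterer,inflation,max_evalue_filter,params,config,threads As in
#'   [run_pipeline()].
#' @return Stage-dependent value, invisibly.
#' @export
run_stage <- function(name, repo_spec = NULL, work_dir = ".", m8_dir = NULL,
                      sim_params = simulation_params(),
                      clusterer = "rbh", inflation = 1.5,
                      max_evalue_filter = NULL, params = chain_params(),
                      config = NULL, threads = 1L) {
  paths <- pipeline_files(work_dir)
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(f, what) {
    if (!file.exists(f)) sv_abort("%s stage: missing expected input %s", what, f)
    f
  }
  switch(
    name,
    simulate = {
      sim <- simulate_repository(sim_params, work_dir)
      simulate_hits(sim$ledger, file.path(work_dir, "m8"))
      invisible(sim)
    },
    validate = {
      spec <- read_repo_spec(need(repo_spec, "validate"))
      report <- validate_repository(spec)
      utils::write.table(report, paths$validation, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      if (nrow(report) > 0L)
        sv_abort("repository validation failed with %d problem(s); see %s",
                 nrow(report), paths$validation)
      invisible(report)
    },
    cluster = {
      spec <- read_repo_spec(need(repo_spec, "cluster"))
      db <- build_repository_db(spec)
      m8_files <- sort(list.files(need(m8_dir, "cluster"), pattern = "\\.m8$",
                                  full.names = TRUE))
      if (length(m8_files) == 0L) sv_abort("cluster stage: no .m8 files in %s", m8_dir)
      hits <- do.call(rbind, lapply(m8_files, read_m8))
      cl <- cluster_hits(hits, db, clusterer, inflation, max_evalue_filter)
      write_clusters(cl, paths$clusters)
      write_cluster_summary(summarize_clusters(cl, db), paths$cluster_summary)
      invisible(cl)
    },
    chain = {
      spec <- read_repo_spec(need(repo_spec, "chain"))
      db <- build_repository_db(spec)
      clusters <- read_clusters(need(paths$clusters, "chain"))
      hits <- NULL
      if (!is.null(m8_dir)) {
        m8_files <- sort(list.files(m8_dir, pattern = "\\.m8$", full.names = TRUE))
        if (length(m8_files) > 0L) hits <- do.call(rbind, lapply(m8_files, read_m8))
      }
      chains <- chain_all_pairs(clusters, db, params, hits, threads)
      write_aligncoords(chains, paths$aligncoords)
      write_spans(chains_to_spans(chains), paths$spans)
      invisible(chains)
    },
    layout = {
      spec <- read_repo_spec(need(repo_spec, "layout"))
      db <- build_repository_db(spec)
      spans <- read_spans(need(paths$spans, "layout"))
      cfg <- if (!is.null(config)) parse_config(config, db = db) else default_figure_config()
      plan <- auto_layout(db, spans, config = cfg)
      write_config(plan, paths$config, cfg)
      invisible(plan)
    },
    render = {
      spec <- read_repo_spec(need(repo_spec, "render"))
      db <- build_repository_db(spec)
      spans <- if (file.exists(paths$spans)) read_spans(paths$spans)
      else chains_to_spans(read_aligncoords(need(paths$aligncoords, "render")))
      cfg_path <- config %||% (if (file.exists(paths$config)) paths$config else NULL)
      cfg <- if (!is.null(cfg_path)) parse_config(cfg_path, db = db) else default_figure_config()
      plan <- auto_layout(db, spans, config = cfg)
      geom <- compute_geometry(plan, db, spans, cfg)
      render_figure(geom, cfg, paths$pdf)
      invisible(paths$pdf)
    },
    sv_abort("unknown stage: %s", name))
}
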