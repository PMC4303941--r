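#' Pipeline configuration
#'
#' Validated, fully serializable configuration for [run_pipeline()]. Input is
#' either a directory of per-volunteer presence TSVs or (default) a synthetic
#' [cohort_design()]. A single global seed is fanned out to per-stage seeds
#' by stable hashing of the stage names.
#'
#' @param input_dir Optional directory of presence matrices (one TSV per
#'   volunteer). When `NULL`, a synthetic cohort is generated from `design`.
#' @param design A [cohort_design()] for synthetic input.
#' @param mode `"mean-volunteer"` (average detections across volunteers) or
#'   `"single-volunteer"` (one joint SOM over all volunteer-week states).
#' @param centralize Train the main SOM on delta-E profiles (default TRUE).
#' @param som A [som_params()].
#' @param spot_mode `"union"` or `"averaged"` (see
#'   [select_percentile_spots()]).
#' @param percentile Spot selection percentile.
#' @param gene_sets Optional GMT path or `gene_set_collection`; defaults to
#'   sets derived from the synthetic ground truth.
#' @param pathways Optional list of KGML paths or `pathway_graph`s; defaults
#'   to demo pathways built from the synthetic ground truth.
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param portraits Write the per-sample portrait gallery (PNG) — slowest
#'   purely cosmetic step; disable for programmatic runs.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, design = cohort_design(),
                            mode = c("mean-volunteer", "single-volunteer"),
                            centralize = TRUE, som = som_params(),
                            spot_mode = c("union", "averaged"), percentile = 2,
                            gene_sets = NULL, pathways = NULL,
                            out_dir = tempfile("somscape_run_"), seed = 1,
                            portraits = FALSE) {
  mode <- match.arg(mode)
  spot_mode <- match.arg(spot_mode)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(sprintf("input_dir does not exist: %s", input_dir))
  }
  stopifnot(inherits(som, "som_params"))
  structure(
    list(input_dir = input_dir, design = design, mode = mode,
         centralize = centralize, som = som, spot_mode = spot_mode,
         percentile = percentile, gene_sets = gene_sets, pathways = pathways,
         out_dir = out_dir, seed = as.integer(seed), portraits = portraits),
    class = "pipeline_config"
  )
}

pipeline_stages <- function() {
  c("simulate", "preprocess", "som", "spots", "trajectories", "network",
    "enrichment", "psf", "abundance")
}

#' Gene sets derived from synthetic ground truth
#'
#' One set per planted module plus the invariant-high and invariant-low
#' groups, usable as a positive-control gene-set collection.
#'
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @return A `gene_set_collection`.
#' @export
truth_gene_sets <- function(truth) {
  labs <- unique(truth$label[truth$label != "spiked"])
  sets <- lapply(labs, function(l) truth$protein[truth$label == l])
  names(sets) <- paste0("set_", labs)
  gene_set_collection(sets)
}

#' Demo pathways over synthetic module proteins
#'
#' Two small signed DAGs whose node members are planted-module proteins:
#' an activation chain early -> intermediate -> late, and a branched pathway
#' in which the late module inhibits a sink fed by the early module. Their
#' PSF time profiles therefore track the planted wave profiles.
#'
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @param per_node Proteins per node (default 10).
#' @return Named list of `pathway_graph`s.
#' @export
demo_pathways <- function(truth, per_node = 10) {
  pick <- function(label) utils::head(truth$protein[truth$label == label], per_node)
  chain <- pathway_from_edges(
    tibble(src = c("early", "intermediate"), dst = c("intermediate", "late"),
           type = "activation"),
    members = list(early = pick("M01"), intermediate = pick("M06"),
                   late = pick("M09")),
    name = "demo_activation_chain"
  )
  branched <- pathway_from_edges(
    tibble(src = c("early", "late_ctrl", "early"),
           dst = c("response", "response", "late_ctrl"),
           type = c("activation", "inhibition", "activation")),
    members = list(early = pick("M02"), late_ctrl = pick("M08"),
                   response = pick("M05")),
    name = "demo_branched_inhibition"
  )
  list(demo_activation_chain = chain, demo_branched_inhibition = branched)
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

cache_save <- function(config, name, value) {
  dir.create(stage_path(config, "cache"), recursive = TRUE, showWarnings = FALSE)
  saveRDS(value, stage_path(config, "cache", paste0(name, ".rds")))
  value
}

cache_load <- function(config, name) {
  p <- stage_path(config, "cache", paste0(name, ".rds"))
  if (!file.exists(p)) {
    abort(sprintf("missing upstream artifact '%s' (expected %s); run earlier stages first",
                  name, p))
  }
  readRDS(p)
}

save_plot <- function(plot, path, width = 5, height = 4) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
  path
}

stage_simulate <- function(config) {
  files <- character(0)
  if (is.null(config$input_dir)) {
    cohort <- generate_cohort(config$design, seed = derive_seed(config$seed, "simulate"))
    f <- stage_path(config, "ground_truth.tsv")
    export_ground_truth(cohort$truth, f)
    files <- f
  } else {
    paths <- sort(list.files(config$input_dir, pattern = "\\.(tsv|csv)$",
                             full.names = TRUE))
    if (!length(paths)) abort("no presence matrices found in input_dir")
    cohort <- list(
      volunteers = lapply(paths, read_presence_matrix),
      truth = NULL, design = NULL
    )
  }
  cache_save(config, "cohort", cohort)
  list(result = cohort, files = files)
}

stage_preprocess <- function(config) {
  cohort <- cache_load(config, "cohort")
  mean_mat <- build_mean_volunteer(cohort$volunteers)
  delta <- centralize(mean_mat)
  if (config$mode == "single-volunteer") {
    blocks <- lapply(cohort$volunteers, function(v) v$values)
    proteins <- rownames(mean_mat$values)
    blocks <- lapply(cohort$volunteers, function(v) {
      m <- matrix(0, length(proteins), ncol(v$values),
                  dimnames = list(proteins, NULL))
      m[rownames(v$values), ] <- v$values
      m
    })
    states <- do.call(cbind, blocks)
    samples <- dplyr::bind_rows(lapply(cohort$volunteers, function(v) {
      tibble(volunteer = v$volunteer_id, week = v$weeks)
    }))
    train_mat <- new_abundance_matrix(states, samples$week)
  } else {
    samples <- tibble(volunteer = "mean", week = mean_mat$weeks)
    train_mat <- mean_mat
  }
  res <- list(mean_matrix = mean_mat, delta = delta, train_matrix = train_mat,
              samples = samples)
  cache_save(config, "preprocess", res)
  list(result = res, files = character(0))
}

stage_som <- function(config) {
  pre <- cache_load(config, "preprocess")
  train_input <- if (config$centralize) centralize(pre$train_matrix) else pre$train_matrix
  model <- train_som(train_input, config$som)
  # separate training on absolute values for the total-abundance analysis
  model_abs <- train_som(pre$train_matrix, config$som)
  pop <- population_map(model)
  f_pop <- stage_path(config, "population_map.tsv")
  utils::write.table(pop, f_pop, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- f_pop
  if (isTRUE(config$portraits)) {
    gallery <- stage_path(config, "portraits")
    dir.create(gallery, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_len(ncol(model$codes))) {
      fn <- file.path(gallery, sprintf("portrait_%02d_%s_wk%+03d.png", s,
                                       pre$samples$volunteer[s],
                                       pre$samples$week[s]))
      save_plot(autoplot(render_portrait(model, s)), fn, width = 4, height = 4)
      files <- c(files, fn)
    }
  }
  res <- list(model = model, model_abs = model_abs)
  cache_save(config, "som", res)
  list(result = res, files = files)
}

stage_spots <- function(config) {
  som <- cache_load(config, "som")
  spots <- select_percentile_spots(som$model, mode = config$spot_mode,
                                   percentile = config$percentile)
  sm <- summary_map(spots, som$model)
  f1 <- stage_path(config, "spots.tsv")
  write_spot_table(spots, f1)
  f2 <- stage_path(config, "summary_map.tsv")
  utils::write.table(sm, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- stage_path(config, "summary_map.png")
  save_plot(plot_summary_map(sm), f3)
  cache_save(config, "spots", spots)
  list(result = spots, files = c(f1, f2, f3))
}

stage_trajectories <- function(config) {
  som <- cache_load(config, "som")
  pre <- cache_load(config, "preprocess")
  seed <- derive_seed(config$seed, "trajectories")
  traj <- second_level_som(som$model, weeks = pre$samples$week, seed = seed)
  traj <- segment_trajectory(traj, k = 3, seed = seed)
  ica <- tryCatch(
    segment_trajectory(ica_projection(som$model, weeks = pre$samples$week,
                                      seed = seed), k = 3, seed = seed),
    error = function(e) NULL
  )
  f1 <- stage_path(config, "trajectory_som2.tsv")
  write_trajectory(traj, f1)
  f2 <- stage_path(config, "trajectory_som2.png")
  save_plot(autoplot(traj), f2)
  files <- c(f1, f2)
  if (!is.null(ica)) {
    f3 <- stage_path(config, "trajectory_ica.tsv")
    write_trajectory(ica, f3)
    files <- c(files, f3)
  }
  res <- list(som2 = traj, ica = ica)
  cache_save(config, "trajectories", res)
  list(result = res, files = files)
}

stage_network <- function(config) {
  som <- cache_load(config, "som")
  spots <- cache_load(config, "spots")
  edges <- dplyr::bind_rows(
    spot_wto_network(spots, wto_scores(som$model, "positive"), "positive"),
    spot_wto_network(spots, wto_scores(som$model, "negative"), "negative")
  )
  betas <- beta_test(spots, som$model,
                     seed = derive_seed(config$seed, "network"))
  f1 <- stage_path(config, "wto_edges.tsv")
  utils::write.table(edges, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- stage_path(config, "beta_results.tsv")
  utils::write.table(betas, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- list(edges = edges, beta = betas)
  cache_save(config, "network", res)
  list(result = res, files = c(f1, f2))
}

stage_enrichment <- function(config) {
  spots <- cache_load(config, "spots")
  pre <- cache_load(config, "preprocess")
  cohort <- cache_load(config, "cohort")
  gsc <- config$gene_sets
  if (is.character(gsc)) gsc <- read_gene_sets(gsc)
  if (is.null(gsc)) {
    if (is.null(cohort$truth)) abort("no gene sets configured and no ground truth available")
    gsc <- truth_gene_sets(cohort$truth)
  }
  res <- enrich_spots(spots, gsc, pre$delta)
  f1 <- stage_path(config, "enrichment.tsv")
  utils::write.table(res, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- f1
  hm <- tryCatch(enrichment_heatmap(res, spots), error = function(e) NULL)
  if (!is.null(hm)) {
    f2 <- stage_path(config, "enrichment_heatmap.tsv")
    write_enrichment_heatmap(hm, f2)
    f3 <- stage_path(config, "enrichment_heatmap.png")
    save_plot(autoplot(hm), f3, width = 7, height = 5)
    files <- c(files, f2, f3)
  }
  cache_save(config, "enrichment", res)
  list(result = res, files = files)
}

stage_psf <- function(config) {
  pre <- cache_load(config, "preprocess")
  spots <- cache_load(config, "spots")
  cohort <- cache_load(config, "cohort")
  pw <- config$pathways
  if (is.null(pw)) {
    if (is.null(cohort$truth)) abort("no pathways configured and no ground truth available")
    pw <- demo_pathways(cohort$truth)
  }
  pw <- lapply(pw, function(p) if (is.character(p)) parse_kgml(p) else p)
  profiles <- dplyr::bind_rows(lapply(names(pw), function(nm) {
    dplyr::mutate(psf_time_profiles(pw[[nm]], pre$mean_matrix),
                  pathway = nm, .before = 1)
  }))
  # single-volunteer spot profiles span (volunteer, week) states; average
  # duplicate weeks so they live on the mean-volunteer grid for matching
  spots_match <- spots
  spots_match$profile <- lapply(spots$profile, function(p) {
    wk <- factor(as.integer(names(p)), levels = sort(unique(as.integer(names(p)))))
    agg <- tapply(p, wk, mean)
    stats::setNames(as.numeric(agg), names(agg))
  })
  matches <- dplyr::bind_rows(lapply(names(pw), function(nm) {
    prof <- profiles[profiles$pathway == nm, ]
    dplyr::mutate(match_profiles(prof, spots_match), pathway = nm, .before = 1)
  }))
  f1 <- stage_path(config, "psf_profiles.tsv")
  utils::write.table(profiles, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- stage_path(config, "psf_matches.tsv")
  utils::write.table(matches, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- list(profiles = profiles, matches = matches)
  cache_save(config, "psf", res)
  list(result = res, files = c(f1, f2))
}

stage_abundance <- function(config) {
  som <- cache_load(config, "som")
  vp <- variance_profile(som$model_abs)
  peaks <- detect_peaks(vp, min_separation = 3)
  f1 <- stage_path(config, "variance_profile.tsv")
  utils::write.table(vp, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- stage_path(config, "variance_profile.png")
  save_plot(plot_variance_profile(vp, peaks), f2)
  res <- list(profile = vp, peaks = peaks)
  cache_save(config, "abundance", res)
  list(result = res, files = c(f1, f2))
}

stage_fn <- function(stage) {
  switch(stage,
    simulate = stage_simulate, preprocess = stage_preprocess, som = stage_som,
    spots = stage_spots, trajectories = stage_trajectories,
    network = stage_network, enrichment = stage_enrichment, psf = stage_psf,
    abundance = stage_abundance,
    abort(sprintf("unknown stage '%s'; stages are: %s", stage,
                  paste(pipeline_stages(), collapse = ", ")))
  )
}

#' Run the full portrait pipeline
#'
#' Executes all nine stages — simulate (or load), preprocess, som, spots,
#' trajectories, network, enrichment, psf, abundance — writing tables,
#' figures, per-stage caches and a machine-readable manifest under
#' `config$out_dir`. A failing stage aborts with the stage named; partial
#' outputs are retained. Identical seed and config give identical numeric
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of stage results; the manifest is written
#'   to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list()
  for (stage in pipeline_stages()) {
    t0 <- Sys.time()
    out <- tryCatch(stage_fn(stage)(config), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[somscape] stage %-12s %6.1fs  %d file(s)", stage, elapsed,
                    length(out$files)))
    results[[stage]] <- out$result
    manifest[[stage]] <- list(
      files = as.list(basename(out$files)),
      md5 = as.list(unname(tools::md5sum(out$files))),
      seconds = round(elapsed, 2)
    )
  }
  meta <- list(
    package = "somscape",
    seed = config$seed, mode = config$mode,
    grid = c(config$som$rows, config$som$cols),
    stages = manifest
  )
  jsonlite::write_json(meta, stage_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Re-run a single pipeline stage from cached inputs
#'
#' @param config The `pipeline_config` of an existing run.
#' @param stage Stage name (see [run_pipeline()]).
#' @return The stage result, invisibly.
#' @export
run_stage <- function(config, stage) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- stage_fn(stage)(config)
  invisible(out$result)
}
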