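#' Experiment configuration
#'
#' Builds (or completes) the structured configuration driving
#' [run_experiment()]. All random stages draw their seeds from the root
#' `seed` with fixed per-stage offsets (trains +1, spine placement +2,
#' mapping +3, variability +4, inhibition +5), recorded in the manifest.
#'
#' @param kind one of `"single_trial"`, `"variability_sweep"`,
#'   `"cluster_sweep"`, `"shuffle_control"`
#' @param seed root integer seed (mandatory)
#' @param ... named sections overriding the defaults: `trains`,
#'   `experiment`, `morphology`, `spines`, `cluster`, `variability`,
#'   `neuron`, `calcium`, `plasticity`, `sim`, `analysis`, `out_dir`
#' @return a list of class `experiment_config`
#' @export
experiment_config <- function(kind = c("single_trial", "variability_sweep",
                                       "cluster_sweep", "shuffle_control"),
                              seed, ...) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is a mandatory field of experiment_config")
  cfg <- list(
    kind = kind, seed = as.integer(seed), out_dir = NULL,
    trains = list(n_trains = 50, trial_duration = 1, rate_median = 4,
                  rate_sdlog = 0.8, ramp_peak = 2.5, mod_sd = 0.5,
                  mod_tau = 0.1),
    experiment = list(n_trials = 10, intertrial_interval = 1, lead_in = 1),
    morphology = list(n_primary = 4, segments_per_branch = 8,
                      seg_length = 16, split_after = 2, n_secondary = 2),
    spines = list(density = 0.1, min_distance = 25, cluster_density = 0.75,
                  cluster_total_um = 200),
    cluster = list(spines_per_cluster = c(1, 2, 5, 10, 20),
                   cluster_length = c(5, 10, 20, 40, 80), n_mappings = 5),
    variability = list(kind = "jitter", sigmas = c(0, 0.01, 0.1),
                       p_moves = c(0.1, 0.5, 1.0)),
    shuffle = list(train_scale = 1.3),
    neuron = list(), calcium = list(), plasticity = list(),
    sim = list(dt = 0.025, w0 = 1),
    analysis = list(k_neighbors = 19, n_bins = 7, sigma = 0.05,
                    grid_dt = 0.01, n_sets = 5, n_repeats = 4,
                    num_trees = 500))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("experiment_config", "list"))
}

#' Read / write an experiment configuration as YAML
#' @param path file path
#' @param cfg an `experiment_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$kind)) stop("config missing required key: kind")
  if (is.null(y$seed)) stop("config missing required key: seed")
  do.call(experiment_config,
          c(list(kind = y$kind, seed = y$seed),
            y[setdiff(names(y), c("kind", "seed"))]))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Select distal segments for high-density clustered spine placement
#'
#' Returns the ids of distal dendritic segments accumulating roughly
#' `total_um` of dendrite, used as the placement subset for clustered-input
#' experiments.
#'
#' @param morph a `morphology`
#' @param total_um target dendritic length (µm)
#' @return integer segment ids
#' @export
select_cluster_segments <- function(morph, total_um = 200) {
  dend <- morph[-1, ]
  ord <- order(-dend$segment_id)
  keep <- ord[cumsum(dend$length_um[ord]) <= total_um + 1e-9]
  sort(dend$segment_id[keep])
}

# assemble the model objects shared by all experiment kinds
.pipeline_setup <- function(cfg) {
  m <- do.call(build_default_morphology, cfg$morphology)
  clustered <- cfg$kind %in% c("cluster_sweep", "shuffle_control")
  sp <- if (clustered)
    place_spines(m, density_per_um = cfg$spines$cluster_density,
                 min_distance_um = cfg$spines$min_distance,
                 seed = cfg$seed + 2L,
                 segments = select_cluster_segments(
                   m, cfg$spines$cluster_total_um))
  else place_spines(m, density_per_um = cfg$spines$density,
                    min_distance_um = cfg$spines$min_distance,
                    seed = cfg$seed + 2L)
  npar <- do.call(neuron_params, cfg$neuron)
  cpar <- do.call(calcium_params, cfg$calcium)
  ppar <- do.call(plasticity_params, cfg$plasticity)
  list(morph = m, spines = sp, neuron = npar, calcium = cpar,
       plasticity = ppar)
}

.make_trains <- function(cfg, seed_offset = 1L) {
  spec <- do.call(rate_ensemble_spec,
                  c(cfg$trains, list(seed = cfg$seed + seed_offset)))
  generate_correlated_trains(spec)
}

#' Run a configured experiment end to end
#'
#' Executes generate -> map -> simulate (voltage, calcium, weights) ->
#' analyze for the configured experiment kind, returning all result tables;
#' with `cfg$out_dir` set, also writes CSV tables and a JSON manifest
#' (config, seeds, package version).
#'
#' Kinds: `single_trial` simulates one trial on a random (1-per-cluster)
#' mapping; `variability_sweep` repeats 10 trials at each jitter SD (or
#' move probability) and tabulates per-synapse cumulative weight changes;
#' `cluster_sweep` simulates one trial per cluster mapping across the
#' configured spines-per-cluster / cluster-length grid and fits the
#' weight-change regressions; `shuffle_control` is the cluster sweep with
#' ISI-shuffled trains (train count scaled by `cfg$shuffle$train_scale`).
#'
#' @param cfg an [experiment_config()] or path to a YAML config
#' @return a list of class `experiment_result` (contents depend on kind)
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "experiment_config"))
  setup <- .pipeline_setup(cfg)
  res <- switch(cfg$kind,
    single_trial = .run_single_trial(cfg, setup),
    variability_sweep = .run_variability_sweep(cfg, setup),
    cluster_sweep = .run_cluster_sweep(cfg, setup, shuffle = FALSE),
    shuffle_control = .run_cluster_sweep(cfg, setup, shuffle = TRUE))
  res$config <- cfg
  res$kind <- cfg$kind
  class(res) <- c("experiment_result", "list")
  if (!is.null(cfg$out_dir)) write_experiment_results(res, cfg$out_dir)
  res
}

.random_mapping <- function(setup, n_trains, seed) {
  cc <- cluster_config(1, 0, seed = seed)
  assign_clusters(setup$morph, setup$spines, n_trains, cc)
}

.run_single_trial <- function(cfg, setup) {
  trial <- .make_trains(cfg)
  n_tr <- min(length(trial$times), nrow(setup$spines))
  mapping <- .random_mapping(setup, n_tr, cfg$seed + 3L)
  ex <- build_experiment(trial, n_trials = 1,
                         intertrial_interval = cfg$experiment$intertrial_interval,
                         lead_in = cfg$experiment$lead_in)
  sim <- simulate_experiment(ex, setup$morph, setup$spines, mapping,
                             setup$neuron, setup$calcium, setup$plasticity,
                             dt = cfg$sim$dt, seed = cfg$seed + 5L,
                             w0 = cfg$sim$w0)
  dw_tab <- data.frame(spine_id = setup$spines$spine_id,
                       dw = sim$dw[, 1], w_end = sim$w_final)
  list(sim = sim, mapping = mapping, dw_table = dw_tab,
       spines = setup$spines, morph = setup$morph)
}

.run_variability_sweep <- function(cfg, setup) {
  trial <- .make_trains(cfg)
  n_tr <- min(length(trial$times), nrow(setup$spines))
  mapping <- .random_mapping(setup, n_tr, cfg$seed + 3L)
  vkind <- cfg$variability$kind
  levels_ <- if (vkind == "jitter") cfg$variability$sigmas
             else cfg$variability$p_moves
  sims <- list(); rows <- list()
  for (i in seq_along(levels_)) {
    lv <- levels_[i]
    vs <- if (vkind == "jitter")
      variability_spec("jitter", sigma = lv, seed = cfg$seed + 4L)
    else variability_spec("move", p_move = lv, seed = cfg$seed + 4L)
    ex <- build_experiment(trial, n_trials = cfg$experiment$n_trials,
                           intertrial_interval = cfg$experiment$intertrial_interval,
                           lead_in = cfg$experiment$lead_in,
                           variability = vs)
    sim <- simulate_experiment(ex, setup$morph, setup$spines, mapping,
                               setup$neuron, setup$calcium,
                               setup$plasticity, dt = cfg$sim$dt,
                               seed = cfg$seed + 5L, w0 = cfg$sim$w0)
    sims[[i]] <- sim
    rows[[i]] <- data.frame(level = lv, spine_id = setup$spines$spine_id,
                            dw_total = rowSums(sim$dw),
                            w_end = sim$w_final,
                            pre_count = .mapped_counts(sim, setup$spines))
  }
  tab <- do.call(rbind, rows)
  # correlation of ending weight with variability, split by direction at
  # the lowest variability level
  base <- rows[[1]]
  dep <- base$spine_id[base$dw_total < -0.01]
  pot <- base$spine_id[base$dw_total > 0.01]
  cor_dep <- if (length(dep) >= 2 && length(levels_) >= 2)
    correlate(tab$level[tab$spine_id %in% dep],
              tab$w_end[tab$spine_id %in% dep]) else NULL
  cor_pot <- if (length(pot) >= 2 && length(levels_) >= 2)
    correlate(tab$level[tab$spine_id %in% pot],
              tab$w_end[tab$spine_id %in% pot]) else NULL
  list(sims = sims, levels = levels_, mapping = mapping, dw_table = tab,
       cor_depressing = cor_dep, cor_potentiating = cor_pot,
       spines = setup$spines, morph = setup$morph)
}

.mapped_counts <- function(sim, spines) {
  cnt <- integer(nrow(spines))
  tt <- experiment_train_times(sim$experiment)
  rows <- match(sim$mapping$spine_id, spines$spine_id)
  cnt[rows] <- vapply(tt[sim$mapping$train_id], length, 1L)
  cnt
}

.run_cluster_sweep <- function(cfg, setup, shuffle = FALSE) {
  tr_cfg <- cfg$trains
  if (shuffle)
    tr_cfg$n_trains <- round(tr_cfg$n_trains * cfg$shuffle$train_scale)
  spec <- do.call(rate_ensemble_spec,
                  c(tr_cfg, list(seed = cfg$seed + 1L)))
  trial <- generate_correlated_trains(spec)
  if (shuffle) trial <- shuffle_isis(trial, seed = cfg$seed + 6L)
  n_tr <- min(length(trial$times), nrow(setup$spines))
  ex <- build_experiment(trial, n_trials = 1,
                         intertrial_interval = cfg$experiment$intertrial_interval,
                         lead_in = cfg$experiment$lead_in)
  grid <- data.frame(spc = cfg$cluster$spines_per_cluster,
                     len = cfg$cluster$cluster_length)
  dmat <- spine_distance_matrix(setup$morph, setup$spines)
  sims <- list(); cfg_rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    cc <- cluster_config(grid$spc[g], grid$len[g],
                         n_mappings = cfg$cluster$n_mappings,
                         seed = cfg$seed + 3L + 100L * g)
    maps <- assign_cluster_mappings(setup$morph, setup$spines, n_tr, cc,
                                    dmat = dmat)
    for (mp in maps) {
      idx <- idx + 1L
      sims[[idx]] <- simulate_experiment(
        ex, setup$morph, setup$spines, mp, setup$neuron, setup$calcium,
        setup$plasticity, dt = cfg$sim$dt, seed = cfg$seed + 5L + idx,
        w0 = cfg$sim$w0)
      cfg_rows[[idx]] <- data.frame(sim = idx, spc = grid$spc[g],
                                    len = grid$len[g])
    }
  }
  an <- cfg$analysis
  ft <- build_feature_table(sims, setup$morph, dmat = dmat,
                            k_neighbors = an$k_neighbors,
                            sigma = an$sigma, grid_dt = an$grid_dt)
  list(sims = sims, sim_grid = do.call(rbind, cfg_rows),
       feature_table = ft, dmat = dmat, spines = setup$spines,
       morph = setup$morph, trial = trial)
}

#' Fit the standard weight-change regressions on a feature table
#'
#' Runs the random-forest comparisons used in the cluster analyses:
#' calcium time samples (1/3/5), direct firing-rate time samples (1/3/5),
#' and rate plus one spatial feature, with the ANOVA across feature sets.
#'
#' @param ft feature table from [build_feature_table()]
#' @param cfg an [experiment_config()] (for rf hyperparameters and seed)
#' @return list with `results` (per feature set: rf_predict output),
#'   `scores` (tidy data.frame), `anova_ca`, `anova_spatial`
#' @export
fit_weight_change_regressions <- function(ft, cfg) {
  an <- cfg$analysis
  sets <- list(
    ca_1 = "ca1", ca_3 = paste0("ca3_", 1:3), ca_5 = paste0("ca5_", 1:5),
    rate_1 = "rate1", rate_3 = paste0("rate3_", 1:3),
    rate_5 = paste0("rate5_", 1:5),
    rate_1_clust = c("rate1", "cluster_length"),
    rate_3_clust = c(paste0("rate3_", 1:3), "cluster_length"),
    rate_1_spc = c("rate1", "spines_per_cluster"),
    rate_1_dist = c("rate1", "dist_soma"),
    rate_1_nb = c("rate1", "nb1"))
  results <- lapply(seq_along(sets), function(i)
    rf_predict(ft, sets[[i]], n_sets = an$n_sets, n_repeats = an$n_repeats,
               seed = cfg$seed + 7L + i, num_trees = an$num_trees))
  names(results) <- names(sets)
  scores <- do.call(rbind, lapply(names(sets), function(nm)
    data.frame(set = nm, r2 = results[[nm]]$scores)))
  g_ca <- scores[scores$set %in% c("ca_1", "ca_3", "ca_5"), ]
  g_sp <- scores[scores$set %in% c("rate_1", "rate_1_clust", "rate_1_spc",
                                   "rate_1_dist"), ]
  list(results = results, scores = scores,
       anova_ca = compare_feature_sets(g_ca$r2, g_ca$set),
       anova_spatial = compare_feature_sets(g_sp$r2, g_sp$set))
}

#' Write experiment results to a directory
#'
#' CSV tables plus a JSON manifest recording the configuration, the seed
#' lineage and the package version. Re-running the same configuration
#' reproduces the tables bit-identically.
#'
#' @param res an `experiment_result`
#' @param out_dir output directory (created if needed)
#' @export
write_experiment_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, nm)
    utils::write.csv(df, file.path(out_dir, nm), row.names = FALSE)
  if (!is.null(res$dw_table)) w(res$dw_table, "dw_table.csv")
  if (!is.null(res$feature_table)) w(res$feature_table, "feature_table.csv")
  if (!is.null(res$sim_grid)) w(res$sim_grid, "sim_grid.csv")
  cfg <- unclass(res$config)
  manifest <- list(
    kind = res$kind, config = cfg,
    seed_lineage = list(root = cfg$seed, trains = cfg$seed + 1,
                        spines = cfg$seed + 2, mapping = cfg$seed + 3,
                        variability = cfg$seed + 4,
                        inhibition = cfg$seed + 5),
    package_version = as.character(utils::packageVersion("spinecap")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
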