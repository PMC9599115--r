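#' Simulate a full plasticity experiment
#'
#' End-to-end mechanistic stage: drives the reduced neuron with the mapped
#' excitatory trains and Poisson inhibition, integrates spine/dendrite
#' calcium, and applies the plasticity rule to every spine-head calcium
#' trace, in one fused fixed-step loop. Stages are open loop in the order
#' voltage -> calcium -> weights: synaptic conductances use the initial
#' weights throughout, while weights accumulate across trials.
#'
#' @param experiment a `trial_set` from [build_experiment()] (a single-trial
#'   `spike_trains` object is wrapped automatically)
#' @param morph a `morphology`
#' @param spines a `spine_set`
#' @param mapping a `cluster_mapping`
#' @param params a [neuron_params()]
#' @param ca a [calcium_params()]
#' @param plast a [plasticity_params()]
#' @param dt integration step (ms)
#' @param seed seed for the inhibitory trains
#' @param w0 initial weights (scalar or per spine)
#' @param inhibition include GABA inputs?
#' @param ca_rec_dt,w_rec_dt,rec_dt recording steps (ms) for calcium,
#'   weights and voltage
#' @return a `plasticity_sim`: list with somatic `spike_times` (ms),
#'   `t_v`/`v_soma`, `t_ca`/`ca_spine` (spines x time, µM),
#'   `t_w`/`w` (spines x time), `w_final`, `events` (engagement onsets),
#'   `dw` (spines x trials; change from each trial start to the next trial
#'   start, so the post-trial calcium tail is attributed to its trial),
#'   `windows_ms`, and the inputs
#' @export
simulate_experiment <- function(experiment, morph, spines, mapping,
                                params = neuron_params(),
                                ca = calcium_params(),
                                plast = plasticity_params(), dt = 0.025,
                                seed = 1, w0 = 1, inhibition = TRUE,
                                ca_rec_dt = 1, w_rec_dt = 1, rec_dt = 1) {
  if (inherits(experiment, "spike_trains"))
    experiment <- build_experiment(experiment, n_trials = 1)
  stopifnot(inherits(experiment, "trial_set"))
  train_times <- experiment_train_times(experiment)
  ns <- nrow(spines)
  w0 <- rep_len(w0, ns)
  a <- .assemble_sim(morph, spines, mapping, train_times, params,
                     duration_s = experiment$duration, dt = dt, seed = seed,
                     inhibition = inhibition, ca = ca, plast = plast,
                     w0 = w0, rec_nodes = 1L, rec_dt = rec_dt,
                     ca_rec_dt = ca_rec_dt, w_rec_dt = w_rec_dt)
  r <- .run_core(a)
  windows_ms <- experiment$windows * 1000
  n_tr <- experiment$n_trials
  # weight change per trial: from trial start to next trial start
  t_w <- r$t_w
  idx_at <- function(tm) pmax(1L, pmin(length(t_w), round(tm / w_rec_dt)))
  starts <- idx_at(windows_ms[, 1])
  nexts <- c(starts[-1], length(t_w))
  dw <- matrix(0, ns, n_tr)
  for (k in seq_len(n_tr))
    dw[, k] <- r$w[, nexts[k]] - r$w[, starts[k]]
  ev <- data.frame(time = r$event_time, synapse = r$event_spine,
                   direction = r$event_sign)
  structure(list(spike_times = r$spike_times, t_v = r$t_v,
                 v_soma = as.numeric(r$v[1, ]), t_ca = r$t_ca,
                 ca_spine = r$ca_spine, t_w = t_w, w = r$w,
                 w_final = r$w_final, events = ev, dw = dw,
                 windows_ms = windows_ms, experiment = experiment,
                 mapping = mapping, spines = spines, w0 = w0,
                 seed = seed),
            class = "plasticity_sim")
}

#' @export
print.plasticity_sim <- function(x, ...) {
  cat("plasticity_sim:", nrow(x$spines), "spines,",
      nrow(x$mapping), "mapped synapses,", ncol(x$dw), "trial(s),",
      length(x$spike_times), "somatic spikes (",
      round(length(x$spike_times) /
              (max(x$t_v) / 1000), 2), "Hz overall)\n")
  cat("  total |dw| > 0.1:", sum(abs(rowSums(x$dw)) > 0.1), "synapses\n")
  invisible(x)
}

#' Per-synapse-per-trial feature table
#'
#' Builds the regression table relating the weight change of each mapped
#' synapse on each trial to discretized time samples of its direct
#' pre-synaptic firing rate, its spine calcium concentration, the combined
#' firing rate of its nearest neighbors, and spatial features (cluster
#' length, spines per cluster, distance to soma). Rate/calcium series are
#' discretized into 1, 3 and 5 mean time samples (columns `rate1`,
#' `rate3_*`, `rate5_*`, `ca1`, ..., `nb5_*`).
#'
#' @param sim a `plasticity_sim` (or list of them, rows concatenated)
#' @param morph the `morphology` used
#' @param dmat spine distance matrix (computed if `NULL`)
#' @param k_neighbors neighbors for the combined rate (19)
#' @param sigma,grid_dt kernel rate estimation parameters (s)
#' @return data.frame, one row per mapped synapse per trial
#' @export
build_feature_table <- function(sim, morph, dmat = NULL, k_neighbors = 19,
                                sigma = 0.05, grid_dt = 0.01) {
  if (inherits(sim, "plasticity_sim")) sim <- list(sim)
  out <- list()
  for (si in seq_along(sim)) {
    s <- sim[[si]]
    spines <- s$spines
    if (is.null(dmat)) dmat <- spine_distance_matrix(morph, spines)
    mapping <- s$mapping
    spine_rows <- match(mapping$spine_id, spines$spine_id)
    map2 <- mapping; map2$spine_row <- spine_rows
    spans <- attr(mapping, "cluster_span_um")
    cfg <- attr(mapping, "config")
    ts <- s$experiment
    for (k in seq_len(ts$n_trials)) {
      win <- ts$windows[k, ]
      ca_idx <- which(s$t_ca / 1000 > win[1] & s$t_ca / 1000 <= win[2])
      trial_trains <- ts$trials[[k]]$times
      for (j in seq_len(nrow(mapping))) {
        sr <- spine_rows[j]
        tr_id <- mapping$train_id[j]
        rate <- instantaneous_rate(trial_trains[[tr_id]], win, grid_dt,
                                   sigma)$rate
        ca_series <- s$ca_spine[sr, ca_idx]
        nb <- neighbor_combined_rate(sr, map2, trial_trains, dmat,
                                     k = k_neighbors, window = win,
                                     grid_dt = grid_dt, sigma = sigma)
        row <- data.frame(
          sim = si, trial = k, synapse = sr, train_id = tr_id,
          dw = s$dw[sr, k],
          cluster_length = if (!is.null(spans))
            spans[mapping$cluster_id[j]] else NA_real_,
          spines_per_cluster = if (!is.null(cfg))
            cfg$spines_per_cluster else NA_real_,
          dist_soma = spines$path_distance_um[sr],
          pre_count = length(trial_trains[[tr_id]]))
        for (nsamp in c(1, 3, 5)) {
          rs <- time_sample_features(rate, nsamp)
          cs <- time_sample_features(ca_series, nsamp)
          ns_ <- time_sample_features(nb$rate, nsamp)
          nm <- function(base) if (nsamp == 1) base
            else paste0(base, nsamp, "_", seq_len(nsamp))
          row[if (nsamp == 1) "rate1" else nm("rate")] <- as.list(rs)
          row[if (nsamp == 1) "ca1" else nm("ca")] <- as.list(cs)
          row[if (nsamp == 1) "nb1" else nm("nb")] <- as.list(ns_)
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  do.call(rbind, out)
}

#' Write simulation traces and weight tables as delimited text
#'
#' `write_voltage_trace` writes time (ms) plus one column per recorded
#' compartment; `write_spike_times` writes the somatic spike times (ms),
#' one per line; `write_calcium_trace` writes time (ms) plus one column per
#' spine (µM); `write_weight_table` writes the per-synapse-per-trial weight
#' changes (`synapse_id`, `trial`, `w_start`, `w_end`, `dw`).
#'
#' @param vt a `voltage_trace`
#' @param sim a `plasticity_sim`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_voltage_trace <- function(vt, path) {
  df <- data.frame(time_ms = vt$time, t(vt$v))
  names(df)[-1] <- paste0("comp", vt$rec_nodes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
write_spike_times <- function(vt, path) {
  writeLines(format(vt$spike_times, trim = TRUE), path)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
write_calcium_trace <- function(sim, path) {
  df <- data.frame(time_ms = sim$t_ca, t(sim$ca_spine))
  names(df)[-1] <- paste0("spine", seq_len(nrow(sim$ca_spine)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
write_weight_table <- function(sim, path) {
  n_tr <- ncol(sim$dw)
  idx_at <- function(tm) pmax(1L, pmin(length(sim$t_w),
                                       round(tm / (sim$t_w[2] - sim$t_w[1]))))
  starts <- idx_at(sim$windows_ms[, 1])
  rows <- do.call(rbind, lapply(seq_len(n_tr), function(k) {
    w_start <- sim$w[, starts[k]]
    data.frame(synapse_id = seq_len(nrow(sim$w)), trial = k,
               w_start = w_start, w_end = w_start + sim$dw[, k],
               dw = sim$dw[, k])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
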