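#' Spike train collection
#'
#' A `spike_trains` object holds the spike times of a set of pre-synaptic
#' input trains over a common time window. Times are in seconds, sorted
#' ascending, and confined to `[t0, t1)`.
#'
#' @param times list of numeric vectors, one per train (seconds)
#' @param window numeric length 2, window `c(t0, t1)` in seconds
#' @param train_id optional character or integer ids (default `1:n`)
#' @return an object of class `spike_trains`
#' @export
spike_trains <- function(times, window, train_id = NULL) {
  stopifnot(is.list(times), length(window) == 2, window[2] > window[1])
  if (is.null(train_id)) train_id <- seq_along(times)
  stopifnot(length(train_id) == length(times))
  times <- lapply(times, function(tt) {
    tt <- as.numeric(sort(tt))
    if (length(tt) && (any(tt < window[1]) || any(tt >= window[2])))
      stop("spike times outside window [", window[1], ", ", window[2], ")")
    tt
  })
  structure(list(times = times, window = as.numeric(window),
                 train_id = train_id),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  n <- vapply(x$times, length, 1L)
  cat("spike_trains:", length(x$times), "trains on [", x$window[1], ",",
      x$window[2], ") s;", sum(n), "spikes (median", stats::median(n),
      "per train)\n")
  invisible(x)
}

#' Spike counts per train
#' @param x a `spike_trains` object
#' @return integer vector
#' @export
spike_counts <- function(x) vapply(x$times, length, 1L)

#' Specification of a correlated rate ensemble
#'
#' Describes how to generate an ensemble of excitatory input trains that
#' emulate simultaneously recorded motor-cortex units: heterogeneous
#' (log-normal) per-train base rates, one shared multiplicative rate
#' modulation giving within-trial correlations, and a late-trial rate ramp
#' resembling motor preparatory activity.
#'
#' @param n_trains number of trains
#' @param trial_duration trial length in seconds
#' @param base_rates per-train mean rates (Hz); by default drawn log-normally
#'   with median `rate_median` and log-SD `rate_sdlog` when the spec is
#'   realized (so high-count trains are rare but present)
#' @param rate_median,rate_sdlog log-normal parameters used when
#'   `base_rates` is `NULL`
#' @param shared_modulation function of time (s) giving the common
#'   multiplicative rate factor, or `NULL` for a smoothed log-normal latent
#'   profile generated per trial (SD `mod_sd` on the log scale, correlation
#'   time `mod_tau` s, normalized to mean 1)
#' @param mod_sd,mod_tau latent-profile parameters
#' @param ramp function of time (s) giving a deterministic rate multiplier,
#'   `NULL` for the default late-trial ramp peaking in the last 300 ms
#'   (factor `ramp_peak` at the trial end), or `FALSE` to disable
#' @param ramp_peak peak multiplier of the default ramp
#' @param seed integer seed (mandatory; generation is reproducible)
#' @return an object of class `rate_ensemble_spec`
#' @export
rate_ensemble_spec <- function(n_trains = 200, trial_duration = 1,
                               base_rates = NULL, rate_median = 4,
                               rate_sdlog = 0.8, shared_modulation = NULL,
                               mod_sd = 0.5, mod_tau = 0.1, ramp = NULL,
                               ramp_peak = 2.5, seed) {
  stopifnot(n_trains >= 1, trial_duration > 0)
  if (missing(seed)) stop("seed is a mandatory field of rate_ensemble_spec")
  if (!is.null(base_rates)) {
    stopifnot(length(base_rates) == n_trains, all(base_rates >= 0))
  }
  if (isFALSE(ramp)) ramp <- function(t) rep(1, length(t))
  structure(list(n_trains = n_trains, trial_duration = trial_duration,
                 base_rates = base_rates, rate_median = rate_median,
                 rate_sdlog = rate_sdlog,
                 shared_modulation = shared_modulation, mod_sd = mod_sd,
                 mod_tau = mod_tau, ramp = ramp, ramp_peak = ramp_peak,
                 seed = as.integer(seed)),
            class = "rate_ensemble_spec")
}

# default late-trial ramp: 1 until 70% of the trial, then smooth rise
# peaking at the trial end
.default_ramp <- function(duration, peak) {
  t_on <- 0.7 * duration
  function(t) {
    r <- rep(1, length(t))
    i <- t > t_on
    r[i] <- 1 + (peak - 1) * ((t[i] - t_on) / (duration - t_on))^2
    r
  }
}

# smoothed log-normal shared latent profile on a fine grid, mean 1
.latent_profile <- function(duration, sd_log, tau, dt = 0.001) {
  n <- ceiling(duration / dt)
  z <- stats::rnorm(n)
  # exponential moving-average smoothing -> correlation time ~ tau
  a <- exp(-dt / tau)
  for (i in 2:n) z[i] <- a * z[i - 1] + sqrt(1 - a^2) * z[i]
  m <- exp(sd_log * z)
  m <- m / mean(m)
  list(t = (seq_len(n) - 0.5) * dt, m = m)
}

#' Generate correlated excitatory spike trains for one trial
#'
#' Each train is an inhomogeneous Poisson process with rate
#' `base_rate[i] * shared_modulation(t) * ramp(t)`; the shared latent
#' modulation induces within-trial correlations between trains.
#'
#' @param spec a [rate_ensemble_spec()]
#' @return a `spike_trains` object over `[0, trial_duration)`
#' @export
generate_correlated_trains <- function(spec) {
  stopifnot(inherits(spec, "rate_ensemble_spec"))
  dur <- spec$trial_duration
  if (dur <= 0) stop("trial_duration must be positive")
  set.seed(spec$seed)
  base <- spec$base_rates
  if (is.null(base))
    base <- stats::rlnorm(spec$n_trains, meanlog = log(spec$rate_median),
                          sdlog = spec$rate_sdlog)
  ramp <- spec$ramp
  if (is.null(ramp)) ramp <- .default_ramp(dur, spec$ramp_peak)
  shared <- spec$shared_modulation
  if (is.null(shared)) {
    prof <- .latent_profile(dur, spec$mod_sd, spec$mod_tau)
    shared <- stats::approxfun(prof$t, prof$m, rule = 2)
  }
  grid <- seq(0, dur, length.out = 512)
  mod_max <- max(shared(grid) * ramp(grid))
  times <- vector("list", spec$n_trains)
  for (i in seq_len(spec$n_trains)) {
    lam_max <- base[i] * mod_max
    if (lam_max <= 0) { times[[i]] <- numeric(0); next }
    # thinning of a homogeneous Poisson process at lam_max
    n_cand <- stats::rpois(1, lam_max * dur)
    tt <- sort(stats::runif(n_cand, 0, dur))
    keep <- stats::runif(n_cand) < base[i] * shared(tt) * ramp(tt) / lam_max
    times[[i]] <- tt[keep]
  }
  spike_trains(times, c(0, dur))
}

#' Trial-to-trial variability specification
#'
#' @param kind one of `"jitter"` (truncated-normal spike-time jitter),
#'   `"move"` (move spikes between trains), `"shuffle_isi"`
#'   (permute interspike intervals within each train)
#' @param sigma jitter SD in seconds (kind `"jitter"`)
#' @param p_move per-spike probability of moving (kind `"move"`)
#' @param seed integer seed
#' @return an object of class `variability_spec`
#' @export
variability_spec <- function(kind = c("jitter", "move", "shuffle_isi"),
                             sigma = 0, p_move = 0, seed) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0, p_move >= 0, p_move <= 1)
  if (missing(seed)) stop("seed is a mandatory field of variability_spec")
  structure(list(kind = kind, sigma = sigma, p_move = p_move,
                 seed = as.integer(seed)),
            class = "variability_spec")
}

#' Jitter spike times with a truncated normal distribution
#'
#' Each spike is displaced by a draw from a normal distribution with mean 0
#' and SD `sigma`, truncated so the jittered time stays inside the trial
#' window. Sampling is by inverse CDF on the truncated interval, so per-train
#' spike counts are preserved exactly and the draw is reproducible.
#'
#' @param trains a `spike_trains` object
#' @param sigma jitter SD in seconds
#' @param seed integer seed
#' @return a `spike_trains` object
#' @export
jitter_trial <- function(trains, sigma, seed) {
  stopifnot(inherits(trains, "spike_trains"), sigma >= 0)
  if (sigma == 0) return(trains)
  set.seed(as.integer(seed))
  t0 <- trains$window[1]; t1 <- trains$window[2]
  out <- lapply(trains$times, function(tt) {
    if (!length(tt)) return(tt)
    p_lo <- stats::pnorm(t0, mean = tt, sd = sigma)
    p_hi <- stats::pnorm(t1, mean = tt, sd = sigma)
    u <- stats::runif(length(tt))
    new <- stats::qnorm(p_lo + u * (p_hi - p_lo), mean = tt, sd = sigma)
    # inverse CDF can return the open upper bound at u ~ 1; keep inside
    new <- pmin(pmax(new, t0), t1 - 1e-12)
    sort(new)
  })
  spike_trains(out, trains$window, trains$train_id)
}

#' Move spikes between trains
#'
#' Each spike is independently selected with probability `p_move`; a moved
#' spike keeps its time but is reassigned to another train, chosen with
#' probability proportional to the (pre-move) spike count of the target
#' trains. Total spike count over all trains is conserved, and the aggregate
#' spike timing to the neuron is unchanged.
#'
#' @param trains a `spike_trains` object with at least 2 trains
#' @param p_move probability in `[0, 1]`
#' @param seed integer seed
#' @return a `spike_trains` object
#' @export
move_spikes <- function(trains, p_move, seed) {
  stopifnot(inherits(trains, "spike_trains"), p_move >= 0, p_move <= 1)
  if (p_move == 0) return(trains)
  n <- length(trains$times)
  if (n < 2) stop("move_spikes needs at least 2 trains (no valid target)")
  set.seed(as.integer(seed))
  counts <- spike_counts(trains)
  new_times <- trains$times
  moved <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- trains$times[[i]]
    if (!length(tt)) { moved[[i]] <- list(); next }
    sel <- stats::runif(length(tt)) < p_move
    if (!any(sel)) { moved[[i]] <- list(); next }
    others <- setdiff(seq_len(n), i)
    wts <- counts[others]
    if (sum(wts) == 0) wts <- rep(1, length(others)) # degenerate: uniform
    dest <- others[sample.int(length(others), sum(sel), replace = TRUE,
                              prob = wts)]
    new_times[[i]] <- tt[!sel]
    moved[[i]] <- split(tt[sel], factor(dest, levels = seq_len(n)))
  }
  for (i in seq_len(n)) {
    add <- unlist(lapply(moved, function(m) if (length(m)) m[[i]] else NULL),
                  use.names = FALSE)
    if (length(add)) new_times[[i]] <- sort(c(new_times[[i]], add))
  }
  spike_trains(new_times, trains$window, trains$train_id)
}

#' Shuffle interspike intervals within each train
#'
#' Permutes the order of the interspike intervals of each train, anchoring
#' the first spike at its original time; the multiset of ISIs, the spike
#' count, and the total span of each train are preserved. Trains with fewer
#' than 2 spikes are returned unchanged.
#'
#' @param trains a `spike_trains` object (or a single numeric vector of
#'   times, in which case a numeric vector is returned)
#' @param seed integer seed
#' @return same class as the input
#' @export
shuffle_isis <- function(trains, seed) {
  set.seed(as.integer(seed))
  shuf1 <- function(tt) {
    if (length(tt) < 2) return(tt)
    isi <- diff(tt)
    tt[1] + c(0, cumsum(sample(isi)))
  }
  if (is.numeric(trains)) return(shuf1(sort(trains)))
  stopifnot(inherits(trains, "spike_trains"))
  out <- lapply(trains$times, shuf1)
  spike_trains(out, trains$window, trains$train_id)
}

#' Apply a variability transform to a trial
#'
#' @param trains a `spike_trains` object (the initial trial)
#' @param spec a [variability_spec()]
#' @param seed optional seed overriding `spec$seed` (used to vary the
#'   transform between repetitions of the same initial trial)
#' @return a transformed `spike_trains` object
#' @export
apply_variability <- function(trains, spec, seed = NULL) {
  stopifnot(inherits(spec, "variability_spec"))
  sd <- if (is.null(seed)) spec$seed else as.integer(seed)
  switch(spec$kind,
    jitter = jitter_trial(trains, spec$sigma, sd),
    move = move_spikes(trains, spec$p_move, sd),
    shuffle_isi = shuffle_isis(trains, sd))
}

#' Generate a homogeneous Poisson spike train
#'
#' Used for inhibitory inputs: striatal fast-spiking interneurons fire at a
#' mean rate of 12 Hz and low-threshold-spiking interneurons at 8 Hz, active
#' for the entire experiment duration.
#'
#' @param rate_hz mean firing rate (Hz), `>= 0`
#' @param duration duration in seconds
#' @param seed integer seed
#' @return numeric vector of spike times in `[0, duration)`
#' @export
generate_poisson_inhibition <- function(rate_hz, duration, seed) {
  stopifnot(rate_hz >= 0, duration > 0)
  if (rate_hz == 0) return(numeric(0))
  set.seed(as.integer(seed))
  # draw slightly beyond and truncate; exponential ISIs
  n_guess <- ceiling(rate_hz * duration + 10 * sqrt(rate_hz * duration) + 10)
  tt <- cumsum(stats::rexp(n_guess, rate_hz))
  while (tt[length(tt)] < duration)
    tt <- c(tt, tt[length(tt)] + cumsum(stats::rexp(n_guess, rate_hz)))
  tt[tt < duration]
}

#' Build a multi-trial experiment timeline
#'
#' Repeats the initial trial `n_trials` times on a global timeline. Each
#' repetition is the initial trial passed through the variability transform
#' (never cumulative: variability is always applied to the initial trial).
#' The layout is a `lead_in` period, then `n_trials` trials each followed by
#' an intertrial interval; with the defaults (10 trials of 1 s, 1 s
#' intertrial interval, 1 s lead-in) the experiment lasts 21 s.
#'
#' @param trial_trains the initial trial, a `spike_trains` object
#' @param n_trials number of repetitions, `>= 1`
#' @param intertrial_interval gap after every trial (s)
#' @param variability optional [variability_spec()]; `NULL` repeats the
#'   trial verbatim
#' @param lead_in quiet period before the first trial (s)
#' @return an object of class `trial_set`: list with `trials` (per-trial
#'   `spike_trains` on the global timeline), `windows` (n_trials x 2 matrix),
#'   `duration` (total s), `trial_duration`, and the inputs
#' @export
build_experiment <- function(trial_trains, n_trials = 10,
                             intertrial_interval = 1, variability = NULL,
                             lead_in = 1) {
  stopifnot(inherits(trial_trains, "spike_trains"), n_trials >= 1,
            intertrial_interval >= 0, lead_in >= 0)
  dur <- diff(trial_trains$window)
  windows <- cbind(lead_in + (seq_len(n_trials) - 1) * (dur + intertrial_interval))
  windows <- cbind(windows, windows[, 1] + dur)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    tr <- trial_trains
    if (!is.null(variability))
      tr <- apply_variability(trial_trains, variability,
                              seed = variability$seed + (k - 1L))
    off <- windows[k, 1] - trial_trains$window[1]
    trials[[k]] <- spike_trains(lapply(tr$times, function(tt) tt + off),
                                windows[k, ], tr$train_id)
  }
  structure(list(trials = trials, windows = windows,
                 duration = lead_in + n_trials * (dur + intertrial_interval),
                 trial_duration = dur, n_trials = n_trials,
                 intertrial_interval = intertrial_interval,
                 lead_in = lead_in),
            class = "trial_set")
}

#' Concatenate the per-train global timelines of a trial set
#'
#' @param ts a `trial_set`
#' @return list of numeric vectors, one per train, on the global timeline
#' @export
experiment_train_times <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  n <- length(ts$trials[[1]]$times)
  lapply(seq_len(n), function(i)
    sort(unlist(lapply(ts$trials, function(tr) tr$times[[i]]),
                use.names = FALSE)))
}

#' Read / write spike trains as delimited text
#'
#' Columns `train_id`, `spike_time_s` with a header row.
#'
#' @param x a `spike_trains` object
#' @param path file path
#' @param window time window used when reading (defaults to `[0, max time]`)
#' @return `read_spike_trains` returns a `spike_trains` object
#' @export
write_spike_trains <- function(x, path) {
  stopifnot(inherits(x, "spike_trains"))
  df <- data.frame(
    train_id = rep(x$train_id, vapply(x$times, length, 1L)),
    spike_time_s = unlist(x$times, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, window = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("train_id", "spike_time_s") %in% names(df)))
  ids <- unique(df$train_id)
  times <- lapply(ids, function(i) sort(df$spike_time_s[df$train_id == i]))
  if (is.null(window)) window <- c(0, max(df$spike_time_s) + 1e-9)
  spike_trains(times, window, ids)
}
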