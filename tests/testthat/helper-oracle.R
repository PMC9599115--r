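# Independent reference implementations used as oracles.

# naive per-step transcription of the dual-threshold rule, kept independent
# of the package's compiled implementation
naive_weight_update <- function(ca, dt, p, w0) {
  w <- w0
  tad <- 0
  tap <- 0
  out <- numeric(length(ca))
  eps <- 1e-9
  for (k in seq_along(ca)) {
    cc <- ca[k]
    tad <- if (cc >= p$t_ad - eps) tad + dt else 0
    tap <- if (cc >= p$t_ap - eps) tap + dt else 0
    dw <- 0
    if (cc >= p$t_ap - eps && tap > p$dur_p + eps) {
      dw <- min(p$g_pmax, p$g_p * (cc - p$t_ap)) *
        (1 - (w - p$wmin) / (p$wmax - p$wmin))
    } else if (cc >= p$t_ad - eps && tad > p$dur_d + eps) {
      dw <- -min(p$g_dmax, p$g_d * (cc - p$t_ad)) *
        (w - p$wmin) / (p$wmax - p$wmin)
    }
    w <- min(p$wmax, max(p$wmin, w + dw * dt))
    out[k] <- w
  }
  out
}

# random calcium traces mixing plateaus, pulses and smooth wander
random_ca_trace <- function(n, seed) {
  set.seed(seed)
  base <- abs(0.15 + 0.25 * sin(seq_len(n) / (50 + 100 * runif(1))) +
                cumsum(rnorm(n, 0, 0.004)))
  k <- sample(0:3, 1)
  for (j in seq_len(k)) {
    at <- sample.int(n - 200, 1)
    base[at:(at + sample(20:200, 1))] <- runif(1, 0.2, 1.2)
  }
  pmax(base, 0)
}

# small shared model fixture (built once per test run)
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      morph <- build_default_morphology()
      spines <- place_spines(morph, 0.1, 25, seed = 3)
      spec <- rate_ensemble_spec(n_trains = 50, seed = 2)
      trial <- generate_correlated_trains(spec)
      mapping <- assign_clusters(morph, spines, 50,
                                 cluster_config(1, 0, seed = 4))
      cache <<- list(morph = morph, spines = spines, trial = trial,
                     mapping = mapping)
    }
    cache
  }
})
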