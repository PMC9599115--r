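#' Instantaneous firing rate by Gaussian kernel estimation
#'
#' Convolves the spike train with a Gaussian kernel (SD `sigma`), reflecting
#' mass at the window edges so that the integral of the rate over the window
#' equals the spike count.
#'
#' @param times_s spike times (s)
#' @param window numeric length 2 (s)
#' @param grid_dt evaluation grid step (s), `<= 0.01`
#' @param sigma kernel SD (s)
#' @return list with `time` (grid centers, s) and `rate` (Hz)
#' @export
instantaneous_rate <- function(times_s, window, grid_dt = 0.01,
                               sigma = 0.05) {
  stopifnot(grid_dt <= 0.01 + 1e-12, length(window) == 2)
  grid <- seq(window[1] + grid_dt / 2, window[2] - grid_dt / 2, by = grid_dt)
  if (!length(times_s))
    return(list(time = grid, rate = rep(0, length(grid))))
  tt <- c(times_s, 2 * window[1] - times_s, 2 * window[2] - times_s)
  rate <- rowSums(stats::dnorm(outer(grid, tt, "-"), sd = sigma))
  list(time = grid, rate = rate)
}

#' Weight-change triggered average
#'
#' Groups synapse-trials into bins of the per-trial weight change and
#' averages the accompanying time series (firing rate or calcium) pointwise
#' within each bin. Bin edges (default 7 bins) are symmetric about zero with
#' a dedicated near-zero bin of half-width 0.01, outer edges placed from the
#' quantiles of `|dw|` above that; the edges used are returned with the
#' result.
#'
#' @param dw per-synapse-trial weight changes (length n)
#' @param series matrix (n x time points), rows aligned to `dw`
#' @param n_bins odd number of bins (middle bin straddles zero)
#' @param edges optional explicit edges (length `n_bins + 1`, increasing)
#' @return a `wcta`: list with `edges`, `bin` (assignment per row), `mean`
#'   (n_bins x time, `NA` for empty bins), `count` (per bin), `flagged`
#'   (TRUE when all `dw` identical, degenerate single-bin case)
#' @export
weight_change_triggered_average <- function(dw, series, n_bins = 7,
                                            edges = NULL) {
  stopifnot(is.matrix(series), nrow(series) == length(dw))
  flagged <- FALSE
  if (length(unique(dw)) == 1) {
    flagged <- TRUE
    edges <- c(dw[1] - 1, dw[1] + 1)
    n_bins <- 1
  }
  if (is.null(edges)) {
    stopifnot(n_bins %% 2 == 1, n_bins >= 3)
    half <- (n_bins - 1) / 2
    abs_dw <- abs(dw)
    eps <- 0.01 # near-zero bin: changes below 0.5% of the weight range
    big <- abs_dw[abs_dw > eps]
    if (!length(big)) big <- max(abs_dw, eps)
    qs <- stats::quantile(big, probs = seq_len(half - 1) / half)
    pos <- unique(c(eps, qs, max(abs_dw, qs, eps) + 1e-9))
    while (length(pos) < half + 1) # degenerate quantiles: pad outward
      pos <- c(pos, max(pos) + 1e-9)
    pos <- sort(pos[seq_len(half + 1)])
    edges <- c(-rev(pos), pos)
  }
  bin <- findInterval(dw, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(edges) - 1
  m <- matrix(NA_real_, nb, ncol(series))
  count <- integer(nb)
  for (b in seq_len(nb)) {
    i <- which(bin == b)
    count[b] <- length(i)
    if (length(i))
      m[b, ] <- colMeans(series[i, , drop = FALSE])
  }
  structure(list(edges = edges, bin = bin, mean = m, count = count,
                 flagged = flagged),
            class = "wcta")
}

#' Combined firing rate of a synapse's nearest neighbors
#'
#' Merges the spike trains of the `k` nearest mapped neighbors of a synapse
#' (by dendritic path distance between spine attachment points, ties by
#' spine id) into a single train and computes its instantaneous firing rate.
#'
#' @param spine_row row index of the synapse's spine in the spine set
#' @param mapping a `cluster_mapping`
#' @param train_times_s list of spike-time vectors (s) indexed by train id
#' @param dmat spine distance matrix
#' @param k number of neighbors (19 in the neighborhood analyses); if fewer
#'   mapped neighbors exist, all are used and the result is flagged
#' @param window,grid_dt,sigma as [instantaneous_rate()]
#' @return list with `time`, `rate`, `neighbors` (spine rows used),
#'   `flagged`
#' @export
neighbor_combined_rate <- function(spine_row, mapping, train_times_s, dmat,
                                   k = 19, window, grid_dt = 0.01,
                                   sigma = 0.05) {
  mapped_rows <- mapping$spine_row
  if (is.null(mapped_rows)) mapped_rows <- mapping$spine_id
  others <- setdiff(mapped_rows, spine_row)
  ord <- others[order(dmat[spine_row, others], others)]
  flagged <- length(ord) < k
  nb <- ord[seq_len(min(k, length(ord)))]
  tr_ids <- mapping$train_id[match(nb, mapped_rows)]
  merged <- sort(unlist(train_times_s[tr_ids], use.names = FALSE))
  r <- instantaneous_rate(merged, window, grid_dt, sigma)
  list(time = r$time, rate = r$rate, neighbors = nb, flagged = flagged)
}

#' Discretize a time series into mean time samples
#'
#' Splits the series into `n_samples` equal consecutive intervals and
#' returns the mean over each: 1 sample is the mean over the whole trial,
#' 5 samples are means over successive 200 ms intervals of a 1 s trial.
#'
#' @param series numeric vector on an equally spaced grid spanning the trial
#' @param n_samples integer in 1..5
#' @return numeric vector of length `n_samples`
#' @export
time_sample_features <- function(series, n_samples) {
  stopifnot(n_samples >= 1, n_samples <= 5)
  n <- length(series)
  idx <- ceiling(seq_len(n) / (n / n_samples))
  as.numeric(tapply(series, idx, mean))
}

#' Random-forest prediction of weight change
#'
#' Fits random-forest regressions of the weight change on a chosen feature
#' set over repeated random train/test splits (default 5 sets x 4 repeats =
#' 20 regressions with 75% training data), scoring each by the coefficient
#' of determination R^2 on the held-out test set, and averaging normalized
#' feature importances.
#'
#' @param table data.frame with response column `dw` and feature columns
#' @param features character vector of feature column names
#' @param n_sets,n_repeats split replication structure
#' @param test_fraction held-out fraction per split
#' @param seed integer seed
#' @param num_trees trees per forest
#' @return list with `scores` (R^2 per regression), `mean_r2`, `se_r2`,
#'   `importance` (mean normalized importances, summing to 1),
#'   `importance_sums` (per-fit normalized importance totals, each 1),
#'   `flagged` (TRUE for constant response)
#' @export
rf_predict <- function(table, features, n_sets = 5, n_repeats = 4,
                       test_fraction = 0.25, seed = 1, num_trees = 500) {
  stopifnot(nrow(table) >= 50, all(features %in% names(table)),
            "dw" %in% names(table))
  if (stats::var(table$dw) == 0)
    return(list(scores = numeric(0), mean_r2 = NA_real_, se_r2 = NA_real_,
                importance = NULL, flagged = TRUE))
  set.seed(as.integer(seed))
  n <- nrow(table)
  scores <- numeric(0)
  imp <- NULL
  imp_sums <- numeric(0)
  dat <- table[, c("dw", features), drop = FALSE]
  for (rep_i in seq_len(n_sets * n_repeats)) {
    test <- sample.int(n, max(1, round(test_fraction * n)))
    fit <- ranger::ranger(
      dw ~ ., data = dat[-test, , drop = FALSE], num.trees = num_trees,
      importance = "impurity", seed = seed + rep_i,
      num.threads = 1)
    pred <- stats::predict(fit, dat[test, , drop = FALSE])$predictions
    y <- dat$dw[test]
    r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    scores <- c(scores, r2)
    ii <- fit$variable.importance
    ii <- if (sum(ii) > 0) ii / sum(ii) else rep(1 / length(ii), length(ii))
    imp_sums <- c(imp_sums, sum(ii))
    imp <- if (is.null(imp)) ii else imp + ii
  }
  imp <- imp / (n_sets * n_repeats)
  list(scores = scores, mean_r2 = mean(scores),
       se_r2 = stats::sd(scores) / sqrt(length(scores)),
       importance = imp, importance_sums = imp_sums, flagged = FALSE)
}

#' Compare prediction scores across feature sets
#'
#' One-way analysis of variance of R^2 scores over feature-set groups,
#' followed by pairwise Welch t-tests (unadjusted, as in the source
#' analyses; noted in the output).
#'
#' @param scores numeric vector of R^2 values
#' @param group factor/character of the same length naming the feature set
#' @return list with `anova` (data.frame: F, df1, df2, p) and `posthoc`
#'   (data.frame of pairwise Welch t-tests: group1, group2, t, p)
#' @export
compare_feature_sets <- function(scores, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 feature-set groups")
  fit <- stats::aov(scores ~ group)
  s <- summary(fit)[[1]]
  an <- data.frame(F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                   p = s$`Pr(>F)`[1])
  lv <- levels(group)
  ph <- do.call(rbind, lapply(utils::combn(lv, 2, simplify = FALSE),
    function(pr) {
      x <- scores[group == pr[1]]; y <- scores[group == pr[2]]
      tt <- stats::t.test(x, y)
      data.frame(group1 = pr[1], group2 = pr[2],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
  list(anova = an, posthoc = ph, correction = "none (Welch t)")
}

#' Pre/post spike-timing features of plasticity events
#'
#' For each weight-change event, finds the most recent pre-synaptic and
#' post-synaptic spikes at or before the event and computes the pre-post
#' interval `dt = t_post - t_pre` (positive when pre precedes post), the
#' interval using the second most recent pre-synaptic spike (`dt2`), the
#' interval between those two pre-synaptic spikes (`pre1_pre2`), and the
#' pre-synaptic firing rate over the `rate_window` before the event. Events
#' lacking the required spikes are flagged (`ok`/`ok2` FALSE) and should be
#' excluded from regressions using the affected features.
#'
#' @param event_times_ms event times (ms)
#' @param pre_times_ms pre-synaptic spike times (ms)
#' @param post_times_ms post-synaptic (somatic) spike times (ms)
#' @param rate_window_ms window for the pre rate (ms)
#' @return data.frame with one row per event: `event_time`, `dt_ms`,
#'   `dt2_ms`, `pre1_pre2_ms`, `pre_rate_hz`, `ok`, `ok2`
#' @export
isi_event_features <- function(event_times_ms, pre_times_ms, post_times_ms,
                               rate_window_ms = 50) {
  pre <- sort(pre_times_ms); post <- sort(post_times_ms)
  out <- lapply(event_times_ms, function(ev) {
    i_pre <- findInterval(ev, pre)   # last pre at or before ev
    i_post <- findInterval(ev, post)
    ok <- i_pre >= 1 && i_post >= 1
    ok2 <- i_pre >= 2 && i_post >= 1
    dt <- if (ok) post[i_post] - pre[i_pre] else NA_real_
    dt2 <- if (ok2) post[i_post] - pre[i_pre - 1] else NA_real_
    p12 <- if (i_pre >= 2) pre[i_pre] - pre[i_pre - 1] else NA_real_
    nr <- sum(pre > ev - rate_window_ms & pre <= ev)
    data.frame(event_time = ev, dt_ms = dt, dt2_ms = dt2,
               pre1_pre2_ms = p12,
               pre_rate_hz = nr / (rate_window_ms / 1000), ok = ok,
               ok2 = ok2)
  })
  do.call(rbind, out)
}

#' Pearson correlation with significance
#'
#' @param x,y numeric vectors, `length >= 3`
#' @return list with `r`, `p` (two-sided), `n`; `r` is `NA` (flagged) if
#'   either input has zero variance
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), flagged = TRUE))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       flagged = FALSE)
}
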