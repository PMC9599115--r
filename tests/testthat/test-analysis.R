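test_that("kernel rate estimates integrate to the spike count and recover mean rates", {
  w <- c(0, 1)
  z <- instantaneous_rate(numeric(0), w)
  expect_true(all(z$rate == 0))
  set.seed(1)
  tt <- sort(runif(37))
  r <- instantaneous_rate(tt, w)
  expect_lt(abs(sum(r$rate) * 0.01 - 37) / 37, 0.01)
  # 100 homogeneous 20 Hz trains: average level 20 Hz within 5%
  set.seed(2)
  lv <- replicate(100, {
    tr <- generate_poisson_inhibition(20, 1, seed = sample.int(1e6, 1))
    mean(instantaneous_rate(tr, w)$rate)
  })
  expect_lt(abs(mean(lv) - 20) / 20, 0.05)
})

test_that("the weight-change triggered average is an exact group-by mean and a partition", {
  set.seed(3)
  n <- 60
  dw <- runif(n, -0.5, 0.5)
  series <- matrix(rnorm(n * 20), n, 20)
  edges <- c(-Inf, -0.3, -0.1, -0.01, 0.01, 0.1, 0.3, Inf)
  wc <- weight_change_triggered_average(dw, series, edges = edges)
  expect_equal(sum(wc$count), n)
  for (b in which(wc$count > 0)) {
    i <- which(wc$bin == b)
    expect_equal(wc$mean[b, ], colMeans(series[i, , drop = FALSE]))
  }
  # count-weighted mean of bin means equals the overall mean
  ok <- wc$count > 0
  expect_equal(colSums(wc$mean[ok, ] * wc$count[ok]) / n, colMeans(series))
  # symmetry: two members s and -s average to zero
  s2 <- rbind(series[1, ], -series[1, ])
  wc2 <- weight_change_triggered_average(c(0.2, 0.25), s2,
                                         edges = c(-1, 0.1, 1))
  expect_equal(wc2$mean[2, ], rep(0, 20))
  # degenerate: identical weight changes flagged as single bin
  wc3 <- weight_change_triggered_average(rep(0.1, 5), series[1:5, ])
  expect_true(wc3$flagged)
})

test_that("neighbor-combined rates equal the rate of the concatenated train", {
  m <- tiny_model()
  dm <- spine_distance_matrix(m$morph, m$spines)
  map2 <- m$mapping
  map2$spine_row <- match(map2$spine_id, m$spines$spine_id)
  w <- c(0, 1)
  sr <- map2$spine_row[1]
  nb <- neighbor_combined_rate(sr, map2, m$trial$times, dm, k = 19,
                               window = w)
  expect_false(nb$flagged)
  expect_equal(length(nb$neighbors), 19)
  merged <- sort(unlist(m$trial$times[
    map2$train_id[match(nb$neighbors, map2$spine_row)]]))
  direct <- instantaneous_rate(merged, w)
  expect_equal(nb$rate, direct$rate)
  # k exceeding the available neighbors: use all, flag
  nb2 <- neighbor_combined_rate(sr, map2, m$trial$times, dm, k = 200,
                                window = w)
  expect_true(nb2$flagged)
  expect_equal(length(nb2$neighbors), nrow(map2) - 1)
})

test_that("time-sample features are interval means with the documented structure", {
  s <- rep(10, 1000)
  for (n in 1:5) expect_equal(time_sample_features(s, n), rep(10, n))
  # 5 samples of a 1 s series = means over consecutive 200 ms intervals
  s2 <- seq_len(1000)
  f5 <- time_sample_features(s2, 5)
  expect_equal(f5, vapply(0:4, function(k) mean(s2[k * 200 + 1:200]), 1.0))
  expect_equal(time_sample_features(s2, 1), mean(f5))
})

test_that("random-forest prediction separates structure from noise with unit importances", {
  set.seed(4)
  n <- 1500
  tab <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  tab$dw <- tab$x1^2 # noiseless monotone function of feature 1
  fit <- rf_predict(tab, c("x1", "x2", "x3"), seed = 5)
  expect_gt(fit$mean_r2, 0.95)
  expect_gt(fit$importance["x1"], 0.9)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-9)
  expect_true(all(abs(fit$importance_sums - 1) < 1e-9))
  tab$dw <- rnorm(n)
  fit0 <- rf_predict(tab, c("x1", "x2", "x3"), seed = 6)
  expect_lte(fit0$mean_r2, 0.05)
  # reproducibility under a fixed seed
  fit2 <- rf_predict(tab, c("x1", "x2", "x3"), seed = 6)
  expect_identical(fit0$scores, fit2$scores)
  tab$dw <- 1
  expect_true(rf_predict(tab, "x1", seed = 1)$flagged)
})

test_that("feature-set comparison reproduces a from-scratch ANOVA", {
  set.seed(7)
  scores <- c(rnorm(20, 0.5, 0.05), rnorm(20, 0.6, 0.05),
              rnorm(20, 0.62, 0.05))
  grp <- rep(c("a", "b", "c"), each = 20)
  res <- compare_feature_sets(scores, grp)
  # direct sum-of-squares computation
  gm <- mean(scores)
  mns <- tapply(scores, grp, mean)
  ssb <- sum(20 * (mns - gm)^2)
  ssw <- sum((scores - mns[grp])^2)
  f_direct <- (ssb / 2) / (ssw / 57)
  expect_equal(res$anova$F, f_direct)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 57)
  # identical groups: F = 0
  same <- rep(rnorm(10), 2)
  res0 <- compare_feature_sets(same, rep(c("a", "b"), each = 10))
  expect_equal(res0$anova$F, 0)
  # disjoint supports: post-hoc p < 0.01
  disj <- c(runif(10, 0, 0.1), runif(10, 0.8, 0.9))
  resd <- compare_feature_sets(disj, rep(c("a", "b"), each = 10))
  expect_lt(resd$posthoc$p[1], 0.01)
  expect_error(compare_feature_sets(1:5, rep("a", 5)), "2")
})

test_that("pre/post spike-interval features follow the stated conventions", {
  f <- isi_event_features(505, pre_times_ms = c(300, 490),
                          post_times_ms = c(200, 500))
  expect_equal(f$dt_ms, 10) # pre at 490, post at 500: dt = +10 ms
  expect_equal(f$dt2_ms, 200)
  expect_equal(f$pre1_pre2_ms, 190)
  expect_true(f$ok && f$ok2)
  # 3 pre spikes within the 50 ms window -> 60 Hz
  f2 <- isi_event_features(100, pre_times_ms = c(60, 70, 80),
                           post_times_ms = 90)
  expect_equal(f2$pre_rate_hz, 60)
  # missing prior spikes are flagged
  f3 <- isi_event_features(50, pre_times_ms = 60, post_times_ms = 40)
  expect_false(f3$ok)
  # brute-force scan over random trains
  set.seed(8)
  pre <- sort(runif(40, 0, 1000))
  post <- sort(runif(15, 0, 1000))
  evs <- sort(runif(10, 100, 1000))
  got <- isi_event_features(evs, pre, post)
  for (i in seq_along(evs)) {
    pp <- pre[pre <= evs[i]]
    qq <- post[post <= evs[i]]
    if (length(pp) && length(qq))
      expect_equal(got$dt_ms[i], max(qq) - max(pp))
    expect_equal(got$pre_rate_hz[i],
                 sum(pre > evs[i] - 50 & pre <= evs[i]) / 0.05)
  }
})

test_that("correlation matches the textbook formula and flags degenerate input", {
  x <- 1:10
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -2 * x + 3)$r, -1)
  set.seed(9)
  a <- rnorm(10); b <- rnorm(10)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  got <- correlate(a, b)
  expect_equal(got$r, r_direct)
  expect_equal(got$n, 10)
  expect_true(correlate(rep(1, 5), rnorm(5))$flagged)
})
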