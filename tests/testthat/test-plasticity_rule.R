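test_that("sub-threshold calcium leaves the weight untouched and bad traces are rejected", {
  tr <- rep(0.2, 10000) # 1 s at 0.1 ms, below the LTD threshold
  out <- update_weights(tr, w0 = 1, dt = 0.1)
  expect_identical(out$w_final, 1)
  expect_equal(nrow(out$events), 0)
  expect_error(update_weights(c(0.1, -0.2, 0.1)), "negative")
})

test_that("pulse amplitude and duration criteria match the rule thresholds", {
  p <- plasticity_params()
  # 0.40 uM in the LTD band: 27 ms no change, 29 ms depression
  for (d in c(27, 28)) {
    tr <- square_pulse_trace(0.40, d, dt = 0.05)
    expect_identical(update_weights(tr, p, w0 = 1, dt = 0.05)$w_final, 1)
  }
  tr29 <- square_pulse_trace(0.40, 29, dt = 0.05)
  expect_lt(update_weights(tr29, p, w0 = 1, dt = 0.05)$w_final, 1)
  # brief high pulse potentiates; prolonged moderate plateau depresses
  hi <- square_pulse_trace(1.0, 10, dt = 0.05)
  expect_gt(update_weights(hi, p, w0 = 1, dt = 0.05)$w_final, 1)
  lo <- square_pulse_trace(0.45, 300, dt = 0.05)
  expect_lt(update_weights(lo, p, w0 = 1, dt = 0.05)$w_final, 1)
  # above T_AP only the potentiation branch applies
  ev <- detect_plasticity_events(square_pulse_trace(0.8, 100, dt = 0.05),
                                 p, dt = 0.05)
  expect_true(all(ev$direction == 1))
})

test_that("threshold scans recover the printed amplitude and duration criteria", {
  expect_equal(scan_amplitude_threshold("ltd", duration_ms = 100), 0.33)
  expect_equal(scan_amplitude_threshold("ltp", duration_ms = 10), 0.53)
  expect_equal(scan_duration_threshold("ltd", amplitude = 0.40, step = 1), 28)
  expect_equal(scan_duration_threshold("ltp", amplitude = 1.0, step = 0.1,
                                       max_value = 20), 3.3)
})

test_that("soft bounds drive the weight to its limits and pin it there", {
  p <- plasticity_params()
  up <- update_weights(rep(1.0, 6e5), p, w0 = 0.5, dt = 0.1)
  expect_lt(abs(up$w_final - 2), 1e-9)
  dn <- update_weights(rep(0.52, 1.2e6), p, w0 = 1.5, dt = 0.1)
  expect_lt(dn$w_final, 1e-6)
  # fixed point: starting at the bound, the weight does not move
  expect_identical(update_weights(rep(1.0, 1e4), p, w0 = 2, dt = 0.1)$w_final,
                   2)
  expect_identical(update_weights(rep(0.45, 1e4), p, w0 = 0, dt = 0.1)$w_final,
                   0)
})

test_that("the update is monotone in calcium below the gain cap", {
  p <- plasticity_params()
  c1 <- update_weights(rep(0.9, 2e4), p, w0 = 1, dt = 0.05)$w
  c2 <- update_weights(rep(0.7, 2e4), p, w0 = 1, dt = 0.05)$w
  expect_true(all(c1 >= c2))
})

test_that("trajectories match the naive per-step reference on random traces", {
  p <- plasticity_params()
  for (s in 1:100) {
    ca <- random_ca_trace(3000, seed = s)
    w0 <- runif(1, 0, 2)
    fast <- update_weights(ca, p, w0 = w0, dt = 0.1)$w
    slow <- naive_weight_update(ca, 0.1, p, w0)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("results are step-size invariant on smooth traces", {
  p <- plasticity_params()
  f <- function(dt) {
    t <- seq(dt, 2000, by = dt)
    ca <- 0.25 + 0.45 * sin(2 * pi * t / 700)^2
    update_weights(ca, p, w0 = 1, dt = dt)$w_final
  }
  expect_lt(abs(f(0.05) - f(0.025)) / abs(f(0.05) - 1), 0.01)
})

test_that("event detection reports engagement onsets consistent with the weight trace", {
  p <- plasticity_params()
  expect_equal(nrow(detect_plasticity_events(rep(0.2, 1e4), p, dt = 0.05)), 0)
  tr <- square_pulse_trace(0.8, 50, dt = 0.05, pre_ms = 20)
  ev <- detect_plasticity_events(tr, p, dt = 0.05)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1)
  # onset at pulse start + LTP duration criterion (within one step)
  expect_lt(abs(ev$time - (20 + p$dur_p)), 0.1 + 1e-9)
  # events coincide with nonzero weight increments
  out <- update_weights(tr, p, w0 = 1, dt = 0.05)
  first_move <- out$time[min(which(diff(c(1, out$w)) != 0))]
  expect_lt(abs(first_move - ev$time), 0.05 + 1e-9)
})
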