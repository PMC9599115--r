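pulse_influx <- function(rate = 2, on_ms = 10, t_stop = 200, dt = 0.025) {
  n <- round(t_stop / dt)
  m <- matrix(0, 1, n)
  m[1, seq_len(round(on_ms / dt))] <- rate
  m
}

test_that("the resting state is the closed-form binding equilibrium", {
  cp <- calcium_params()
  rs <- resting_state(cp)
  kd <- cp$buf_koff / cp$buf_kon
  expect_equal(unname(rs$bound), cp$buf_tot * 0.05 / (0.05 + kd))
  expect_true(all(abs(rs$residual) < 1e-9))
  # doubling a buffer total doubles its bound calcium at fixed free calcium
  cp2 <- cp
  cp2$buf_tot <- 2 * cp$buf_tot
  expect_equal(unname(resting_state(cp2)$bound), 2 * unname(rs$bound))
})

test_that("the integrator holds the resting fixed point over one second", {
  cp <- calcium_params()
  g <- single_spine_geometry(params = cp)
  r <- step_calcium(g$geom, cp, t_stop = 1000, dt = 0.025, rec_dt = 100)
  expect_lt(max(abs(r$ca - cp$ca_rest) / cp$ca_rest), 1e-3)
})

test_that("total calcium is conserved with pumps and influx off", {
  cp <- calcium_params()
  g <- single_spine_geometry(params = cp)
  influx <- pulse_influx(rate = 2, on_ms = 10, t_stop = 1000)
  r <- step_calcium(g$geom, cp, influx_elem = g$spine_head_elem + 1L,
                    influx_rates = influx, t_stop = 1000, dt = 0.025,
                    rec_dt = 10, pumps_on = FALSE)
  m <- r$mass[r$time > 10] # after influx ends the system is closed
  expect_lt((max(m) - min(m)) / m[1], 1e-4)
})

test_that("a spine-head pulse reaches the dendritic shell delayed and attenuated", {
  cp <- calcium_params()
  g <- single_spine_geometry(params = cp)
  r <- step_calcium(g$geom, cp, influx_elem = g$spine_head_elem + 1L,
                    influx_rates = pulse_influx(), t_stop = 300, dt = 0.025,
                    rec_dt = 0.5)
  h <- r$ca[g$spine_head_elem + 1L, ]
  d <- r$ca[g$sub_elem[2], ]
  expect_gt(max(h) - cp$ca_rest, 10 * (max(d) - cp$ca_rest))
  expect_gt(r$time[which.max(d)], r$time[which.max(h)])
})

test_that("buffering reduces the peak: removing calbindin raises the spine transient", {
  cp <- calcium_params()
  b <- cp$buffers
  b$total[b$name == "calbindin"] <- 1e-3
  cp_no <- calcium_params(buffers = b)
  g <- single_spine_geometry(params = cp)
  g_no <- single_spine_geometry(params = cp_no)
  p_with <- max(step_calcium(g$geom, cp, g$spine_head_elem + 1L,
                             pulse_influx(), t_stop = 100,
                             dt = 0.025)$ca[g$spine_head_elem + 1L, ])
  p_without <- max(step_calcium(g_no$geom, cp_no, g_no$spine_head_elem + 1L,
                                pulse_influx(), t_stop = 100,
                                dt = 0.025)$ca[g_no$spine_head_elem + 1L, ])
  expect_gt(p_without, p_with)
})

test_that("a longer spine neck attenuates the dendritic transient", {
  cp <- calcium_params()
  peak_dend <- function(neck) {
    g <- single_spine_geometry(params = cp, neck_len_um = neck)
    r <- step_calcium(g$geom, cp, g$spine_head_elem + 1L, pulse_influx(),
                      t_stop = 300, dt = 0.025, rec_dt = 1)
    max(r$ca[g$sub_elem[2], ]) - cp$ca_rest
  }
  expect_gt(peak_dend(0.5), peak_dend(1.0))
})

test_that("halving the step changes the spine-head peak by less than 2 percent", {
  cp <- calcium_params()
  g <- single_spine_geometry(params = cp)
  f1 <- pulse_influx(dt = 0.025)
  f2 <- pulse_influx(dt = 0.0125)
  p1 <- max(step_calcium(g$geom, cp, g$spine_head_elem + 1L, f1,
                         t_stop = 200, dt = 0.025)$ca[g$spine_head_elem + 1L, ])
  p2 <- max(step_calcium(g$geom, cp, g$spine_head_elem + 1L, f2,
                         t_stop = 200, dt = 0.0125)$ca[g$spine_head_elem + 1L, ])
  expect_lt(abs(p2 - p1) / p1, 0.02)
})

test_that("a step too large for the stiff dynamics aborts with a diagnostic", {
  cp <- calcium_params()
  g <- single_spine_geometry(params = cp)
  expect_error(step_calcium(g$geom, cp, t_stop = 10, dt = 0.2), "dt")
})
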