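soma_only <- function() {
  m <- data.frame(segment_id = 1L, parent_id = 0L, length_um = 14,
                  diameter_um = 14, path_start_um = 0, path_mid_um = 0)
  class(m) <- c("morphology", "data.frame")
  m
}

test_that("a passive cell with no input stays at the leak reversal", {
  p <- neuron_params(spiking = FALSE)
  vt <- simulate_voltage(build_default_morphology(), params = p,
                         duration_s = 0.5, dt = 0.05, inhibition = FALSE,
                         rec_nodes = 1)
  expect_lt(max(abs(vt$v - p$Eleak)), 1e-9)
})

test_that("step-current charging of an isolated compartment matches the RC closed form", {
  p <- neuron_params(spiking = FALSE)
  vt <- simulate_voltage(soma_only(), params = p, duration_s = 0.3,
                         dt = 0.01, inhibition = FALSE,
                         iclamp = list(node = 1, amp = 0.01, on = 50,
                                       off = 300),
                         rec_nodes = 1, rec_dt = 0.5)
  area_m2 <- pi * 14^2 * 1e-12
  g_leak <- area_m2 / p$RM * 1e6          # uS
  tau <- p$RM * p$CM * 1000               # ms
  v_inf <- p$Eleak + 0.01 / g_leak
  t <- vt$time
  v_th <- ifelse(t <= 50, p$Eleak,
                 v_inf + (p$Eleak - v_inf) * exp(-(t - 50) / tau))
  expect_lt(max(abs(vt$v[1, ] - v_th)) / abs(v_inf - p$Eleak), 0.01)
})

test_that("a single synaptic event attenuates monotonically along the dendritic path", {
  m <- tiny_model()
  p <- neuron_params(spiking = FALSE)
  one <- c(list(0.1), rep(list(numeric(0)), 49))
  vs <- simulate_voltage(m$morph, m$spines, m$mapping, one, p,
                         duration_s = 0.3, inhibition = FALSE,
                         rec_nodes = seq_len(nrow(m$morph)), rec_dt = 0.1)
  peaks <- apply(vs$v, 1, max) - p$Eleak
  src_seg <- m$spines$segment_id[match(m$mapping$spine_id[1],
                                       m$spines$spine_id)]
  # walk from the source segment toward the soma: peaks must decrease
  chain <- src_seg
  while (m$morph$parent_id[chain[length(chain)]] > 0)
    chain <- c(chain, m$morph$parent_id[chain[length(chain)]])
  expect_true(all(diff(peaks[chain]) < 0))
  # and decrease again out along a different primary dendrite
  other_prim <- setdiff(which(m$morph$parent_id == 1), chain)[1]
  down <- other_prim
  repeat {
    nxt <- which(m$morph$parent_id == down[length(down)])[1]
    if (is.na(nxt)) break
    down <- c(down, nxt)
  }
  expect_true(all(diff(peaks[down]) < 0))
})

test_that("the NMDA magnesium block is sigmoidal, monotone, and open when depolarized", {
  v <- seq(-100, 50, by = 1)
  f <- nmda_open_fraction(v)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_lt(nmda_open_fraction(-70), 0.1)
  expect_gt(nmda_open_fraction(1000), 0.999)
  expect_gt(nmda_open_fraction(0), 5 * nmda_open_fraction(-70))
})

test_that("somatic spiking is dt-converged and in an in vivo-like range under the default trial", {
  m <- tiny_model()
  tt <- m$trial$times
  n1 <- simulate_voltage(m$morph, m$spines, m$mapping, tt, neuron_params(),
                         duration_s = 1, dt = 0.025, seed = 6,
                         rec_nodes = 1)
  n2 <- simulate_voltage(m$morph, m$spines, m$mapping, tt, neuron_params(),
                         duration_s = 1, dt = 0.0125, seed = 6,
                         rec_nodes = 1)
  expect_lte(abs(length(n1$spike_times) - length(n2$spike_times)), 1)
  expect_gte(length(n1$spike_times), 1)
  expect_lte(length(n1$spike_times), 15)
})

test_that("removing inhibition never decreases the somatic spike count", {
  m <- tiny_model()
  tt <- m$trial$times
  with_inh <- simulate_voltage(m$morph, m$spines, m$mapping, tt,
                               neuron_params(), duration_s = 1, seed = 6,
                               rec_nodes = 1)
  no_inh <- simulate_voltage(m$morph, m$spines, m$mapping, tt,
                             neuron_params(), duration_s = 1, seed = 6,
                             rec_nodes = 1, inhibition = FALSE)
  expect_gte(length(no_inh$spike_times), length(with_inh$spike_times))
})
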