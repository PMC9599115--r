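#' Reduced neuron model parameters
#'
#' Passive membrane constants, the minimal two-conductance spiking mechanism
#' of the soma, dual-exponential synaptic channels, and the lumped
#' high-voltage-activated calcium conductance. Passive values follow the
#' optimized spiny-projection-neuron constants (RM 6.02 ohm m^2, CM
#' 0.011 F/m^2, RA 1.3 ohm m); synaptic kinetics are typical corticostriatal
#' values from the slice literature, exposed here for configuration since
#' they are model inputs rather than outputs.
#'
#' @param RM membrane resistivity (ohm m^2)
#' @param CM specific capacitance (F/m^2)
#' @param RA axial resistivity (ohm m)
#' @param Eleak leak reversal / resting potential (mV)
#' @param spiking enable the somatic spiking mechanism
#' @param soma named list: fast inward conductance `gna` (uS), reversal
#'   `ena`, Boltzmann half-activation `vh_m` and slope `k_m` (mV);
#'   delayed outward `gk`, `ek`, `vh_n`, `k_n`, time constant `tau_n` (ms)
#' @param ampa,nmda,gaba named lists: `gmax` (uS), `tau_r`, `tau_d` (ms),
#'   `erev` (mV); `nmda` additionally `mg_mM`, `mg_K` (mM), `mg_vslope`
#'   (mV) for the magnesium block and `ca_fraction` (fraction of NMDA
#'   current carried by calcium)
#' @param vgcc named list: spine conductance `g_spine` (uS), dendritic
#'   density `dens` (uS/um^2), activation `vhalf`, `kslope` (mV),
#'   reversal `eca` (mV)
#' @param gaba_per_comp GABA-A synapses per dendritic compartment
#' @param fsi_rate_hz,ltsi_rate_hz inhibitory Poisson rates; FSI inputs
#'   target compartments within `fsi_max_dist_um` of the soma, LTSI inputs
#'   the rest
#' @param fsi_max_dist_um proximal/distal boundary (um)
#' @return a list of class `neuron_params`
#' @export
neuron_params <- function(RM = 6.02, CM = 0.011, RA = 1.3, Eleak = -85,
                          spiking = TRUE,
                          soma = list(gna = 2.0, ena = 50, vh_m = -29,
                                      k_m = 4, gk = 2.5, ek = -90,
                                      vh_n = -27, k_n = 4, tau_n = 2),
                          ampa = list(gmax = 0.00030, tau_r = 1.1,
                                      tau_d = 5.75, erev = 0),
                          nmda = list(gmax = 0.0023, tau_r = 2.2,
                                      tau_d = 115, erev = 0, mg_mM = 1,
                                      mg_K = 3.57, mg_vslope = 16.13,
                                      ca_fraction = 0.3),
                          gaba = list(gmax = 0.0019, tau_r = 0.5,
                                      tau_d = 10, erev = -75),
                          vgcc = list(g_spine = 0.0016, dens = 2e-6,
                                      vhalf = -20, kslope = 7, eca = 45),
                          gaba_per_comp = 4, fsi_rate_hz = 12,
                          ltsi_rate_hz = 8, fsi_max_dist_um = 80) {
  stopifnot(RM > 0, CM > 0, RA > 0)
  stopifnot(ampa$tau_d > ampa$tau_r, nmda$tau_d > nmda$tau_r,
            gaba$tau_d > gaba$tau_r)
  structure(list(RM = RM, CM = CM, RA = RA, Eleak = Eleak, spiking = spiking,
                 soma = soma, ampa = ampa, nmda = nmda, gaba = gaba,
                 vgcc = vgcc, gaba_per_comp = gaba_per_comp,
                 fsi_rate_hz = fsi_rate_hz, ltsi_rate_hz = ltsi_rate_hz,
                 fsi_max_dist_um = fsi_max_dist_um),
            class = "neuron_params")
}

#' NMDA receptor open fraction under magnesium block
#'
#' Single-exponential voltage-dependent block
#' `1 / (1 + [Mg]/K * exp(-V/s))`; monotone increasing in V, approaching 1
#' at depolarized potentials.
#'
#' @param v membrane potential (mV)
#' @param mg_mM magnesium concentration (mM)
#' @param mg_K block constant (mM)
#' @param mg_vslope voltage slope (mV)
#' @return open fraction in `[0, 1]`
#' @export
nmda_open_fraction <- function(v, mg_mM = 1, mg_K = 3.57, mg_vslope = 16.13) {
  1 / (1 + mg_mM / mg_K * exp(-v / mg_vslope))
}

# ---- cable assembly -------------------------------------------------------

# electrical constants per node; nodes = morphology rows then spine heads.
# Hines ordering (parent index < node index) holds by construction.
.build_cable <- function(morph, spines, params) {
  nm <- nrow(morph)
  ns <- if (is.null(spines)) 0L else nrow(spines)
  n <- nm + ns
  area <- pi * morph$diameter_um * morph$length_um # lateral, um^2
  area[1] <- pi * morph$diameter_um[1]^2           # soma: sphere equivalent
  cross <- pi * (morph$diameter_um / 2)^2
  cap <- area * params$CM * 1e-3                   # nF
  g_leak <- area / params$RM * 1e-6                # uS
  parent <- morph$parent_id                        # 1-based; 0 = none
  # axial conductance to parent: half-cylinder resistances in series
  g_ax <- numeric(nm)
  for (i in seq_len(nm)[-1]) {
    p <- parent[i]
    r <- params$RA * morph$length_um[i] / (2 * cross[i]) # ohm * 1e6
    if (p > 1) r <- r + params$RA * morph$length_um[p] / (2 * cross[p])
    g_ax[i] <- 1 / r                               # uS
  }
  if (ns > 0) {
    g <- attr(spines, "geometry")
    a_head <- pi * g$head_diam_um * g$head_len_um +
      pi * (g$head_diam_um / 2)^2 + pi * g$neck_diam_um * g$neck_len_um
    r_neck <- params$RA * g$neck_len_um / (pi * (g$neck_diam_um / 2)^2)
    cap <- c(cap, rep(a_head * params$CM * 1e-3, ns))
    g_leak <- c(g_leak, rep(a_head / params$RM * 1e-6, ns))
    parent <- c(parent, spines$segment_id)
    g_ax <- c(g_ax, rep(1 / r_neck, ns))
  }
  list(n = n, n_morph = nm, n_spine = ns, parent = as.integer(parent),
       cap = cap, g_leak = g_leak, e_leak = rep(params$Eleak, n),
       g_axial = g_ax, area = c(area, rep(NA_real_, ns)))
}

# synapse tables for the engine. Excitatory inputs: AMPA + NMDA pairs on
# spine heads carrying the mapped trains; inhibitory GABA-A on dendritic
# shafts, gaba_per_comp per compartment, FSI-driven proximally and
# LTSI-driven distally, active over the full duration.
.build_synapses <- function(morph, spines, mapping, train_times_s, params,
                            duration_s, seed, weights = NULL,
                            inhibition = TRUE) {
  nm <- nrow(morph)
  node <- integer(0); type <- integer(0); gmax <- numeric(0)
  tau_r <- numeric(0); tau_d <- numeric(0); erev <- numeric(0)
  events <- list()
  syn_spine <- integer(0) # spine row index carrying each synapse (0 = none)
  if (!is.null(mapping) && nrow(mapping) > 0) {
    if (is.null(weights)) weights <- rep(1, nrow(mapping))
    for (k in seq_len(nrow(mapping))) {
      srow <- match(mapping$spine_id[k], spines$spine_id)
      nd <- nm + srow
      tt <- train_times_s[[mapping$train_id[k]]] * 1000 # ms
      for (ch in c("ampa", "nmda")) {
        p <- params[[ch]]
        node <- c(node, nd)
        type <- c(type, if (ch == "nmda") 1L else 0L)
        gmax <- c(gmax, p$gmax * weights[k])
        tau_r <- c(tau_r, p$tau_r); tau_d <- c(tau_d, p$tau_d)
        erev <- c(erev, p$erev)
        events[[length(events) + 1]] <- tt
        syn_spine <- c(syn_spine, srow)
      }
    }
  }
  if (inhibition && params$gaba_per_comp > 0 && nm > 1) {
    gp <- params$gaba
    idx <- 0L
    for (comp in 2:nm) {
      proximal <- morph$path_mid_um[comp] <= params$fsi_max_dist_um
      rate <- if (proximal) params$fsi_rate_hz else params$ltsi_rate_hz
      for (j in seq_len(params$gaba_per_comp)) {
        idx <- idx + 1L
        tt <- generate_poisson_inhibition(rate, duration_s,
                                          seed = seed + 1000L + idx) * 1000
        node <- c(node, comp)
        type <- c(type, 2L)
        gmax <- c(gmax, gp$gmax)
        tau_r <- c(tau_r, gp$tau_r); tau_d <- c(tau_d, gp$tau_d)
        erev <- c(erev, gp$erev)
        events[[length(events) + 1]] <- tt
        syn_spine <- c(syn_spine, 0L)
      }
    }
  }
  ev <- unlist(events, use.names = FALSE)
  if (is.null(ev)) ev <- numeric(0)
  ptr <- c(0L, cumsum(vapply(events, length, 1L)))
  list(node = node, type = type, gmax = gmax, tau_r = tau_r, tau_d = tau_d,
       erev = erev, events = ev, ev_ptr = as.integer(ptr),
       syn_spine = syn_spine)
}

# full argument list for sim_core_cpp; calcium/plasticity parts optional
.assemble_sim <- function(morph, spines, mapping, train_times_s, params,
                          duration_s, dt = 0.025, seed = 1, weights = NULL,
                          inhibition = TRUE, ca = NULL, plast = NULL,
                          w0 = NULL, iclamp = NULL, rec_nodes = 1L,
                          rec_dt = 0.5, ca_rec_dt = 1, w_rec_dt = 1,
                          record_influx = FALSE) {
  cab <- .build_cable(morph, spines, params)
  syn <- .build_synapses(morph, spines, mapping, train_times_s, params,
                         duration_s, seed, weights, inhibition)
  soma_pars <- if (isTRUE(params$spiking))
    unlist(params$soma[c("gna", "ena", "vh_m", "k_m", "gk", "ek", "vh_n",
                         "k_n", "tau_n")]) else numeric(0)
  vg <- params$vgcc
  vgcc_g <- numeric(cab$n)
  if (cab$n_spine > 0)
    vgcc_g[cab$n_morph + seq_len(cab$n_spine)] <- vg$g_spine
  if (nrow(morph) > 1)
    vgcc_g[2:cab$n_morph] <- vg$dens * cab$area[2:cab$n_morph]
  ca_geom <- list(vol = numeric(0)); ca_pars <- list()
  node_ca_elem <- rep(-1L, cab$n); spine_head_elem <- integer(0)
  syn_ca_elem <- rep(-1L, length(syn$node))
  if (!is.null(ca)) {
    geom <- build_calcium_geometry(morph, spines, ca)
    ca_geom <- geom$geom
    ca_pars <- ca
    node_ca_elem <- geom$node_elem
    spine_head_elem <- geom$spine_head_elem
    nmda_idx <- which(syn$type == 1L)
    syn_ca_elem[nmda_idx] <- spine_head_elem[syn$syn_spine[nmda_idx]]
  }
  plast_vec <- if (!is.null(plast)) unlist(plast[c(
    "t_ad", "t_ap", "dur_d", "dur_p", "g_p", "g_pmax", "g_d", "g_dmax",
    "wmin", "wmax")]) else numeric(0)
  if (is.null(w0)) w0 <- rep(1, cab$n_spine)
  if (is.null(iclamp)) iclamp <- list(node = 0L, amp = 0, on = 0, off = 0)
  list(parent = cab$parent - 1L, cap = cab$cap, g_leak = cab$g_leak,
       e_leak = cab$e_leak, g_axial = cab$g_axial, v_init = params$Eleak,
       soma_index = 0L, soma_pars = as.numeric(soma_pars),
       syn_node = as.integer(syn$node - 1L), syn_type = as.integer(syn$type),
       syn_gmax = syn$gmax, syn_tau_r = syn$tau_r, syn_tau_d = syn$tau_d,
       syn_erev = syn$erev, syn_events = syn$events, syn_ev_ptr = syn$ev_ptr,
       nmda_pars = c(params$nmda$mg_mM, params$nmda$mg_K,
                     params$nmda$mg_vslope, params$nmda$ca_fraction),
       vgcc_g = vgcc_g, vgcc_pars = c(vg$eca, vg$vhalf, vg$kslope),
       iclamp_node = as.integer(iclamp$node - 1L), iclamp_amp = iclamp$amp,
       iclamp_on = iclamp$on, iclamp_off = iclamp$off, dt = dt,
       t_stop = duration_s * 1000,
       rec_nodes = as.integer(rec_nodes - 1L),
       rec_stride = max(1L, round(rec_dt / dt)), spike_thresh = 0,
       ca_geom = ca_geom, ca_pars = ca_pars,
       syn_ca_elem = as.integer(syn_ca_elem),
       node_ca_elem = as.integer(node_ca_elem),
       spine_head_elem = as.integer(spine_head_elem),
       ca_rec_stride = max(1L, round(ca_rec_dt / dt)),
       plast_pars = as.numeric(plast_vec), w0 = as.numeric(w0),
       w_rec_stride = max(1L, round(w_rec_dt / dt)),
       record_influx = record_influx, n_spine = cab$n_spine,
       n_morph = cab$n_morph)
}

.run_core <- function(a) {
  sim_core_cpp(a$parent, a$cap, a$g_leak, a$e_leak, a$g_axial, a$v_init,
               a$soma_index, a$soma_pars, a$syn_node, a$syn_type, a$syn_gmax,
               a$syn_tau_r, a$syn_tau_d, a$syn_erev, a$syn_events,
               a$syn_ev_ptr, a$nmda_pars, a$vgcc_g, a$vgcc_pars,
               a$iclamp_node, a$iclamp_amp, a$iclamp_on, a$iclamp_off, a$dt,
               a$t_stop, a$rec_nodes, a$rec_stride, a$spike_thresh, a$ca_geom,
               a$ca_pars, a$syn_ca_elem, a$node_ca_elem, a$spine_head_elem,
               a$ca_rec_stride, a$plast_pars, a$w0, a$w_rec_stride,
               a$record_influx)
}

#' Simulate membrane potential of the reduced neuron
#'
#' Integrates the cable equation on the compartment tree (soma, dendritic
#' segments, spine heads coupled through neck resistances) with leak,
#' synaptic and somatic spiking currents, using a fixed-step semi-implicit
#' (backward-Euler) update solved by the Hines tree algorithm.
#'
#' @param morph a `morphology`
#' @param spines a `spine_set` or `NULL`
#' @param mapping a `cluster_mapping` (train -> spine) or `NULL`
#' @param train_times_s list of spike-time vectors (s) indexed by train id,
#'   e.g. from [experiment_train_times()], or `NULL`
#' @param params a [neuron_params()]
#' @param duration_s simulated time (s)
#' @param dt integration step (ms), `<= 0.1`
#' @param seed seed for the inhibitory Poisson trains
#' @param inhibition generate GABA inputs?
#' @param weights synaptic weights per mapping row (default 1)
#' @param iclamp optional list `(node, amp, on, off)`: step current of
#'   `amp` nA into compartment `node` between `on` and `off` ms
#' @param rec_nodes compartment indices to record (default: soma and all
#'   spine heads)
#' @param rec_dt recording step (ms)
#' @return a `voltage_trace`: list with `time` (ms), `v` (matrix, recorded
#'   nodes x time), `rec_nodes`, `spike_times` (ms, somatic)
#' @export
simulate_voltage <- function(morph, spines = NULL, mapping = NULL,
                             train_times_s = NULL, params = neuron_params(),
                             duration_s = 1, dt = 0.025, seed = 1,
                             inhibition = TRUE, weights = NULL,
                             iclamp = NULL, rec_nodes = NULL, rec_dt = 0.5) {
  stopifnot(dt <= 0.1, dt > 0)
  if (is.null(rec_nodes)) {
    ns <- if (is.null(spines)) 0 else nrow(spines)
    rec_nodes <- c(1L, if (ns) nrow(morph) + seq_len(ns))
  }
  a <- .assemble_sim(morph, spines, mapping, train_times_s, params,
                     duration_s, dt = dt, seed = seed, weights = weights,
                     inhibition = inhibition, iclamp = iclamp,
                     rec_nodes = rec_nodes, rec_dt = rec_dt)
  r <- .run_core(a)
  structure(list(time = r$t_v, v = r$v, rec_nodes = rec_nodes,
                 spike_times = r$spike_times, dt = dt),
            class = "voltage_trace")
}
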