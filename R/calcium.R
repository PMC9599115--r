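#' Calcium dynamics parameters
#'
#' Kinetic constants for the mechanistic calcium model: mobile buffers
#' (calbindin and the N- and C-lobes of calmodulin), an endogenous immobile
#' buffer, Michaelis-Menten membrane pumps (PMCA everywhere, NCX restricted
#' to spines), and diffusion coefficients. Defaults are representative
#' values from the calcium-modeling literature, with buffer totals and pump
#' densities set so that synaptically driven spine-head transients during
#' active input are of order 0.1-1 µM, commensurate with the plasticity
#' thresholds; all are configurable.
#'
#' @param d_ca free-calcium diffusion coefficient (µm²/ms)
#' @param buffers data.frame with columns `name`, `total` (µM), `kon`
#'   (1/(µM ms)), `koff` (1/ms), `d` (µm²/ms; 0 = immobile)
#' @param pmca_vmax,pmca_km PMCA maximum surface flux density
#'   (1e-21 mol/(µm² ms)) and Michaelis constant (µM)
#' @param ncx_vmax,ncx_km NCX parameters (spines only)
#' @param ca_rest resting free calcium (µM)
#' @param shell_um thickness of the dendritic submembrane shell (µm)
#' @param react_substeps sub-steps of the stiff buffer-reaction stage per
#'   integration step (controls the operator-splitting error)
#' @param neck_slabs axial slabs in the spine neck
#' @return a list of class `calcium_params`
#' @export
calcium_params <- function(d_ca = 0.2,
                           buffers = data.frame(
                             name = c("calbindin", "cam_n", "cam_c",
                                      "immobile"),
                             total = c(160, 20, 20, 160),
                             kon = c(0.028, 0.77, 0.025, 0.247),
                             koff = c(0.0196, 16, 0.00925, 0.524),
                             d = c(0.028, 0.066, 0.066, 0)),
                           pmca_vmax = 0.035, pmca_km = 0.3, ncx_vmax = 0.035,
                           ncx_km = 1.0, ca_rest = 0.05, shell_um = 0.1,
                           neck_slabs = 2L, react_substeps = 8L) {
  stopifnot(all(buffers$total >= 0), all(buffers$kon > 0),
            all(buffers$koff > 0), pmca_vmax >= 0, pmca_km > 0,
            ncx_vmax >= 0, ncx_km > 0, ca_rest > 0)
  structure(list(d_ca = d_ca, buffers = buffers,
                 buf_tot = buffers$total, buf_kon = buffers$kon,
                 buf_koff = buffers$koff, buf_d = buffers$d,
                 pmca_vmax = pmca_vmax, pmca_km = pmca_km,
                 ncx_vmax = ncx_vmax, ncx_km = ncx_km, ca_rest = ca_rest,
                 shell_um = shell_um, neck_slabs = as.integer(neck_slabs),
                 react_substeps = as.integer(react_substeps)),
            class = "calcium_params")
}

#' Build the calcium compartment stack for a morphology with spines
#'
#' Each dendritic compartment hosting at least one spine gets concentric
#' radial shells (outermost = submembrane shell of thickness `shell_um`);
#' each spine gets one head slab and `neck_slabs` neck slabs coupled
#' axially from the head through the neck into the submembrane shell of its
#' dendritic compartment. Dendritic compartments without spines carry no
#' calcium stack (their transients do not feed any plasticity readout).
#'
#' @param morph a `morphology`
#' @param spines a `spine_set`
#' @param params a [calcium_params()]
#' @return list with `geom` (element volumes µm³, membrane areas µm²,
#'   spine flags, diffusion coupling pairs with area/distance factors),
#'   `node_elem` (per cable node, element receiving that node's VGCC
#'   influx; -1 none), `spine_head_elem` (per spine, head element index,
#'   0-based for the engine), and bookkeeping vectors
#' @export
build_calcium_geometry <- function(morph, spines, params = calcium_params()) {
  stopifnot(nrow(spines) >= 1)
  nm <- nrow(morph)
  vol <- numeric(0); area <- numeric(0); is_spine <- integer(0)
  pair_a <- integer(0); pair_b <- integer(0); pair_k <- numeric(0)
  node_elem <- rep(-1L, nm + nrow(spines))
  elem_label <- character(0)
  host <- sort(unique(spines$segment_id))
  sub_elem <- integer(nm) # submembrane element per hosting compartment
  for (comp in host) {
    r <- morph$diameter_um[comp] / 2
    L <- morph$length_um[comp]
    sh <- params$shell_um
    bounds <- if (r <= 1.5 * sh) c(r, 0) else if (r <= 4 * sh)
      c(r, r - sh, 0) else c(r, r - sh, (r - sh) / 2, 0)
    nsh <- length(bounds) - 1
    idx <- length(vol) + seq_len(nsh)
    for (s in seq_len(nsh)) {
      ro <- bounds[s]; ri <- bounds[s + 1]
      vol <- c(vol, pi * (ro^2 - ri^2) * L)
      area <- c(area, if (s == 1) 2 * pi * r * L else 0)
      is_spine <- c(is_spine, 0L)
      elem_label <- c(elem_label, sprintf("dend%d_shell%d", comp, s))
    }
    mids <- (bounds[-length(bounds)] + bounds[-1]) / 2
    if (nsh > 1) for (s in seq_len(nsh - 1)) {
      pair_a <- c(pair_a, idx[s]); pair_b <- c(pair_b, idx[s + 1])
      pair_k <- c(pair_k, 2 * pi * bounds[s + 1] * L / (mids[s] - mids[s + 1]))
    }
    sub_elem[comp] <- idx[1]
    node_elem[comp] <- idx[1]
  }
  g <- attr(spines, "geometry")
  rh <- g$head_diam_um / 2; lh <- g$head_len_um
  rn <- g$neck_diam_um / 2; ln <- g$neck_len_um
  nslab <- params$neck_slabs
  slab_len <- ln / nslab
  a_cross <- pi * rn^2
  spine_head_elem <- integer(nrow(spines))
  for (s in seq_len(nrow(spines))) {
    head <- length(vol) + 1L
    vol <- c(vol, pi * rh^2 * lh)
    area <- c(area, pi * g$head_diam_um * lh + pi * rh^2)
    is_spine <- c(is_spine, 1L)
    elem_label <- c(elem_label, sprintf("spine%d_head", s))
    spine_head_elem[s] <- head
    prev <- head; prev_half <- lh / 2
    for (q in seq_len(nslab)) {
      el <- length(vol) + 1L
      vol <- c(vol, a_cross * slab_len)
      area <- c(area, pi * g$neck_diam_um * slab_len)
      is_spine <- c(is_spine, 1L)
      elem_label <- c(elem_label, sprintf("spine%d_neck%d", s, q))
      pair_a <- c(pair_a, prev); pair_b <- c(pair_b, el)
      pair_k <- c(pair_k, a_cross / (prev_half + slab_len / 2))
      prev <- el; prev_half <- slab_len / 2
    }
    dend_el <- sub_elem[spines$segment_id[s]]
    pair_a <- c(pair_a, prev); pair_b <- c(pair_b, dend_el)
    pair_k <- c(pair_k, a_cross / (prev_half + params$shell_um / 2))
    node_elem[nm + s] <- spine_head_elem[s]
  }
  list(geom = list(vol = vol, area = area, is_spine = is_spine,
                   pair_a = as.integer(pair_a - 1L),
                   pair_b = as.integer(pair_b - 1L), pair_k = pair_k,
                   label = elem_label),
       node_elem = as.integer(node_elem - 1L),
       spine_head_elem = as.integer(spine_head_elem - 1L),
       sub_elem = sub_elem)
}

#' Resting state of the calcium system
#'
#' Closed-form binding equilibrium at the baseline free calcium
#' concentration: for each buffer, `bound = total * C / (C + koff/kon)`.
#' This is the fixed point at which the integrator starts; with pumps on, a
#' constant leak influx balancing extrusion at baseline keeps it invariant.
#'
#' @param params a [calcium_params()]
#' @param ca_free baseline free calcium (µM; default `params$ca_rest`)
#' @return list with `ca_free` and per-buffer `bound` (µM) and the residual
#'   binding flux at equilibrium (µM/ms, ~0)
#' @export
resting_state <- function(params = calcium_params(), ca_free = NULL) {
  if (is.null(ca_free)) ca_free <- params$ca_rest
  kd <- params$buf_koff / params$buf_kon
  bound <- params$buf_tot * ca_free / (ca_free + kd)
  resid <- params$buf_kon * ca_free * (params$buf_tot - bound) -
    params$buf_koff * bound
  list(ca_free = ca_free, bound = stats::setNames(bound,
                                                  params$buffers$name),
       residual = resid)
}

#' Advance the calcium system with prescribed influx
#'
#' Runs the operator-split integrator (influx, mass-action buffer reactions,
#' 1-D diffusion of free calcium and mobile buffers, Michaelis-Menten
#' extrusion) for a given geometry and an influx schedule, starting from the
#' resting state. Used directly for component-level experiments and tests;
#' the full neuron simulation drives the same integrator with currents from
#' the membrane model.
#'
#' @param geom geometry list (`$geom` from [build_calcium_geometry()], or a
#'   hand-built list with the same fields)
#' @param params a [calcium_params()]
#' @param influx_elem integer element indices (1-based) receiving influx
#' @param influx_rates matrix (length(influx_elem) x n steps) of influx
#'   rates (µM/ms), or `NULL`
#' @param t_stop duration (ms)
#' @param dt step (ms), `<= 0.05`
#' @param rec_dt recording step (ms)
#' @param pumps_on include pumps and their balancing leak?
#' @return list with `time` (ms), `ca` (elements x time, µM), `mass`
#'   (total free+bound calcium, µM µm³, per recorded time), `ca_final`,
#'   `bound_final`
#' @export
step_calcium <- function(geom, params = calcium_params(),
                         influx_elem = integer(0), influx_rates = NULL,
                         t_stop = 1000, dt = 0.025, rec_dt = 1,
                         pumps_on = TRUE) {
  stopifnot(dt <= 0.05, dt > 0)
  nsteps <- round(t_stop / dt)
  if (is.null(influx_rates))
    influx_rates <- matrix(0, length(influx_elem), 0)
  r <- calcium_run_cpp(geom, params, as.integer(influx_elem - 1L),
                       influx_rates, dt, nsteps,
                       max(1L, round(rec_dt / dt)), pumps_on)
  r$label <- geom$label
  r
}

#' Single-spine calcium geometry for component experiments
#'
#' One spine (head + neck) on one dendritic compartment, standalone.
#'
#' @param dend_diam_um,dend_len_um dendritic compartment dimensions
#' @param params a [calcium_params()]
#' @param neck_len_um optional neck length override (µm)
#' @return as [build_calcium_geometry()]
#' @export
single_spine_geometry <- function(dend_diam_um = 1.4, dend_len_um = 16,
                                  params = calcium_params(),
                                  neck_len_um = NULL) {
  morph <- data.frame(segment_id = 1:2, parent_id = c(0L, 1L),
                      length_um = c(14, dend_len_um),
                      diameter_um = c(14, dend_diam_um),
                      path_start_um = c(0, 0),
                      path_mid_um = c(0, dend_len_um / 2))
  class(morph) <- c("morphology", "data.frame")
  spines <- data.frame(spine_id = 1L, segment_id = 2L,
                       arc_pos_um = dend_len_um / 2,
                       path_distance_um = dend_len_um / 2)
  geometry <- list(head_diam_um = 0.5, head_len_um = 0.5,
                   neck_diam_um = 0.12,
                   neck_len_um = if (is.null(neck_len_um)) 0.5
                   else neck_len_um)
  attr(spines, "geometry") <- geometry
  class(spines) <- c("spine_set", "data.frame")
  build_calcium_geometry(morph, spines, params)
}
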