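#' Plasticity rule parameters
#'
#' The dual amplitude/duration calcium-threshold rule. Long-term depression
#' engages while spine calcium stays at or above the LTD amplitude threshold
#' `t_ad` (0.33 µM) but below the LTP threshold, for longer than the LTD
#' duration criterion `dur_d` (28 ms); long-term potentiation engages while
#' calcium stays at or above `t_ap` (0.53 µM) for longer than `dur_p`
#' (3.3 ms). While a branch is engaged the weight moves each time step by a
#' calcium-dependent, capped gain with soft bounds:
#' potentiation `dw = min(g_pmax, g_p (Ca - t_ap)) (1 - (w-wmin)/(wmax-wmin))`
#' and depression `dw = -min(g_dmax, g_d (Ca - t_ad)) (w-wmin)/(wmax-wmin)`,
#' so the weight asymptotes at `wmax` (2.0) and `wmin` (0).
#'
#' Gains are per millisecond (multiplied by the trace step each update, so
#' trajectories are step-size invariant); the defaults are set so that a
#' 100 ms plateau at 1.0 µM moves `w` from 1 by about +0.1.
#' Amplitude comparisons are closed (`>=`, with a 1 ns-scale guard against
#' floating-point ties) so a plateau at exactly the threshold engages the
#' branch with vanishing gain; duration criteria are strict (`>`).
#' Excursion timers are continuous: they reset whenever calcium drops below
#' the corresponding amplitude threshold.
#'
#' @param t_ad,t_ap LTD / LTP amplitude thresholds (µM), `t_ap > t_ad > 0`
#' @param dur_d,dur_p LTD / LTP duration thresholds (ms)
#' @param g_p,g_d gains (1/(ms µM)); `g_pmax`, `g_dmax` gain caps (1/ms)
#' @param wmin,wmax weight bounds
#' @return a list of class `plasticity_params`
#' @export
plasticity_params <- function(t_ad = 0.33, t_ap = 0.53, dur_d = 28,
                              dur_p = 3.3, g_p = 0.0044, g_pmax = 0.0066,
                              g_d = 0.002, g_dmax = 0.003, wmin = 0,
                              wmax = 2) {
  stopifnot(t_ap > t_ad, t_ad > 0, dur_d > 0, dur_p > 0, g_p > 0,
            g_pmax > 0, g_d > 0, g_dmax > 0, wmax > wmin)
  structure(list(t_ad = t_ad, t_ap = t_ap, dur_d = dur_d, dur_p = dur_p,
                 g_p = g_p, g_pmax = g_pmax, g_d = g_d, g_dmax = g_dmax,
                 wmin = wmin, wmax = wmax),
            class = "plasticity_params")
}

.plast_vec <- function(p)
  unlist(p[c("t_ad", "t_ap", "dur_d", "dur_p", "g_p", "g_pmax", "g_d",
             "g_dmax", "wmin", "wmax")])

#' Apply the plasticity rule to a calcium trace
#'
#' @param ca_trace numeric vector of spine calcium samples (µM) at fixed
#'   step `dt`, or a matrix (spines x time)
#' @param params a [plasticity_params()]
#' @param w0 initial weight(s) in `[wmin, wmax]`
#' @param dt trace step (ms)
#' @return a `weight_trace`: list with `time` (ms), `w` (same shape as
#'   input), `events` (data.frame time/synapse/direction of rule-engagement
#'   onsets, +1 potentiation, -1 depression), `w_final`
#' @export
update_weights <- function(ca_trace, params = plasticity_params(), w0 = 1,
                           dt = 0.1) {
  if (any(ca_trace < 0)) stop("calcium trace contains negative concentrations")
  stopifnot(all(w0 >= params$wmin), all(w0 <= params$wmax))
  pv <- .plast_vec(params)
  if (is.matrix(ca_trace)) {
    n <- nrow(ca_trace)
    w0 <- rep_len(w0, n)
    runs <- lapply(seq_len(n), function(i)
      weight_update_cpp(ca_trace[i, ], dt, pv, w0[i]))
    w <- do.call(rbind, lapply(runs, `[[`, "w"))
    ev <- do.call(rbind, lapply(seq_len(n), function(i) {
      r <- runs[[i]]
      if (!length(r$event_time)) return(NULL)
      data.frame(time = r$event_time, synapse = i, direction = r$event_sign)
    }))
    if (is.null(ev))
      ev <- data.frame(time = numeric(0), synapse = integer(0),
                       direction = integer(0))
    structure(list(time = seq_len(ncol(w)) * dt, w = w, events = ev,
                   w_final = w[, ncol(w)], dt = dt),
              class = "weight_trace")
  } else {
    r <- weight_update_cpp(as.numeric(ca_trace), dt, pv, w0)
    ev <- data.frame(time = r$event_time,
                     synapse = rep(1L, length(r$event_time)),
                     direction = r$event_sign)
    structure(list(time = seq_along(r$w) * dt, w = r$w, events = ev,
                   w_final = r$w[length(r$w)], dt = dt),
              class = "weight_trace")
  }
}

#' Detect plasticity events in a calcium trace
#'
#' Returns the onset of every contiguous period during which the rule's
#' potentiation or depression branch is engaged (amplitude and duration
#' criteria both met), with its direction.
#'
#' @inheritParams update_weights
#' @return data.frame with columns `time` (ms), `synapse`, `direction`
#' @export
detect_plasticity_events <- function(ca_trace, params = plasticity_params(),
                                     dt = 0.1, w0 = 1) {
  update_weights(ca_trace, params, w0 = w0, dt = dt)$events
}

#' Square calcium pulse on a resting baseline
#'
#' @param amplitude pulse amplitude (µM)
#' @param duration_ms pulse duration; the pulse occupies
#'   `round(duration_ms/dt)` samples
#' @param dt sample step (ms)
#' @param baseline resting concentration (µM)
#' @param pre_ms,post_ms baseline padding before and after
#' @return numeric vector of samples
#' @export
square_pulse_trace <- function(amplitude, duration_ms, dt = 0.05,
                               baseline = 0.05, pre_ms = 10, post_ms = 50) {
  n_pre <- round(pre_ms / dt); n_on <- round(duration_ms / dt)
  n_post <- round(post_ms / dt)
  c(rep(baseline, n_pre), rep(amplitude, n_on), rep(baseline, n_post))
}

#' Threshold recovery scans over square calcium pulses
#'
#' `scan_amplitude_threshold` feeds the rule square pulses of fixed duration
#' at amplitudes `step, 2 step, ...` and returns the smallest amplitude at
#' which the requested branch engages (produces a weight change; at the
#' boundary amplitude the change is vanishingly small since the gain is
#' proportional to the threshold excess, so engagement is detected from the
#' rule's event record rather than a floating-point weight comparison).
#' `scan_duration_threshold` feeds pulses of fixed amplitude at durations
#' `step, 2 step, ...` and returns the longest ineffective duration, i.e.
#' the duration strictly above which the branch engages.
#'
#' @param direction `"ltd"` or `"ltp"`
#' @param duration_ms fixed pulse duration for the amplitude scan (ms)
#' @param amplitude fixed pulse amplitude for the duration scan (µM)
#' @param step scan step (µM or ms)
#' @param max_value scan upper limit
#' @param params a [plasticity_params()]
#' @param dt trace step (ms)
#' @return the recovered threshold (µM or ms), or `NA` if never engaged
#' @export
scan_amplitude_threshold <- function(direction = c("ltd", "ltp"),
                                     duration_ms = 100, step = 0.01,
                                     max_value = 1.5,
                                     params = plasticity_params(),
                                     dt = 0.05) {
  direction <- match.arg(direction)
  want <- if (direction == "ltd") -1 else 1
  for (k in seq_len(round(max_value / step))) {
    amp <- k * step
    tr <- square_pulse_trace(amp, duration_ms, dt = dt)
    ev <- detect_plasticity_events(tr, params, dt = dt)
    if (any(ev$direction == want)) return(amp)
  }
  NA_real_
}

#' @rdname scan_amplitude_threshold
#' @export
scan_duration_threshold <- function(direction = c("ltd", "ltp"),
                                    amplitude = 0.4, step = 1,
                                    max_value = 100,
                                    params = plasticity_params(),
                                    dt = 0.05) {
  direction <- match.arg(direction)
  want <- if (direction == "ltd") -1 else 1
  for (k in seq_len(round(max_value / step))) {
    dur <- k * step
    tr <- square_pulse_trace(amplitude, dur, dt = dt)
    ev <- detect_plasticity_events(tr, params, dt = dt)
    if (any(ev$direction == want)) return(dur - step)
  }
  NA_real_
}
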