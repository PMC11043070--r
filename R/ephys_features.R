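#' Input resistance from hyperpolarizing current steps
#'
#' Least-squares slope of the steady-state voltage deflection against the
#' injected current over a train of hyperpolarizing steps (the 0 to -80 pA
#' in -10 pA protocol). The slope in mV/pA is a GOhm, reported in MOhm.
#'
#' @param steps Tibble with `current_pA` (all <= 0, at least two distinct
#'   levels) and `delta_v_mV` (steady-state deflection).
#' @return Input resistance in MOhm.
#' @export
#' @examples
#' input_resistance(tibble::tibble(current_pA = c(-10, -20, -30),
#'                                 delta_v_mV = c(-1, -2, -3))) # 100 MOhm
input_resistance <- function(steps) {
  i <- steps$current_pA
  v <- steps$delta_v_mV
  if (any(i > 0)) {
    stop_ghostmap("input-resistance steps must be hyperpolarizing (<= 0 pA)",
                  "ghostmap_value_error")
  }
  if (length(unique(i)) < 2) {
    stop_ghostmap("need >= 2 distinct current levels", "ghostmap_value_error")
  }
  unname(coef(lm(v ~ i))[2]) * 1000
}

# dV/dt in mV/ms for a regularly sampled trace (forward difference, last
# value repeated so the vector length matches).
dvdt_mv_per_ms <- function(time, voltage) {
  dt_ms <- diff(time) * 1000
  d <- diff(voltage) / dt_ms
  c(d, d[length(d)])
}

# Logical mask: TRUE where a sample is within +/- mask_ms of a point where
# dV/dt exceeds the spike criterion.
spike_mask <- function(time, voltage, dvdt_threshold = 20, mask_ms = 5) {
  fast <- which(dvdt_mv_per_ms(time, voltage) > dvdt_threshold)
  if (length(fast) == 0) {
    return(rep(FALSE, length(time)))
  }
  masked <- rep(FALSE, length(time))
  half <- mask_ms / 1000
  for (i in fast) {
    masked <- masked | abs(time - time[i]) <= half
  }
  masked
}

#' Resting membrane potential over a time window
#'
#' Mean voltage over the window after masking action potentials (samples
#' within `spike_mask_ms` of any dV/dt > `dvdt_threshold` crossing) and,
#' when a `current` column is present, samples drawn during monitor
#' pulses.
#'
#' @param trace Tibble with `time` (s), `voltage` (mV) and optionally
#'   `current` (pA).
#' @param window `c(start, end)` in seconds; must lie inside the
#'   recording.
#' @param params Ephys parameters ([ghost_config()]`$ephys`).
#' @return Mean membrane potential (mV).
#' @export
resting_potential <- function(trace, window,
                              params = ghost_config()$ephys) {
  params <- modify_defaults(ghost_config()$ephys, params %||% list())
  if (window[1] < min(trace$time) - 1e-9 ||
      window[2] > max(trace$time) + 1e-9) {
    stop_ghostmap("window extends beyond the recording",
                  "ghostmap_value_error")
  }
  inside <- trace$time >= window[1] & trace$time <= window[2]
  masked <- spike_mask(trace$time, trace$voltage,
                       params$dvdt_threshold, params$spike_mask_ms)
  keep <- inside & !masked
  if ("current" %in% names(trace)) {
    keep <- keep & trace$current == 0
  }
  if (!any(keep)) {
    stop_ghostmap("no usable samples in window after masking",
                  "ghostmap_value_error")
  }
  mean(trace$voltage[keep])
}

#' Rheobase and action-potential features from a current-step train
#'
#' Scans the sweeps of a step protocol for action potentials (dV/dt
#' exceeding the detection criterion). The rheobase is the lowest step
#' current with at least one spike; spike-shape features are measured on
#' the first spike of the rheobase sweep: threshold (voltage at the first
#' dV/dt crossing), amplitude (peak minus threshold), halfwidth (time
#' above threshold + amplitude/2, linearly interpolated), fAHP (threshold
#' minus the minimum within `fahp_window_ms` after the peak) and mAHP
#' (threshold minus the minimum in the `mahp_window_ms` window after the
#' peak).
#'
#' @param sweeps Tibble with `sweep`, `step_pA`, `time` (s), `voltage`
#'   (mV); step levels must form an arithmetic sequence.
#' @param params Ephys parameters ([ghost_config()]`$ephys`).
#' @return A one-row tibble: `rheobase_pA`, `threshold`, `amplitude`,
#'   `halfwidth_ms`, `fahp`, `mahp`, `has_spike`. When no step elicits a
#'   spike, `has_spike` is `FALSE` and the features are `NA` (flagged, not
#'   an error).
#' @export
rheobase_and_ap <- function(sweeps, params = ghost_config()$ephys) {
  params <- modify_defaults(ghost_config()$ephys, params %||% list())
  lv <- sort(unique(sweeps$step_pA))
  if (length(lv) > 2) {
    incr <- diff(lv)
    if (max(abs(incr - incr[1])) > 1e-6) {
      stop_ghostmap("step levels must form an arithmetic sequence",
                    "ghostmap_value_error")
    }
  }
  spiking <- sweeps |>
    dplyr::group_by(.data$sweep, .data$step_pA) |>
    dplyr::summarise(
      spike = any(dvdt_mv_per_ms(.data$time, .data$voltage) >
                    params$dvdt_threshold),
      .groups = "drop"
    )
  if (!any(spiking$spike)) {
    return(tibble::tibble(rheobase_pA = NA_real_, threshold = NA_real_,
                          amplitude = NA_real_, halfwidth_ms = NA_real_,
                          fahp = NA_real_, mahp = NA_real_,
                          has_spike = FALSE))
  }
  rheo <- min(spiking$step_pA[spiking$spike])
  sw <- sweeps[sweeps$step_pA == rheo, ]
  sw <- sw[order(sw$time), ]
  tt <- sw$time
  vv <- sw$voltage
  d <- dvdt_mv_per_ms(tt, vv)
  onset <- which(d > params$dvdt_threshold)[1]
  thr_v <- vv[onset]
  # peak: maximum within 10 ms of onset
  peak_win <- which(tt >= tt[onset] & tt <= tt[onset] + 0.010)
  peak <- peak_win[which.max(vv[peak_win])]
  amp <- vv[peak] - thr_v
  half_v <- thr_v + amp / 2
  cross_time <- function(i0, i1) {
    # linear interpolation of the half-level crossing between samples
    tt[i0] + (half_v - vv[i0]) / (vv[i1] - vv[i0]) * (tt[i1] - tt[i0])
  }
  up <- max(which(vv[seq_len(peak)] < half_v))
  after <- which(vv < half_v & seq_along(vv) > peak)[1]
  hw <- if (is.na(after) || up == peak) {
    NA_real_
  } else {
    (cross_time(after - 1L, after) - cross_time(up, up + 1L)) * 1000
  }
  t_peak <- tt[peak]
  fahp_win <- tt > t_peak & tt <= t_peak + params$fahp_window_ms / 1000
  mahp_win <- tt >= t_peak + params$mahp_window_ms[1] / 1000 &
    tt <= t_peak + params$mahp_window_ms[2] / 1000
  tibble::tibble(
    rheobase_pA = rheo,
    threshold = thr_v,
    amplitude = amp,
    halfwidth_ms = hw,
    fahp = if (any(fahp_win)) thr_v - min(vv[fahp_win]) else NA_real_,
    mahp = if (any(mahp_win)) thr_v - min(vv[mahp_win]) else NA_real_,
    has_spike = TRUE
  )
}
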