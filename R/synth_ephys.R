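#' Simulate a whole-cell recording cohort with known hormone responses
#'
#' Generates current-clamp traces spanning a hormone-application
#' experiment: a baseline segment ending at `application_onset`, then a
#' post-application segment in which the membrane potential is shifted by
#' the class-specific delta and the input resistance scaled by the
#' class-specific percentage change. Constant hyperpolarizing monitor
#' pulses (default -5 pA, 1 s every 10 s) are embedded throughout so the
#' input resistance can be measured from the voltage deflections before and
#' after application, as in longitudinal leptin/insulin challenge
#' recordings. Pulse deflections settle instantaneously (no membrane time
#' constant), so noiseless deltas equal the generating effect sizes exactly.
#'
#' @param n_per_class Named integer vector: recordings per ground-truth
#'   category, e.g. `c(activated = 8, inhibited = 9, nonresponsive = 7)`.
#' @param effect_sizes List with `activated` and `inhibited`, each
#'   `c(delta_rmp, delta_ri_pct)` in (mV, percent). The nonresponsive class
#'   is always (0, 0).
#' @param noise_sd Voltage noise sd in mV added to every sample.
#' @param rmp Mean resting membrane potential across cells (mV) and its
#'   between-cell sd, `c(mean, sd)`.
#' @param ri Mean input resistance across cells (MOhm) and its between-cell
#'   sd.
#' @param application_onset Hormone application time (s).
#' @param fs Sampling rate (Hz).
#' @param monitor_current Monitor pulse amplitude (pA, negative).
#' @param params Response-rule parameters ([ghost_config()]`$ephys`) used
#'   for the dead-zone warning and the window layout.
#' @param seed Integer seed.
#' @return List with `traces` (tibble `cell_id`, `time`, `voltage`,
#'   `current`) and `cells`, the ground truth (`cell_id`, `true_category`,
#'   `true_delta_rmp`, `true_delta_ri_pct`, `rmp`, `ri_pre`).
#' @export
gen_ephys_cohort <- function(n_per_class = c(activated = 8, inhibited = 9,
                                             nonresponsive = 7),
                             effect_sizes = list(
                               activated = c(delta_rmp = 4,
                                             delta_ri_pct = 15),
                               inhibited = c(delta_rmp = -4,
                                             delta_ri_pct = -15)
                             ),
                             noise_sd = 0,
                             rmp = c(-55, 3),
                             ri = c(1000, 100),
                             application_onset = 600,
                             fs = 50,
                             monitor_current = -5,
                             params = ghost_config()$ephys,
                             seed = 1) {
  stopifnot(all(names(n_per_class) %in%
                  c("activated", "inhibited", "nonresponsive")))
  deltas <- list(
    activated = unname(effect_sizes$activated),
    inhibited = unname(effect_sizes$inhibited),
    nonresponsive = c(0, 0)
  )
  for (cls in c("activated", "inhibited")) {
    n_cls <- n_per_class[cls]
    if (!is.na(n_cls) && n_cls > 0 && noise_sd == 0) {
      d <- deltas[[cls]]
      hit <- classify_response(d[1], d[2], params = params)
      if (hit != cls) {
        warn(sprintf(
          "%s effect size (%.3g mV, %.3g%%) lies inside the threshold dead-zone; ground truth would be nonresponsive",
          cls, d[1], d[2]
        ))
      }
    }
  }

  set.seed(seed)
  cats <- rep(names(n_per_class), n_per_class)
  n <- length(cats)
  if (n == 0) {
    return(list(
      traces = tibble::tibble(cell_id = character(), time = numeric(),
                              voltage = numeric(), current = numeric()),
      cells = tibble::tibble(cell_id = character(), true_category = character(),
                             true_delta_rmp = numeric(),
                             true_delta_ri_pct = numeric(),
                             rmp = numeric(), ri_pre = numeric())
    ))
  }
  cell_ids <- sprintf("cell%03d", seq_len(n))
  rmp_i <- rnorm(n, rmp[1], rmp[2])
  ri_i <- pmax(rnorm(n, ri[1], ri[2]), 50)

  t0 <- application_onset - 60
  t1 <- application_onset + params$post_offset + params$post_window + 10
  time <- seq(t0, t1, by = 1 / fs)
  # monitor pulse: 1 s on every 10 s, aligned to integer multiples of 10
  in_pulse <- (time %% 10) < 1
  current <- ifelse(in_pulse, monitor_current, 0)

  traces <- purrr::map_dfr(seq_len(n), function(i) {
    d <- deltas[[cats[i]]]
    post <- time > application_onset # effect begins strictly after onset
    ri_t <- ifelse(post, ri_i[i] * (1 + d[2] / 100), ri_i[i])
    v <- rmp_i[i] + ifelse(post, d[1], 0) +
      current * ri_t / 1000 + # pA * GOhm = mV
      if (noise_sd > 0) rnorm(length(time), 0, noise_sd) else 0
    tibble::tibble(cell_id = cell_ids[i], time = time, voltage = v,
                   current = current)
  })
  cells <- tibble::tibble(
    cell_id = cell_ids,
    true_category = cats,
    true_delta_rmp = vapply(cats, function(cl) deltas[[cl]][1], 1),
    true_delta_ri_pct = vapply(cats, function(cl) deltas[[cl]][2], 1),
    rmp = rmp_i,
    ri_pre = ri_i
  )
  list(traces = traces, cells = cells)
}

#' Simulate a current-step train with an idealised spike
#'
#' Builds the step protocol used for intrinsic characterisation: steps
#' starting at `start_pA` and incrementing by `delta_pA`, each of
#' `step_dur` seconds. Subthreshold steps deflect the voltage by
#' `I x Ri` (instantaneous settling); at and above the true rheobase a
#' single idealised piecewise-linear action potential is inserted: a slow
#' 5 ms approach ramp to `threshold` (below the dV/dt detection criterion),
#' a fast linear rise to `peak`, a fall to the fast-AHP trough `fahp_v`,
#' recovery to the step baseline, and a shallow medium-AHP excursion to
#' `mahp_v` centred at `mahp_t_ms` after the peak. All extracted features
#' (threshold, amplitude, halfwidth, fAHP, mAHP) therefore have closed-form
#' expected values; see [ap_expected_features()].
#'
#' @param true_rheobase_pA Smallest current (pA) that elicits the spike.
#' @param start_pA,delta_pA,n_steps Step-protocol layout.
#' @param rmp Resting potential (mV).
#' @param ri Input resistance (MOhm).
#' @param ap Spike shape: named list `threshold` and `peak` (absolute mV),
#'   `rise_ms`, `fall_ms`, absolute trough voltages `fahp_v` and `mahp_v`
#'   (mV), `mahp_t_ms` (trough time after the peak), `recover_ms` (time to
#'   regain the step baseline after the fast trough) and `mahp_span_ms`
#'   (half-width of the medium excursion). `fahp_v` and `mahp_v` must lie
#'   below the step baseline at rheobase for the window minima to be the
#'   troughs.
#' @param fs Sampling rate (Hz).
#' @param step_dur Step duration (s).
#' @param onset Spike onset time within the step (s).
#' @param seed Integer seed (noise only).
#' @param noise_sd Voltage noise sd (mV).
#' @return Tibble with `sweep`, `step_pA`, `time`, `voltage`.
#' @export
gen_step_train <- function(true_rheobase_pA = 40,
                           start_pA = -60, delta_pA = 10, n_steps = 15,
                           rmp = -60, ri = 150,
                           ap = list(threshold = -40, peak = 20,
                                     rise_ms = 1, fall_ms = 1.5,
                                     fahp_v = -58, mahp_v = -56,
                                     mahp_t_ms = 120, recover_ms = 30,
                                     mahp_span_ms = 60),
                           fs = 20000, step_dur = 0.5, onset = 0.1,
                           seed = 1, noise_sd = 0) {
  set.seed(seed)
  steps <- start_pA + delta_pA * (seq_len(n_steps) - 1L)
  time <- seq(0, step_dur, by = 1 / fs)
  purrr::map_dfr(seq_along(steps), function(s) {
    i_pa <- steps[s]
    base <- rmp + i_pa * ri / 1000
    v <- rep(base, length(time))
    if (i_pa >= true_rheobase_pA) {
      ms <- 1e-3
      # knot times (s) and voltages of the piecewise-linear waveform
      t_thr <- onset + 5 * ms
      t_peak <- t_thr + ap$rise_ms * ms
      t_fahp <- t_peak + ap$fall_ms * ms
      t_rec <- t_fahp + ap$recover_ms * ms
      t_m0 <- t_peak + (ap$mahp_t_ms - ap$mahp_span_ms) * ms
      t_m1 <- t_peak + ap$mahp_t_ms * ms
      t_m2 <- t_peak + (ap$mahp_t_ms + ap$mahp_span_ms) * ms
      knots_t <- c(0, onset, t_thr, t_peak, t_fahp, t_rec,
                   t_m0, t_m1, t_m2, step_dur)
      knots_v <- c(base, base, ap$threshold, ap$peak, ap$fahp_v, base,
                   base, ap$mahp_v, base, base)
      v <- stats::approx(knots_t, knots_v, xout = time, rule = 2)$y
    }
    if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
    tibble::tibble(sweep = s, step_pA = i_pa, time = time, voltage = v)
  })
}

#' Closed-form action-potential features of the idealised spike
#'
#' Expected values of the features extracted by [rheobase_and_ap()] for a
#' spike generated by [gen_step_train()], derived analytically from the
#' piecewise-linear waveform (used as an independent oracle in tests).
#'
#' @param ap Spike-shape list as in [gen_step_train()].
#' @return Tibble with `threshold`, `amplitude`, `halfwidth_ms`, `fahp`,
#'   `mahp`.
#' @export
ap_expected_features <- function(ap) {
  vh <- ap$threshold + (ap$peak - ap$threshold) / 2
  up <- ap$rise_ms * (ap$peak - vh) / (ap$peak - ap$threshold)
  down <- ap$fall_ms * (ap$peak - vh) / (ap$peak - ap$fahp_v)
  tibble::tibble(
    threshold = ap$threshold,
    amplitude = ap$peak - ap$threshold,
    halfwidth_ms = up + down,
    fahp = ap$threshold - ap$fahp_v,
    mahp = ap$threshold - ap$mahp_v
  )
}
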