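#' Pre/post hormone deltas from a monitored recording
#'
#' Computes the change in resting membrane potential and input resistance
#' across a hormone application. The membrane potential is averaged over a
#' `pre_window`-second window ending at the application onset and a
#' `post_window`-second window starting `post_offset` seconds after it
#' (spike-masked, monitor-pulse samples excluded). The input resistance in
#' each phase is taken from the embedded constant hyperpolarizing monitor
#' pulses: `Ri = (mean V during pulses - mean V between pulses) / I`,
#' using pulses before the onset (pre) and at/after the post window
#' opening (post).
#'
#' @param trace Single-cell tibble with `time` (s), `voltage` (mV),
#'   `current` (pA; non-zero during monitor pulses).
#' @param application_onset Hormone application time (s).
#' @param params Ephys parameters ([ghost_config()]`$ephys`).
#' @return One-row tibble: `delta_rmp` (mV), `delta_ri_pct` (%),
#'   `rmp_pre`, `rmp_post`, `ri_pre`, `ri_post` (MOhm).
#' @export
response_deltas <- function(trace, application_onset,
                            params = ghost_config()$ephys) {
  params <- modify_defaults(ghost_config()$ephys, params %||% list())
  if (!"current" %in% names(trace)) {
    stop_ghostmap("trace must carry a current column with monitor pulses",
                  "ghostmap_value_error")
  }
  pre_win <- c(application_onset - params$pre_window, application_onset)
  post_win <- application_onset + params$post_offset +
    c(0, params$post_window)
  rmp_pre <- resting_potential(trace, pre_win, params)
  rmp_post <- resting_potential(trace, post_win, params)

  ri_phase <- function(win) {
    inside <- trace$time >= win[1] & trace$time <= win[2]
    pulse <- inside & trace$current != 0
    flat <- inside & trace$current == 0
    if (!any(pulse) || !any(flat)) {
      stop_ghostmap(
        sprintf("no monitor pulse inside window [%.1f, %.1f] s",
                win[1], win[2]),
        "ghostmap_value_error"
      )
    }
    i_pa <- mean(trace$current[pulse])
    deflect <- mean(trace$voltage[pulse]) - mean(trace$voltage[flat])
    deflect / i_pa * 1000 # mV/pA = GOhm -> MOhm
  }
  ri_pre <- ri_phase(pre_win)
  ri_post <- ri_phase(post_win)
  if (ri_pre == 0) {
    stop_ghostmap("Ri_pre is zero: percentage change undefined",
                  "ghostmap_value_error")
  }
  tibble::tibble(
    delta_rmp = rmp_post - rmp_pre,
    delta_ri_pct = 100 * (ri_post - ri_pre) / ri_pre,
    rmp_pre = rmp_pre, rmp_post = rmp_post,
    ri_pre = ri_pre, ri_post = ri_post
  )
}

#' Classify a hormone response as activated, inhibited or non-responsive
#'
#' The responsiveness rule: a cell is `activated` when the membrane
#' potential rises by at least the voltage threshold (default +2 mV) AND
#' the input resistance changes by at least the percentage threshold in
#' magnitude (default 10%); `inhibited` when the potential falls by at
#' least the threshold with the same resistance gate; `nonresponsive`
#' otherwise. Both boundaries are inclusive. The resistance criterion uses
#' the magnitude of the change; `combine_rule = "or"` relaxes the
#' conjunction for sensitivity analyses.
#'
#' @param delta_rmp Membrane-potential change(s), mV (post - pre).
#' @param delta_ri_pct Input-resistance change(s), percent.
#' @param params Ephys parameters ([ghost_config()]`$ephys`).
#' @return Character vector: `activated`, `inhibited` or `nonresponsive`.
#' @export
#' @examples
#' classify_response(c(2, -3, 1.9), c(12, -11, 50))
classify_response <- function(delta_rmp, delta_ri_pct,
                              params = ghost_config()$ephys) {
  params <- modify_defaults(ghost_config()$ephys, params %||% list())
  stopifnot(is.finite(delta_rmp), is.finite(delta_ri_pct))
  ri_ok <- abs(delta_ri_pct) >= params$delta_ri_threshold_pct
  up <- delta_rmp >= params$delta_rmp_threshold
  down <- delta_rmp <= -params$delta_rmp_threshold
  if (identical(params$combine_rule, "or")) {
    dplyr::case_when(up | (ri_ok & delta_rmp > 0) ~ "activated",
                     down | (ri_ok & delta_rmp < 0) ~ "inhibited",
                     TRUE ~ "nonresponsive")
  } else {
    dplyr::case_when(up & ri_ok ~ "activated",
                     down & ri_ok ~ "inhibited",
                     TRUE ~ "nonresponsive")
  }
}

#' Run the response pipeline over a recorded cohort
#'
#' Applies [response_deltas()] and [classify_response()] to every cell of
#' a multi-cell trace table.
#'
#' @param traces Tibble with `cell_id`, `time`, `voltage`, `current`.
#' @param application_onset Hormone application time (s).
#' @param params Ephys parameters.
#' @return Tibble with one row per cell: the deltas and the `category`.
#' @export
call_hormone_responses <- function(traces, application_onset,
                                   params = ghost_config()$ephys) {
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ response_deltas(.x, application_onset, params)) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = classify_response(.data$delta_rmp,
                                               .data$delta_ri_pct,
                                               params))
}

#' Chi-squared test of response-category distributions between populations
#'
#' Pearson chi-squared (no continuity correction) on a population x
#' category count table, with the per-population percentage breakdown
#' integer-rounded for reporting (half away from zero, so counts of
#' 8/9/7 print as 33/38/29).
#'
#' @param counts Matrix of non-negative integer counts, populations in
#'   rows, categories in columns (dimnames recommended).
#' @return Object of class `contingency_test`: `chi2`, `df`, `p` and the
#'   `percentages` tibble.
#' @export
#' @examples
#' m <- rbind(pomc = c(activated = 8, inhibited = 9, nonresponsive = 7),
#'            ghost = c(5, 2, 17))
#' response_contingency_test(m)
response_contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0) || any(rowSums(counts) == 0)) {
    stop_ghostmap("degenerate margin: a row or column total is zero",
                  "ghostmap_value_error")
  }
  res <- pearson_chisq(counts)
  rn <- rownames(counts) %||% paste0("pop", seq_len(nrow(counts)))
  cn <- colnames(counts) %||% paste0("cat", seq_len(ncol(counts)))
  pct <- purrr::map_dfr(seq_len(nrow(counts)), function(r) {
    tibble::tibble(
      population = rn[r],
      category = cn,
      n = as.integer(counts[r, ]),
      pct = as.numeric(100 * counts[r, ] / sum(counts[r, ])),
      pct_int = as.numeric(percent_shares(counts[r, ]))
    )
  })
  structure(
    list(chi2 = res$chi2, df = res$df, p = res$p, counts = counts,
         percentages = pct),
    class = "contingency_test"
  )
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("<contingency_test> chi2(%d) = %.4g, p = %.4g\n",
              x$df, x$chi2, x$p))
  print(x$percentages)
  invisible(x)
}

#' @export
tidy.contingency_test <- function(x, ...) {
  x$percentages
}

#' @export
glance.contingency_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}

#' Monte-Carlo permutation p-value for a contingency table
#'
#' Reference null for the chi-squared test: tables drawn with fixed
#' margins (`r2dtable`), p = (1 + #\{chi2* >= chi2\}) / (B + 1).
#'
#' @param counts Count matrix.
#' @param n_draws Number of null tables.
#' @param seed Integer seed.
#' @return Permutation p-value.
#' @export
permutation_chisq_p <- function(counts, n_draws = 1e5, seed = 1) {
  counts <- as.matrix(counts)
  obs <- pearson_chisq(counts)$chi2
  set.seed(seed)
  sims <- r2dtable(n_draws, rowSums(counts), colSums(counts))
  exp_tab <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- vapply(sims, function(tb) sum((tb - exp_tab)^2 / exp_tab), 1)
  (1 + sum(stat >= obs - 1e-12)) / (n_draws + 1)
}
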