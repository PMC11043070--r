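test_that("input resistance follows Ohm's law and the regression oracle", {
  expect_equal(
    input_resistance(tibble::tibble(current_pA = c(-10, -20, -30),
                                    delta_v_mV = c(-1, -2, -3))),
    100
  )
  # noiseless 9-step 0..-80 pA train at a true 150 MOhm
  steps <- tibble::tibble(current_pA = seq(0, -80, by = -10))
  steps$delta_v_mV <- steps$current_pA * 150 / 1000
  expect_equal(input_resistance(steps), 150)

  expect_error(input_resistance(tibble::tibble(current_pA = c(-10, -10),
                                               delta_v_mV = c(-1, -1))),
               class = "ghostmap_value_error")
  expect_error(input_resistance(tibble::tibble(current_pA = c(-10, 10),
                                               delta_v_mV = c(-1, 1))),
               class = "ghostmap_value_error")

  # with voltage noise the estimator is unbiased and its sd matches the
  # closed-form regression-slope standard error
  set.seed(15)
  i_pa <- seq(0, -80, by = -10)
  sims <- replicate(1000, {
    input_resistance(tibble::tibble(
      current_pA = i_pa,
      delta_v_mV = i_pa * 150 / 1000 + rnorm(9, 0, 0.2)
    ))
  })
  se_theory <- 0.2 / sqrt(sum((i_pa - mean(i_pa))^2)) * 1000
  expect_lt(abs(mean(sims) - 150), 1)
  expect_lt(abs(sd(sims) - se_theory) / se_theory, 0.15)
})

test_that("resting potential averages the window with spikes and pulses masked", {
  flat <- tibble::tibble(time = seq(0, 60, by = 0.01), voltage = -60)
  expect_equal(resting_potential(flat, c(10, 40)), -60)

  set.seed(16)
  noisy <- flat
  noisy$voltage <- -60 + rnorm(nrow(flat), 0, 0.5)
  expect_lt(abs(resting_potential(noisy, c(0, 30)) + 60), 0.05)

  # superimposed spikes shift the naive mean but not the masked mean
  spiky <- flat
  for (t0 in seq(5, 50, by = 5)) {
    idx <- which(flat$time >= t0 & flat$time <= t0 + 0.002)
    spiky$voltage[idx] <- 20
  }
  expect_gt(mean(spiky$voltage[spiky$time >= 0 & spiky$time <= 60]), -60)
  expect_equal(resting_potential(spiky, c(0, 60)), -60, tolerance = 0.1)

  expect_error(resting_potential(flat, c(10, 100)),
               class = "ghostmap_value_error")
})

test_that("rheobase and spike-shape features match the analytic waveform", {
  ap <- list(threshold = -40, peak = 20, rise_ms = 1, fall_ms = 1.5,
             fahp_v = -58, mahp_v = -56, mahp_t_ms = 120, recover_ms = 30,
             mahp_span_ms = 60)
  st <- gen_step_train(true_rheobase_pA = 40, ap = ap, seed = 1)
  feat <- rheobase_and_ap(st)
  expected <- ap_expected_features(ap)
  expect_true(feat$has_spike)
  expect_equal(feat$rheobase_pA, 40)
  # sampling at 20 kHz resolves the piecewise-linear spike to ~0.3 mV /
  # ~0.1 ms
  expect_lt(abs(feat$threshold - expected$threshold), 0.5)
  expect_lt(abs(feat$amplitude - expected$amplitude), 1)
  expect_lt(abs(feat$halfwidth_ms - expected$halfwidth_ms), 0.15)
  expect_lt(abs(feat$fahp - expected$fahp), 0.5)
  expect_lt(abs(feat$mahp - expected$mahp), 0.5)

  # rheobase is a multiple of the step increment by construction
  expect_equal(feat$rheobase_pA %% 10, 0)

  # all-subthreshold protocol is flagged, not an error
  quiet <- gen_step_train(true_rheobase_pA = 1e6, n_steps = 5, seed = 1)
  expect_false(rheobase_and_ap(quiet)$has_spike)

  bad <- st
  bad$step_pA[bad$sweep == 2] <- -55 # breaks the arithmetic sequence
  expect_error(rheobase_and_ap(bad), class = "ghostmap_value_error")
})

test_that("response deltas are exact on noiseless traces and unbiased under noise", {
  coh <- gen_ephys_cohort(n_per_class = c(activated = 1), noise_sd = 0,
                          seed = 2)
  d <- response_deltas(coh$traces, 600)
  expect_equal(d$delta_rmp, 4)
  expect_equal(d$delta_ri_pct, 15)

  # identical pre/post: a nonresponsive cell gives (0, 0)
  coh0 <- gen_ephys_cohort(n_per_class = c(nonresponsive = 1),
                           noise_sd = 0, seed = 3)
  d0 <- response_deltas(coh0$traces, 600)
  expect_equal(d0$delta_rmp, 0)
  expect_equal(d0$delta_ri_pct, 0)

  # CLT check: delta_rmp sd ~ sqrt(2) * noise_sd / sqrt(n_window_samples)
  set.seed(17)
  deltas <- vapply(1:100, function(s) {
    coh <- gen_ephys_cohort(n_per_class = c(nonresponsive = 1),
                            noise_sd = 0.3, fs = 20, seed = 1000 + s)
    response_deltas(coh$traces, 600)$delta_rmp
  }, 1)
  n_flat <- 30 * 20 * 0.9 # pulse duty cycle removes ~10% of samples
  sd_theory <- sqrt(2) * 0.3 / sqrt(n_flat)
  expect_lt(abs(mean(deltas)), 3 * sd_theory / sqrt(100))
  expect_lt(abs(sd(deltas) - sd_theory) / sd_theory, 0.35)
})

test_that("the response rule is inclusive at its boundaries, total and monotone", {
  expect_equal(classify_response(2.0, 12), "activated")
  expect_equal(classify_response(-3.0, -11), "inhibited")
  expect_equal(classify_response(1.9, 50), "nonresponsive")
  expect_equal(classify_response(2.0, 9.9), "nonresponsive")
  expect_equal(classify_response(-2.0, -10), "inhibited")

  # vectorised and total on a grid
  grid <- expand.grid(drmp = seq(-5, 5, by = 0.5),
                      dri = seq(-30, 30, by = 5))
  calls <- classify_response(grid$drmp, grid$dri)
  expect_true(all(calls %in% c("activated", "inhibited", "nonresponsive")))

  # monotone in |delta_rmp| beyond the Ri gate: once activated at some
  # delta, any larger delta is still activated
  for (dri in c(10, 25)) {
    along <- classify_response(seq(0, 6, by = 0.25), rep(dri, 25))
    first_act <- match("activated", along)
    expect_true(all(along[first_act:25] == "activated"))
  }

  # OR variant relaxes the conjunction
  or_params <- modifyList(ghost_config()$ephys, list(combine_rule = "or"))
  expect_equal(classify_response(3, 0, params = or_params), "activated")
  expect_equal(classify_response(3, 0), "nonresponsive")
})

test_that("noisy cohorts are classified back to ground truth at >= 95% over seeds", {
  agree <- vapply(1:10, function(s) {
    coh <- gen_ephys_cohort(noise_sd = 0.3, fs = 20, seed = s)
    calls <- call_hormone_responses(coh$traces, 600)
    truth <- coh$cells$true_category[match(calls$cell_id,
                                           coh$cells$cell_id)]
    mean(calls$category == truth)
  }, 1)
  expect_gte(mean(agree), 0.95)
})

test_that("contingency test matches chisq.test, its permutation null and the printed shares", {
  leptin <- rbind(pomc = c(activated = 8, inhibited = 9, nonresponsive = 7),
                  ghost = c(5, 2, 17))
  res <- response_contingency_test(leptin)
  ref <- suppressWarnings(chisq.test(leptin, correct = FALSE))
  expect_equal(res$chi2, unname(ref$statistic))
  expect_equal(res$df, 2L)
  expect_equal(res$p, ref$p.value)

  p_perm <- permutation_chisq_p(leptin, n_draws = 2e4, seed = 5)
  expect_lt(abs(p_perm - res$p), 0.015)

  pomc_pct <- res$percentages[res$percentages$population == "pomc", ]
  expect_equal(pomc_pct$pct_int, c(33, 38, 29))
  ghost_pct <- res$percentages[res$percentages$population == "ghost", ]
  expect_equal(ghost_pct$pct_int[ghost_pct$category == "nonresponsive"], 71)

  same <- rbind(a = c(10, 10, 10), b = c(10, 10, 10))
  res0 <- response_contingency_test(same)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  expect_error(response_contingency_test(rbind(c(0, 5), c(0, 3))),
               class = "ghostmap_value_error")
})
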