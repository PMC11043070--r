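test_that("segmentation recovers every planted cell in 2D and 3D", {
  sim <- gen_image_stack(shape = c(96, 96, 24), n_cells = 30,
                         ghost_fraction = 0.1, seed = 2)
  seg3 <- segment_cells_3d(sim$stack, "reporter")
  expect_equal(nrow(seg3$cells), 30L)

  # detected 3D centroids match ground truth within one voxel
  # (greedy nearest matching; fixtures guarantee separation)
  d <- as.matrix(stats::dist(rbind(
    as.matrix(seg3$cells[, c("x", "y", "z")]),
    as.matrix(sim$cells[, c("x", "y", "z")])
  )))[seq_len(30), 30 + seq_len(30)]
  nearest <- apply(d, 1, min)
  expect_true(all(nearest <= sqrt(3)))
  expect_equal(as.integer(sort(apply(d, 1, which.min))), seq_len(30)) # 1-1 matching

  # 2D mode needs cells whose xy projections also stay disjoint
  sim2d <- gen_image_stack(shape = c(96, 96, 24), n_cells = 30,
                           ghost_fraction = 0.1, separate_in_xy = TRUE,
                           seed = 2)
  seg2 <- segment_cells_2d(sim2d$stack, "reporter")
  expect_equal(nrow(seg2$cells), 30L)
  expect_true(all(seg2$cells$z == 12)) # projected z = stack mid-plane

  # a sub-threshold speck is removed by the size filter
  tiny <- array(0, dim = c(16, 16, 4))
  tiny[8, 8, 2] <- 100; tiny[8, 9, 2] <- 100
  stack <- image_stack(list(reporter = tiny))
  seg <- segment_cells_2d(stack, "reporter",
                          params = list(threshold_method = "fixed",
                                        fixed_threshold = 50,
                                        min_size = 10))
  expect_equal(nrow(seg$cells), 0L)

  expect_error(segment_cells_3d(sim$stack, "nope"),
               class = "ghostmap_value_error")
})

test_that("ROI quantification equals the brute-force per-voxel oracle", {
  set.seed(4)
  arr <- array(runif(20^3, 0, 100), dim = c(20, 20, 20))
  mask <- array(FALSE, dim = dim(arr))
  mask[3:6, 3:6, 3:6] <- TRUE
  mask[12:15, 12:15, 12:15] <- TRUE
  labels <- label_components(mask)
  stack <- image_stack(list(reporter = (mask * 100) + 1, sig = arr))
  seg <- segment_cells_3d(stack, "reporter",
                          params = list(threshold_method = "fixed",
                                        fixed_threshold = 50, min_size = 1))
  ct <- quantify_rois(stack, seg)
  oracle <- brute_force_quantify(arr, seg$labels)
  expect_equal(sort(ct$mean_sig), sort(oracle$mean), tolerance = 1e-9)
  expect_equal(sort(ct$max_sig), sort(oracle$max), tolerance = 1e-9)

  # uniform ROI: mean = max = value
  expect_true(all(abs(ct$mean_reporter - 101) < 1e-12))
})

test_that("lineage classification recovers the ghost fraction and is monotone", {
  sim <- gen_image_stack(
    shape = c(128, 128, 32), n_cells = 200, ghost_fraction = 0.10,
    channels = list(reporter = list(typical = 150, ghost = 150, noise_sd = 5),
                    pomc = list(typical = 120, ghost = 0, noise_sd = 5)),
    seed = 11
  )
  seg <- segment_cells_3d(sim$stack, "reporter")
  ct <- quantify_rois(sim$stack, seg)
  cl <- classify_lineage_cells(ct)
  ghost_pct <- 100 * mean(cl$class_label == "ghost")
  expect_lt(abs(ghost_pct - 10), 2)
  expect_true(is.finite(attr(cl, "pomc_threshold")))

  # zero intensity with any positive fixed threshold -> ghost
  one <- tiny_cell_table(1)
  one$mean_pomc <- 0
  expect_equal(
    classify_lineage_cells(one, rule = list(type = "fixed", value = 5))$class_label,
    "ghost"
  )

  # monotone: raising the threshold never decreases the ghost count
  thr_grid <- seq(0, 200, by = 20)
  counts <- vapply(thr_grid, function(th) {
    sum(classify_lineage_cells(ct, rule = list(type = "fixed", value = th))$class_label == "ghost")
  }, 1L)
  expect_true(all(diff(counts) >= 0))

  # degenerate constant input -> all typical with a warning
  flat <- tiny_cell_table(5)
  flat$mean_pomc <- 7
  expect_warning(res <- classify_lineage_cells(flat), "degenerate")
  expect_true(all(res$class_label == "typical"))
})

test_that("marker positivity uses an inclusive boundary and recovers true rates", {
  ct <- tiny_cell_table(3)
  ct$max_glipr1 <- c(10, 9.999, 20)
  called <- call_marker_positivity(ct, "glipr1", threshold = 10)
  expect_identical(called$marker_glipr1, c(TRUE, FALSE, TRUE))

  # threshold above every value -> all negative
  none <- call_marker_positivity(ct, "glipr1", threshold = 1e9)
  expect_false(any(none$marker_glipr1))

  expect_error(call_marker_positivity(ct, "unknown", 1),
               "available", class = "ghostmap_value_error")

  # binomial recovery: true co-positivity rate 0.30 at n = 500
  set.seed(9)
  coh <- tiny_cell_table(500)
  pos <- rbinom(500, 1, 0.30) == 1
  coh$max_lepr <- ifelse(pos, 50, 5)
  called <- call_marker_positivity(coh, "lepr", threshold = 25)
  expect_lt(abs(mean(called$marker_lepr) - 0.30), 0.04 + 0.02)
})

test_that("cohort summaries pool sections first and report integer shares", {
  ghosts <- tiny_cell_table(10)
  ghosts$cell_id <- paste0("g", seq_len(10))
  cells <- dplyr::bind_rows(tiny_cell_table(90), ghosts)
  cells$class_label <- rep(c("typical", "ghost"), c(90, 10))
  s <- summarize_cohort(cells, by = "group")
  expect_equal(s$pct[s$class_label == "ghost"], 10)

  # pooling sections is additive: (60+30 typical, 5+5 ghost) over two
  # sections equals pooling counts before dividing
  two_sec <- tiny_cell_table(100)
  two_sec$section_id <- rep(c("s1", "s2"), c(65, 35))
  two_sec$class_label <- "typical"
  two_sec$class_label[c(61:65, 96:100)] <- "ghost"
  s2 <- summarize_cohort(two_sec, by = "group")
  expect_equal(s2$pct[s2$class_label == "ghost"], 10)

  # integer shares follow the half-up rule: 8/9/7 -> 33/38/29
  expect_equal(percent_shares(c(8, 9, 7)), c(33, 38, 29))

  # an animal without lineage-positive cells is dropped with a warning
  lost <- tiny_cell_table(5)
  lost$animal_id <- "a2"
  lost$lineage_positive <- FALSE
  lost$class_label <- "unassigned"
  both <- dplyr::bind_rows(cells, lost)
  expect_warning(summarize_cohort(both, by = "group"), "a2")
})

test_that("group comparison and covariate correlation behave at their edges and under simulation", {
  pa <- tibble::tibble(group = rep(c("CD", "HFD"), each = 3),
                       pct = c(1, 2, 3, 1, 2, 3))
  res <- compare_groups(pa, "pct")
  expect_equal(res$test$statistic, 0)
  expect_equal(res$test$p, 1)
  expect_error(
    compare_groups(tibble::tibble(group = c("a", "a", "b"), pct = 1:3), "pct"),
    class = "ghostmap_value_error"
  )

  # two-group power at a 2-sd separation, n = 20 per group
  set.seed(5)
  rej <- vapply(seq_len(300), function(i) {
    df <- tibble::tibble(group = rep(c("a", "b"), each = 20),
                         y = c(rnorm(20, 0), rnorm(20, 2)))
    compare_groups(df, "y", "group")$test$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.99)

  # three equal-mean groups: ANOVA type-I error near nominal
  set.seed(6)
  rej0 <- vapply(seq_len(600), function(i) {
    df <- tibble::tibble(group = rep(c("a", "b", "c"), each = 8),
                         y = rnorm(24))
    compare_groups(df, "y", "group")$test$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej0) - 0.05), 0.03)

  # exact linear covariate -> r = 1; too-few pairs -> error
  pa2 <- tibble::tibble(pct = 1:5, bw = 2 * (1:5))
  expect_equal(correlate_with_covariate(pa2, "pct", "bw")$r, 1)
  expect_error(
    correlate_with_covariate(pa2[1:2, ], "pct", "bw"),
    class = "ghostmap_value_error"
  )
  pa2$flat <- 3
  expect_error(correlate_with_covariate(pa2, "pct", "flat"),
               class = "ghostmap_value_error")
})
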