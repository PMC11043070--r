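test_that("normalisation is log counts-per-10k, scale-invariant, and matches a reference", {
  m <- matrix(c(1, 0, 0), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), "c1"))
  norm <- normalize_counts(m)
  expect_equal(unname(norm[, 1]), c(log1p(1e4), 0, 0))

  # doubling a cell's counts leaves its normalised vector unchanged
  m2 <- matrix(rpois(20, 5) + 1, nrow = 5,
               dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  doubled <- m2
  doubled[, 2] <- m2[, 2] * 2
  expect_equal(normalize_counts(m2)[, 2], normalize_counts(doubled)[, 2])

  # independent two-line reference on a 5 x 4 fixture
  ref <- log1p(t(t(m2) / colSums(m2)) * 1e4)
  expect_equal(normalize_counts(m2), ref, tolerance = 1e-12)

  bad <- m2
  bad[, 3] <- 0
  expect_error(normalize_counts(bad), "c3", class = "ghostmap_value_error")
})

test_that("Leiden + silhouette recovers well-separated clusters and the degenerate null", {
  cm <- gen_count_matrix(list(a = 60, b = 60, c = 60), n_genes = 200,
                         markers_per_cluster = 10, marker_fold = 8,
                         baseline_mean = 2, dispersion = 2, seed = 1)
  norm <- normalize_counts(cm)
  cr <- cluster_cells(norm, seed = 1)
  expect_equal(cr$n_clusters, 3L)
  expect_gte(adjusted_rand_index(cr$labels$cluster,
                                 cm$cell_meta$true_cluster), 0.9)
  # selected resolution attains the maximum recorded silhouette
  sil <- cr$silhouette_by_resolution
  expect_equal(cr$resolution_selected,
               min(sil$resolution[which(sil$silhouette ==
                                          max(sil$silhouette, na.rm = TRUE))]))

  # structureless matrix: the degenerate rule returns one cluster
  flat <- gen_count_matrix(list(a = 40, b = 40), n_genes = 100,
                           marker_fold = 1, seed = 2)
  cr_flat <- cluster_cells(normalize_counts(flat), seed = 1)
  expect_equal(cr_flat$n_clusters, 1L)

  # cell-order invariance at a fixed seed
  perm <- sample(ncol(norm))
  cr_perm <- cluster_cells(norm[, perm], seed = 1)
  merged <- dplyr::left_join(cr$labels, cr_perm$labels, by = "cell")
  expect_equal(adjusted_rand_index(merged$cluster.x, merged$cluster.y), 1)

  expect_error(cluster_cells(norm[, 1:5]), class = "ghostmap_value_error")
})

test_that("relative expression has the right signs and matches brute force", {
  set.seed(20)
  norm <- matrix(rnorm(10 * 30, 5, 1), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
  labels <- rep(c(1, 2, 3), each = 10)
  norm["g1", labels == 1] <- norm["g1", labels == 1] + 10 # only cluster 1

  rel <- relative_expression(norm, labels)
  g1 <- rel[rel$gene == "g1", ]
  expect_gt(g1$rel_expr[g1$cluster == 1], 0)
  expect_true(all(g1$rel_expr[g1$cluster != 1] < 0))

  # brute-force oracle: per-entry group means
  for (cl in 1:3) {
    for (g in c("g1", "g5")) {
      expect_equal(
        rel$rel_expr[rel$cluster == cl & rel$gene == g],
        mean(norm[g, labels == cl]) - mean(norm[g, labels != cl]),
        tolerance = 1e-12
      )
    }
  }

  # identical expression everywhere -> all zeros
  flat <- matrix(3, nrow = 4, ncol = 12,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:12)))
  rel0 <- relative_expression(flat, rep(1:2, each = 6))
  expect_true(all(rel0$rel_expr == 0))
})

test_that("marker panel scores rank program-depleted clusters lowest", {
  panel <- paste0("pomcgene", 1:10)
  hits <- vapply(1:10, function(s) {
    cm <- fig4_fixture(seed = s)
    norm <- normalize_counts(cm)
    # k below the smallest expected cluster so the kNN graph can isolate it
    cr <- cluster_cells(norm, params = list(knn_k = 5), seed = s)
    ps <- marker_panel_score(norm, cr, panel)
    ranked <- ps$scores[order(ps$scores$score), ]
    low2 <- ranked$cluster[1:2]
    truth_map <- vapply(
      split(cm$cell_meta$true_cluster, cr$labels$cluster),
      function(v) names(sort(table(v), decreasing = TRUE))[1], ""
    )
    cr$n_clusters >= 3 &&
      setequal(unname(truth_map[as.character(low2)]), c("c", "d"))
  }, TRUE)
  expect_gte(sum(hits), 9)

  # uniform expression with the full gene panel scores zero everywhere
  flat <- matrix(2, nrow = 5, ncol = 10,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  ps0 <- marker_panel_score(flat, rep(1:2, each = 5), paste0("g", 1:5))
  expect_true(all(ps0$scores$score == 0))

  # a missing panel gene is reported, not fatal; none present is an error
  ps1 <- marker_panel_score(flat, rep(1:2, each = 5), c("g1", "absent"))
  expect_equal(ps1$genes_missing, "absent")
  expect_error(marker_panel_score(flat, rep(1:2, each = 5), "nope"),
               class = "ghostmap_value_error")
})

test_that("cluster QC reports totals and organelle fractions faithfully", {
  cm <- gen_count_matrix(list(a = 30, b = 30), n_genes = 100,
                         n_mito_genes = 0, seed = 4)
  qc <- cluster_qc(cm, cm$cell_meta$true_cluster)
  expect_true(all(qc$per_cluster$mean_mito_frac == 0))

  # half the genes mitochondrial at equal means -> mito fraction ~ 0.5
  cm2 <- gen_count_matrix(list(a = 60), n_genes = 100, n_mito_genes = 50,
                          markers_per_cluster = 0, marker_fold = 1,
                          seed = 5)
  qc2 <- cluster_qc(cm2, rep(1, 60))
  expect_lt(abs(qc2$per_cluster$mean_mito_frac - 0.5), 0.02)

  # equal generating totals: ANOVA on totals is calibrated near 0.05
  set.seed(21)
  rej <- vapply(seq_len(300), function(i) {
    cmn <- gen_count_matrix(list(a = 20, b = 20), n_genes = 60,
                            marker_fold = 1, seed = 3000 + i)
    qcn <- cluster_qc(cmn, cmn$cell_meta$true_cluster)
    qcn$anova$p[qcn$anova$metric == "total"] < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("composition shift detects an enrichment and matches its permutation null", {
  # identical composition: chi2 = 0, p = 1
  labs <- rep(c("a", "b"), each = 40)
  cond <- rep(rep(c("CD", "HFD"), each = 20), 2)
  cs0 <- composition_shift(labs, cond)
  expect_equal(cs0$chi2, 0)
  expect_equal(cs0$p, 1)

  # 4 clusters x 2 conditions -> df = 3
  cs_df <- composition_shift(rep(letters[1:4], each = 10),
                             rep(c("CD", "HFD"), 20))
  expect_equal(cs_df$df, 3L)

  # power: cluster d at 5% of CD vs 25% of HFD cells, n = 500/500
  set.seed(22)
  rej <- vapply(seq_len(200), function(i) {
    cd <- sample(c("a", "d"), 500, replace = TRUE, prob = c(0.95, 0.05))
    hfd <- sample(c("a", "d"), 500, replace = TRUE, prob = c(0.75, 0.25))
    composition_shift(c(cd, hfd),
                      rep(c("CD", "HFD"), each = 500))$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.99)

  # chi-squared p agrees with the fixed-margin permutation null
  cm <- fig4_fixture(seed = 3)
  cr <- cluster_cells(normalize_counts(cm),
                      params = list(knn_k = 5), seed = 3)
  cs <- composition_shift(cr, cm$cell_meta$condition)
  p_perm <- permutation_chisq_p(cs$counts, n_draws = 2e4, seed = 7)
  expect_lt(abs(cs$p - p_perm), 0.02)

  expect_error(composition_shift(labs, rep("CD", 80)),
               class = "ghostmap_value_error")
})
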