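#' Relative expression of genes per cluster
#'
#' The heatmap statistic behind cluster characterisation: for every
#' cluster and gene, the mean normalised expression inside the cluster
#' minus the mean over all other cells (a log-scale difference; positive
#' means enriched in the cluster).
#'
#' @param normalized Genes x cells matrix from [normalize_counts()].
#' @param labels Per-cell cluster labels (vector aligned with columns, or
#'   the `labels` tibble of a [cluster_cells()] result).
#' @param genes Genes to report (default: all).
#' @return Tidy tibble: `cluster`, `gene`, `rel_expr`.
#' @export
relative_expression <- function(normalized, labels, genes = NULL) {
  labels <- as_label_vector(labels, colnames(normalized))
  if (length(unique(labels)) < 2) {
    stop_ghostmap("need >= 2 clusters for relative expression",
                  "ghostmap_value_error")
  }
  genes <- genes %||% rownames(normalized)
  missing <- setdiff(genes, rownames(normalized))
  genes <- intersect(genes, rownames(normalized))
  m <- normalized[genes, , drop = FALSE]
  out <- purrr::map_dfr(sort(unique(labels)), function(cl) {
    inside <- labels == cl
    tibble::tibble(
      cluster = cl,
      gene = genes,
      rel_expr = as.numeric(rowMeans(m[, inside, drop = FALSE]) -
                              rowMeans(m[, !inside, drop = FALSE]))
    )
  })
  attr(out, "missing_genes") <- missing
  out
}

as_label_vector <- function(labels, cells) {
  if (inherits(labels, "cluster_result")) {
    labels <- labels$labels
  }
  if (is.data.frame(labels)) {
    labels <- labels$cluster[match(cells, labels$cell)]
  }
  if (length(labels) != length(cells)) {
    stop_ghostmap("labels do not align with the matrix columns",
                  "ghostmap_value_error")
  }
  labels
}

#' Mean relative expression of a marker panel per cluster
#'
#' Averages [relative_expression()] over a panel of identity genes (e.g.
#' an atlas-derived neuron-type-specific panel); clusters that have lost
#' the program score lowest. Panel genes absent from the matrix are
#' reported, not an error, as long as at least one is present.
#'
#' @inheritParams relative_expression
#' @param panel Character vector of panel gene names.
#' @return Object of class `panel_score`: per-cluster `score` tibble,
#'   per-gene values, and the genes found/missing.
#' @export
marker_panel_score <- function(normalized, labels, panel) {
  found <- intersect(panel, rownames(normalized))
  if (length(found) == 0) {
    stop_ghostmap("no panel gene present in the matrix",
                  "ghostmap_value_error")
  }
  per_gene <- relative_expression(normalized, labels, genes = found)
  scores <- per_gene |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(score = mean(.data$rel_expr),
                     n_genes = dplyr::n(), .groups = "drop")
  structure(
    list(scores = scores, per_gene = per_gene, genes_found = found,
         genes_missing = setdiff(panel, found)),
    class = "panel_score"
  )
}

#' @export
print.panel_score <- function(x, ...) {
  cat(sprintf("<panel_score> %d panel gene(s)%s\n", length(x$genes_found),
              if (length(x$genes_missing))
                paste0(", missing: ",
                       paste(x$genes_missing, collapse = ", "))
              else ""))
  print(x$scores)
  invisible(x)
}

#' @export
tidy.panel_score <- function(x, ...) {
  x$scores
}

#' Per-cluster quality-control summary
#'
#' Checks that clusters are not artefacts of technical covariates: per
#' cluster, the mean and sd of per-cell total counts and the mean
#' mitochondrial and ribosomal count fractions, with a one-way ANOVA
#' p-value across clusters for each metric.
#'
#' @param x A [count_matrix] with populated gene flags.
#' @param labels Per-cell cluster labels (vector, tibble or
#'   [cluster_cells()] result).
#' @return List with `per_cluster` tibble and `anova` tibble
#'   (`metric`, `p`).
#' @export
cluster_qc <- function(x, labels) {
  stopifnot(inherits(x, "count_matrix"))
  labels <- as_label_vector(labels, colnames(x$counts))
  totals <- colSums(x$counts)
  mito <- colSums(x$counts[x$gene_flags$is_mito, , drop = FALSE]) /
    pmax(totals, 1)
  ribo <- colSums(x$counts[x$gene_flags$is_ribo, , drop = FALSE]) /
    pmax(totals, 1)
  df <- tibble::tibble(cluster = labels, total = totals,
                       mito_frac = mito, ribo_frac = ribo)
  per_cluster <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_total = mean(.data$total), sd_total = sd(.data$total),
      mean_mito_frac = mean(.data$mito_frac),
      mean_ribo_frac = mean(.data$ribo_frac),
      .groups = "drop"
    )
  anova_p <- function(v) {
    if (length(unique(df$cluster)) < 2 || sd(v) == 0) {
      return(NA_real_)
    }
    summary(aov(v ~ factor(df$cluster)))[[1]][["Pr(>F)"]][1]
  }
  list(
    per_cluster = per_cluster,
    anova = tibble::tibble(
      metric = c("total", "mito_frac", "ribo_frac"),
      p = c(anova_p(df$total), anova_p(df$mito_frac),
            anova_p(df$ribo_frac))
    )
  )
}

#' Cluster-composition shift between conditions
#'
#' Tests whether cells of two diet conditions distribute differently over
#' the clusters: the percentage of each condition's cells per cluster and
#' a Pearson chi-squared test on the cluster x condition count table
#' (df = (clusters - 1)(conditions - 1)).
#'
#' @param labels Per-cell cluster labels.
#' @param condition Per-cell condition (e.g. CD/HFD), aligned with
#'   `labels`.
#' @return Object of class `composition_shift`: `chi2`, `df`, `p`, the
#'   count table and the percentage tibble.
#' @export
composition_shift <- function(labels, condition) {
  if (inherits(labels, "cluster_result")) {
    labels <- labels$labels$cluster
  }
  if (length(labels) != length(condition)) {
    stop_ghostmap("labels and condition must align", "ghostmap_value_error")
  }
  conds <- unique(condition)
  if (length(conds) < 2) {
    stop_ghostmap("both conditions must be present", "ghostmap_value_error")
  }
  tab <- table(cluster = labels, condition = condition)
  if (any(colSums(tab) == 0)) {
    stop_ghostmap("a condition has 0 cells", "ghostmap_value_error")
  }
  res <- pearson_chisq(tab)
  pct <- purrr::map_dfr(colnames(tab), function(cd) {
    tibble::tibble(
      condition = cd,
      cluster = rownames(tab),
      n = as.integer(tab[, cd]),
      pct = 100 * tab[, cd] / sum(tab[, cd])
    )
  })
  structure(
    list(chi2 = res$chi2, df = res$df, p = res$p,
         counts = unclass(tab), percentages = pct),
    class = "composition_shift"
  )
}

#' @export
print.composition_shift <- function(x, ...) {
  cat(sprintf("<composition_shift> chi2(%d) = %.4g, p = %.4g\n",
              x$df, x$chi2, x$p))
  print(tidyr::pivot_wider(x$percentages[, c("condition", "cluster", "pct")],
                           names_from = "condition", values_from = "pct"))
  invisible(x)
}

#' @export
tidy.composition_shift <- function(x, ...) {
  x$percentages
}

#' @export
glance.composition_shift <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}
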