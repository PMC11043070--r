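#' Simulate a patch-seq count matrix with known cluster structure
#'
#' Draws a negative-binomial gene x cell count matrix in which each cluster
#' carries a disjoint block of marker genes whose mean is multiplied by
#' `marker_fold`, and an optional highly expressed identity-gene program
#' (e.g. the Pomc-specific panel) that is divided by `depletion_fold` in
#' designated ghost-like clusters. Cells are split between two diet
#' conditions per cluster, so composition shifts between conditions can be
#' simulated exactly. The negative binomial is parameterised by mean `mu`
#' and dispersion `size` with variance `mu + mu^2/size`.
#'
#' @param n_cells_per_cluster Named list or vector: per-cluster cell
#'   counts. Each element is either a single total or a named pair
#'   `c(CD = , HFD = )`.
#' @param n_genes Number of background genes (markers and program genes are
#'   drawn from this pool).
#' @param markers_per_cluster Number of marker genes per cluster.
#' @param baseline_mean Negative-binomial mean of a background gene.
#' @param marker_fold Fold change of a cluster's markers inside that
#'   cluster (>= 1).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param pomc_program Optional list `list(genes = , depleted_in = ,
#'   depletion_fold = , program_mean = )`: gene names (created if absent
#'   from the background pool), clusters in which the program is depleted,
#'   the depletion fold, and the undepleted program mean (default
#'   `8 * baseline_mean`).
#' @param n_mito_genes,n_ribo_genes Number of genes given mitochondrial
#'   (`mt-`) / ribosomal (`Rps`) name prefixes for QC summaries.
#' @param seed Integer seed.
#' @return A [count_matrix] whose `cell_meta` carries `condition`,
#'   `preselect_label` (ghost for cells of program-depleted clusters) and
#'   the ground-truth `true_cluster`.
#' @export
#' @examples
#' cm <- gen_count_matrix(list(a = 30, b = 30), n_genes = 50, seed = 1)
#' dim(cm)
gen_count_matrix <- function(n_cells_per_cluster,
                             n_genes = 200,
                             markers_per_cluster = 20,
                             baseline_mean = 2,
                             marker_fold = 8,
                             dispersion = 10,
                             pomc_program = NULL,
                             n_mito_genes = 0L,
                             n_ribo_genes = 0L,
                             seed = 1) {
  if (marker_fold < 1 || dispersion <= 0 || baseline_mean <= 0) {
    stop_ghostmap(
      "marker_fold must be >= 1; baseline_mean and dispersion must be > 0",
      "ghostmap_value_error"
    )
  }
  sizes <- lapply(n_cells_per_cluster, function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      c(CD = ceiling(x / 2), HFD = floor(x / 2))
    } else {
      c(CD = unname(x["CD"]), HFD = unname(x["HFD"]))
    }
  })
  clusters <- names(sizes) %||% paste0("k", seq_along(sizes))
  names(sizes) <- clusters
  totals <- vapply(sizes, sum, 1)
  if (any(totals == 0)) {
    stop_ghostmap(
      paste0("cluster requested with 0 cells in both conditions: ",
             paste(clusters[totals == 0], collapse = ", ")),
      "ghostmap_value_error"
    )
  }

  gene_names <- paste0("gene", seq_len(n_genes))
  if (n_mito_genes > 0) {
    gene_names[seq_len(n_mito_genes)] <-
      paste0("mt-g", seq_len(n_mito_genes))
  }
  if (n_ribo_genes > 0) {
    idx <- n_mito_genes + seq_len(n_ribo_genes)
    gene_names[idx] <- paste0("Rps", seq_len(n_ribo_genes))
  }
  prog_genes <- character(0)
  if (!is.null(pomc_program)) {
    prog_genes <- pomc_program$genes
    gene_names <- union(gene_names, prog_genes)
  }
  n_genes_all <- length(gene_names)

  # per-cluster mean matrix
  mu <- matrix(baseline_mean, n_genes_all, length(clusters),
               dimnames = list(gene_names, clusters))
  non_special <- setdiff(gene_names, prog_genes)
  marker_pool <- tail(non_special,
                      markers_per_cluster * length(clusters))
  for (k in seq_along(clusters)) {
    mk <- marker_pool[(k - 1L) * markers_per_cluster +
                        seq_len(markers_per_cluster)]
    mk <- mk[!is.na(mk)]
    mu[mk, k] <- baseline_mean * marker_fold
  }
  depleted <- character(0)
  if (!is.null(pomc_program)) {
    program_mean <- pomc_program$program_mean %||% (8 * baseline_mean)
    depletion_fold <- pomc_program$depletion_fold %||% 4
    if (depletion_fold < 1) {
      stop_ghostmap("depletion_fold must be >= 1", "ghostmap_value_error")
    }
    depleted <- pomc_program$depleted_in %||% character(0)
    mu[prog_genes, ] <- program_mean
    mu[prog_genes, intersect(depleted, clusters)] <-
      program_mean / depletion_fold
  }

  set.seed(seed)
  blocks <- list()
  meta <- list()
  for (k in seq_along(clusters)) {
    for (cond in c("CD", "HFD")) {
      n_c <- sizes[[k]][cond]
      if (n_c == 0) next
      m <- matrix(
        rnbinom(n_genes_all * n_c, mu = rep(mu[, k], n_c),
                size = dispersion),
        n_genes_all, n_c
      )
      blocks[[length(blocks) + 1L]] <- m
      meta[[length(meta) + 1L]] <- tibble::tibble(
        true_cluster = clusters[k], condition = cond, n = n_c
      )
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- dplyr::bind_rows(meta)
  cell_meta <- tibble::tibble(
    cell = sprintf("cell%03d", seq_len(ncol(counts))),
    condition = rep(meta$condition, meta$n),
    true_cluster = rep(meta$true_cluster, meta$n)
  )
  cell_meta$preselect_label <-
    ifelse(cell_meta$true_cluster %in% depleted, "ghost", "typical")
  dimnames(counts) <- list(gene_names, cell_meta$cell)
  count_matrix(counts, cell_meta = cell_meta)
}
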