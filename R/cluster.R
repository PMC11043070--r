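#' Cluster cells by Leiden community detection with silhouette selection
#'
#' The clustering chain for small patch-seq cohorts: PCA of the
#' normalised expression (cells centred, `n_pcs` components, capped at
#' cells - 1), an unweighted undirected union k-nearest-neighbour graph in
#' PC space, Leiden modularity partitions at every resolution of the grid,
#' and the mean silhouette width (Euclidean, PC space) as the model
#' selector: the resolution with the highest mean silhouette among
#' partitions with at least two clusters wins, ties going to the smallest
#' resolution. If no partition has two or more clusters, or the best
#' silhouette falls below `min_silhouette` (default 0.05, the level that
#' separates genuine cluster structure from the weakly positive
#' silhouettes graph partitions attain on structureless data), a single
#' cluster is returned.
#' Cells are canonically ordered internally, so the partition is invariant
#' to the input cell order at a fixed seed; cluster ids are relabelled
#' 1, 2, ... by decreasing size.
#'
#' @param normalized Genes x cells matrix from [normalize_counts()].
#' @param params Clustering parameters ([ghost_config()]`$cluster`).
#' @param seed Integer seed (Leiden refinement is stochastic).
#' @return Object of class `cluster_result`: `labels` tibble (`cell`,
#'   `cluster`), `n_clusters`, `resolution_selected`,
#'   `silhouette_by_resolution` tibble, `embedding` (cells x PCs matrix).
#' @export
cluster_cells <- function(normalized, params = ghost_config()$cluster,
                          seed = 1) {
  params <- modify_defaults(ghost_config()$cluster, params %||% list())
  cells <- colnames(normalized)
  n <- length(cells)
  if (n < params$knn_k + 1) {
    stop_ghostmap(
      sprintf("need at least knn_k + 1 = %d cells, got %d",
              params$knn_k + 1, n),
      "ghostmap_value_error"
    )
  }
  ord <- order(cells)          # canonical order: input-order invariance
  m <- t(normalized[, ord, drop = FALSE])
  n_pcs <- min(params$n_pcs, n - 1L, ncol(m))
  pcs <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  dmat <- as.matrix(dist(pcs))

  k <- params$knn_k
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(k + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)          # undirected union of neighbourhoods
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")

  sil_tbl <- purrr::map_dfr(params$resolution_grid, function(res) {
    set.seed(seed)
    part <- igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 10
    )
    lab <- igraph::membership(part)
    k_found <- length(unique(lab))
    sil <- if (k_found >= 2 && k_found < n) {
      mean(cluster::silhouette(as.integer(lab), dmat)[, "sil_width"])
    } else {
      NA_real_
    }
    tibble::tibble(resolution = res, n_clusters = k_found,
                   silhouette = sil,
                   labels = list(as.integer(lab)))
  })

  eligible <- which(!is.na(sil_tbl$silhouette) &
                      sil_tbl$silhouette >= params$min_silhouette)
  if (length(eligible) == 0) {
    labels <- rep(1L, n)
    res_sel <- NA_real_
  } else {
    best <- eligible[which.max(sil_tbl$silhouette[eligible])]
    labels <- sil_tbl$labels[[best]]
    res_sel <- sil_tbl$resolution[best]
  }
  # relabel by decreasing cluster size (ties: first appearance)
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- setNames(seq_along(sizes), names(sizes))
  labels <- unname(remap[as.character(labels)])

  lab_tbl <- tibble::tibble(cell = cells[ord], cluster = labels)
  lab_tbl <- lab_tbl[match(cells, lab_tbl$cell), ]
  structure(
    list(
      labels = lab_tbl,
      n_clusters = length(unique(labels)),
      resolution_selected = res_sel,
      silhouette_by_resolution = sil_tbl[, c("resolution", "n_clusters",
                                             "silhouette")],
      embedding = pcs[match(cells, cells[ord]), , drop = FALSE]
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), resolution %.2g, sizes: %s\n",
              x$n_clusters,
              x$resolution_selected,
              paste(sort(table(x$labels$cluster), decreasing = TRUE),
                    collapse = "/")))
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  x$labels
}

#' @export
glance.cluster_result <- function(x, ...) {
  best <- x$silhouette_by_resolution
  tibble::tibble(
    n_clusters = x$n_clusters,
    resolution_selected = x$resolution_selected,
    silhouette = if (all(is.na(best$silhouette))) NA_real_
                 else max(best$silhouette, na.rm = TRUE)
  )
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between a recovered partition and a reference, corrected for
#' chance; 1 means identical up to label permutation, 0 is the chance
#' level.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_idx - expected)
}
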