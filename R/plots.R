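# ggplot2 views of the main result types. These are thin layers over the
# tabular outputs; all quantitative reporting goes through the tables.

#' @export
autoplot.density_field <- function(object, ...) {
  proj <- object |>
    dplyr::group_by(.data$x, .data$z) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(proj, ggplot2::aes(.data$z, .data$x,
                                     fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "rostro-caudal (um)", y = "medio-lateral (um)",
                  fill = "density",
                  title = "density field (dorso-ventral projection)")
}

#' @export
autoplot.pvalue_field <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(object, significant = .data$p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$x,
                                   size = -log10(.data$p),
                                   colour = .data$direction,
                                   alpha = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.9, `FALSE` = 0.15),
                                guide = "none") +
    ggplot2::labs(x = "rostro-caudal (um)", y = "medio-lateral (um)",
                  size = "-log10 p", colour = "enriched",
                  title = "node-wise subpopulation comparison")
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(
    pc1 = object$embedding[, 1],
    pc2 = object$embedding[, min(2, ncol(object$embedding))],
    cluster = factor(object$labels$cluster)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = sprintf("Leiden partition (k = %d, resolution %.2g)",
                                  object$n_clusters,
                                  object$resolution_selected))
}

#' Plot empirical axis CDFs with their Gaussian fits
#'
#' @param cdfs Named list of CDF tibbles (e.g. typical and ghost).
#' @param fits Optional named list of matching [fit_gaussian_cdf()]
#'   results; fitted curves are overlaid when given.
#' @return A ggplot object.
#' @export
plot_axis_cdf <- function(cdfs, fits = NULL) {
  df <- purrr::imap_dfr(cdfs, ~ dplyr::mutate(.x, subpop = .y))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$cum_frac,
                                        colour = .data$subpop)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "axis position (um)", y = "cumulative fraction")
  if (!is.null(fits)) {
    grid <- seq(min(df$position), max(df$position), length.out = 200)
    curves <- purrr::imap_dfr(fits, function(f, nm) {
      tibble::tibble(position = grid,
                     cum_frac = pnorm(grid, f$mu, f$sigma),
                     subpop = nm)
    })
    p <- p + ggplot2::geom_line(data = curves, linetype = 2)
  }
  p
}

#' Plot the silhouette trace over the resolution grid
#'
#' @param result A [cluster_cells()] result.
#' @return A ggplot object.
#' @export
plot_silhouette_trace <- function(result) {
  df <- result$silhouette_by_resolution
  ggplot2::ggplot(df, ggplot2::aes(.data$resolution, .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$n_clusters))) +
    ggplot2::geom_vline(xintercept = result$resolution_selected,
                        linetype = 2) +
    ggplot2::labs(colour = "clusters", y = "mean silhouette")
}
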