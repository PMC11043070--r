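# Per-axis kernel bandwidth for a 3D Gaussian product kernel.
# Scott's rule: h_j = sd_j * n^(-1/(d+4)), d = 3; Silverman multiplies by
# (4/(d+2))^(1/(d+4)).
kde_bandwidth <- function(pts, params) {
  n <- nrow(pts)
  rule <- params$bandwidth_rule %||% "scott"
  if (rule == "fixed") {
    h <- params$fixed_bandwidth
    if (is.null(h) || any(h <= 0)) {
      stop_ghostmap("fixed bandwidth rule requires positive fixed_bandwidth",
                    "ghostmap_config_error")
    }
    return(rep_len(as.numeric(h), 3))
  }
  sds <- apply(pts, 2, sd)
  if (any(sds == 0)) {
    stop_ghostmap("degenerate point cloud: zero variance along an axis",
                  "ghostmap_value_error")
  }
  f <- n^(-1 / 7)
  if (rule == "silverman") f <- f * (4 / 5)^(1 / 7)
  sds * f
}

# Gaussian-product-kernel density on a regular grid. axes is a list of the
# three node-coordinate vectors; returns the 3D density array.
kde3d_grid <- function(pts, axes, bandwidth) {
  n <- nrow(pts)
  K <- lapply(1:3, function(j) {
    outer(axes[[j]], pts[, j],
          function(g, p) dnorm((g - p) / bandwidth[j]) / bandwidth[j])
  })
  gx <- length(axes[[1]]); gy <- length(axes[[2]]); gz <- length(axes[[3]])
  f <- array(0, dim = c(gx, gy, gz))
  for (c_idx in seq_len(gz)) {
    m <- K[[2]] * matrix(K[[3]][c_idx, ], gy, n, byrow = TRUE)
    f[, , c_idx] <- K[[1]] %*% t(m)
  }
  f / n
}

grid_axes_for <- function(pts, bandwidth, spacing) {
  lapply(1:3, function(j) {
    lo <- min(pts[, j]) - 3 * bandwidth[j]
    hi <- max(pts[, j]) + 3 * bandwidth[j]
    seq(lo, hi, by = spacing)
  })
}

cloud_points <- function(cloud, subpop = "all", animal = NULL) {
  sel <- cloud
  if (!identical(subpop, "all")) {
    sel <- dplyr::filter(sel, .data$subpop == .env$subpop)
  }
  if (!is.null(animal)) {
    sel <- dplyr::filter(sel, .data$animal_id == .env$animal)
  }
  as.matrix(sel[, c("x", "y", "z")])
}

#' Estimate the 3D density field of a cell subpopulation
#'
#' Gaussian-product-kernel density estimate of a point cloud on a regular
#' 3D grid (Scott's rule bandwidth per axis by default). The grid spans
#' the selected points' range plus three bandwidths, so the Riemann sum of
#' the field times the voxel volume is within 5% of one.
#'
#' @param cloud Point-cloud tibble (`x`, `y`, `z`, `subpop`, `animal_id`).
#' @param subpop `"typical"`, `"ghost"` or `"all"`.
#' @param animal Optional animal id to restrict to.
#' @param params KDE parameters ([ghost_config()]`$kde`).
#' @param min_points Minimum selection size (relax for tiny test
#'   fixtures).
#' @return A `density_field` tibble (`x`, `y`, `z`, `density`) carrying
#'   `bandwidth`, `axes`, `spacing`, `n_points`, `subpop` attributes.
#' @export
estimate_density <- function(cloud, subpop = "all", animal = NULL,
                             params = ghost_config()$kde, min_points = 5) {
  params <- modify_defaults(ghost_config()$kde, params %||% list())
  pts <- cloud_points(cloud, subpop, animal)
  if (nrow(pts) < min_points) {
    stop_ghostmap(
      sprintf("insufficient data: %d point(s) for subpop=%s animal=%s (need >= %d)",
              nrow(pts), subpop, animal %||% "all", min_points),
      "ghostmap_value_error"
    )
  }
  bw <- if (nrow(pts) >= 2 && !identical(params$bandwidth_rule, "fixed")) {
    kde_bandwidth(pts, params)
  } else if (identical(params$bandwidth_rule, "fixed")) {
    kde_bandwidth(pts, params)
  } else {
    rep(params$grid_spacing, 3) # single point: fall back to grid-scale kernel
  }
  axes <- grid_axes_for(pts, bw, params$grid_spacing)
  f <- kde3d_grid(pts, axes, bw)
  out <- tibble::as_tibble(expand.grid(x = axes[[1]], y = axes[[2]],
                                       z = axes[[3]],
                                       KEEP.OUT.ATTRS = FALSE))
  out$density <- as.numeric(f)
  attr(out, "bandwidth") <- bw
  attr(out, "axes") <- axes
  attr(out, "spacing") <- params$grid_spacing
  attr(out, "n_points") <- nrow(pts)
  attr(out, "subpop") <- subpop
  class(out) <- c("density_field", class(out))
  out
}

#' Super-level-set summaries of a density field
#'
#' For each quantile `q` of the field's positive densities, summarises the
#' super-level set (the nodes at or above that level): node count, volume
#' and centroid. These are the tabular counterpart of isosurface density
#' plots; volumes are monotone non-increasing in `q`.
#'
#' @param field A `density_field` from [estimate_density()].
#' @param quantiles Quantiles in (0, 1).
#' @return Tibble with `quantile`, `level`, `n_nodes`, `volume_um3`,
#'   `centroid_x`, `centroid_y`, `centroid_z`.
#' @export
isosurface_levels <- function(field, quantiles = c(0.25, 0.5, 0.75)) {
  if (any(quantiles <= 0 | quantiles >= 1)) {
    stop_ghostmap("quantiles must lie strictly inside (0, 1)",
                  "ghostmap_range_error")
  }
  spacing <- attr(field, "spacing")
  pos <- field$density[field$density > 0]
  purrr::map_dfr(quantiles, function(q) {
    lev <- as.numeric(quantile(pos, q))
    set <- field$density >= lev
    tibble::tibble(
      quantile = q,
      level = lev,
      n_nodes = sum(set),
      volume_um3 = sum(set) * spacing^3,
      centroid_x = mean(field$x[set]),
      centroid_y = mean(field$y[set]),
      centroid_z = mean(field$z[set])
    )
  })
}
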