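#' Node-wise local comparison of two subpopulations' spatial densities
#'
#' The "p-value sphere" analysis: for every animal and subpopulation a
#' normalised density field is estimated on one common grid (bandwidth
#' from the pooled cloud, shared across fields so local values are
#' comparable). The occupied region is the super-level set of the pooled
#' all-cells density at `occupancy_quantile` of its positive values. At
#' each occupied node the per-animal typical and ghost densities are
#' compared by a paired two-tailed t-test across animals; the sign of the
#' mean difference gives the locally enriched subpopulation. Nodes where
#' every animal shows a zero difference get p = 1 by convention. With
#' `mode = "permutation"` the t statistic is referenced against
#' within-animal label permutations instead of the t distribution
#' (calibration checks).
#'
#' @param cloud Point-cloud tibble with both subpopulations in every
#'   animal and at least two animals.
#' @param params KDE parameters ([ghost_config()]`$kde`).
#' @param mode `"t"` (default) or `"permutation"`.
#' @param n_perm Permutations for `mode = "permutation"`.
#' @param min_points Minimum points per (animal, subpop) selection.
#' @param seed Seed used by the permutation mode.
#' @return A `pvalue_field` tibble over the occupied nodes: `x`, `y`,
#'   `z`, `p` (two-tailed, in (0, 1]), `direction`
#'   (`typical`/`ghost`/`none`), `mean_diff`.
#' @export
local_subpopulation_test <- function(cloud, params = ghost_config()$kde,
                                     mode = c("t", "permutation"),
                                     n_perm = 200, min_points = 5,
                                     seed = 1) {
  mode <- match.arg(mode)
  params <- modify_defaults(ghost_config()$kde, params %||% list())
  animals <- sort(unique(cloud$animal_id))
  if (length(animals) < 2) {
    stop_ghostmap("need at least 2 animals", "ghostmap_value_error")
  }
  tab <- table(cloud$animal_id, cloud$subpop)
  need <- c("typical", "ghost")
  if (!all(need %in% colnames(tab)) || any(tab[, need] < min_points)) {
    offenders <- if (!all(need %in% colnames(tab))) animals
                 else rownames(tab)[apply(tab[, need, drop = FALSE], 1,
                                          function(r) any(r < min_points))]
    stop_ghostmap(
      paste0("animal(s) missing a subpopulation (or below ", min_points,
             " points): ", paste(offenders, collapse = ", ")),
      "ghostmap_value_error"
    )
  }

  all_pts <- cloud_points(cloud)
  bw <- kde_bandwidth(all_pts, params)
  axes <- grid_axes_for(all_pts, bw, params$grid_spacing)
  pooled <- kde3d_grid(all_pts, axes, bw)
  lev <- as.numeric(quantile(pooled[pooled > 0],
                             params$occupancy_quantile))
  occ <- which(pooled >= lev)

  field_at_occ <- function(pts) {
    kde3d_grid(pts, axes, bw)[occ]
  }
  diffs_for <- function(cl) {
    vapply(animals, function(a) {
      field_at_occ(cloud_points(cl, "typical", a)) -
        field_at_occ(cloud_points(cl, "ghost", a))
    }, numeric(length(occ)))
  }
  node_t <- function(D) {
    m <- rowMeans(D)
    s <- apply(D, 1, sd)
    t_stat <- ifelse(s > 0, m / (s / sqrt(ncol(D))), Inf * sign(m))
    list(m = m, s = s, t = t_stat)
  }

  D <- diffs_for(cloud)
  nt <- node_t(D)
  n_anim <- length(animals)
  if (mode == "t") {
    p <- rep(1, length(occ))                    # s = 0 & m = 0: all-zero diffs
    ok <- nt$s > 0
    p[ok] <- 2 * pt(-abs(nt$t[ok]), df = n_anim - 1)
    p[!ok & nt$m != 0] <- .Machine$double.xmin  # identical non-zero diffs
  } else {
    # reference |t| against within-animal label shuffles (exchangeable null)
    set.seed(seed)
    exceed <- rep(1L, length(occ)) # count the observed statistic itself
    for (b in seq_len(n_perm)) {
      shuffled <- cloud
      for (a in animals) {
        idx <- which(cloud$animal_id == a)
        shuffled$subpop[idx] <- sample(cloud$subpop[idx])
      }
      ntb <- node_t(diffs_for(shuffled))
      exceed <- exceed + (abs(ntb$t) >= abs(nt$t) |
                            (!is.finite(ntb$t) & !is.finite(nt$t)))
    }
    p <- exceed / (n_perm + 1)
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  coords <- arrayInd(occ, dim(pooled))
  out <- tibble::tibble(
    x = axes[[1]][coords[, 1]],
    y = axes[[2]][coords[, 2]],
    z = axes[[3]][coords[, 3]],
    p = p,
    mean_diff = nt$m,
    direction = dplyr::case_when(nt$m > 0 ~ "typical",
                                 nt$m < 0 ~ "ghost",
                                 TRUE ~ "none")
  )
  attr(out, "bandwidth") <- bw
  attr(out, "occupancy_level") <- lev
  attr(out, "n_animals") <- n_anim
  attr(out, "mode") <- mode
  class(out) <- c("pvalue_field", class(out))
  out
}
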