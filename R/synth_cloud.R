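#' Simulate a 3D cell point cloud with a caudally shifted subpopulation
#'
#' Draws `n_typical` and `n_ghost` cell centroids from trivariate normal
#' distributions. The ghost centre is the typical centre (or an explicit
#' `ghost_center`) displaced by `caudal_shift` micrometres along the third
#' (rostro-caudal) axis, emulating a subpopulation concentrated in the
#' caudal part of the nucleus. Points are assigned to `n_animals` animals
#' round-robin, so per-animal counts within a subpopulation differ by at
#' most one.
#'
#' @param n_typical,n_ghost Number of points per subpopulation.
#' @param typical_center Length-3 centre of the typical subpopulation (um).
#' @param ghost_center Length-3 centre of the ghost subpopulation before
#'   the caudal shift; defaults to `typical_center`.
#' @param covariances Either one 3x3 symmetric positive-definite matrix used
#'   for both subpopulations or `list(typical = , ghost = )`.
#' @param caudal_shift Displacement (um) added to the ghost centre along
#'   the third axis.
#' @param n_animals Number of animals points are cycled over.
#' @param axis_names Names of the three anatomical axes.
#' @param seed Integer seed.
#' @return A point-cloud tibble with columns `x`, `y`, `z`, `subpop`
#'   (`typical`/`ghost`), `animal_id`, carrying `axis_names` as an
#'   attribute.
#' @export
#' @examples
#' cloud <- gen_point_cloud(n_typical = 100, n_ghost = 50,
#'                          caudal_shift = 200, seed = 1)
#' dplyr::count(cloud, subpop, animal_id)
gen_point_cloud <- function(n_typical,
                            n_ghost,
                            typical_center = c(0, 0, 0),
                            ghost_center = NULL,
                            covariances = diag(100^2, 3),
                            caudal_shift = 0,
                            n_animals = 1,
                            axis_names = c("medio-lateral", "dorso-ventral",
                                           "rostro-caudal"),
                            seed = 1) {
  if (n_animals < 1) {
    stop_ghostmap("n_animals must be >= 1", "ghostmap_value_error")
  }
  if (!is.list(covariances)) {
    covariances <- list(typical = covariances, ghost = covariances)
  }
  chol_of <- function(sigma) {
    sigma <- as.matrix(sigma)
    if (!isSymmetric(sigma, tol = 1e-8)) {
      stop_ghostmap("covariance must be symmetric positive definite",
                    "ghostmap_value_error")
    }
    out <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(out)) {
      stop_ghostmap("covariance must be symmetric positive definite",
                    "ghostmap_value_error")
    }
    out
  }
  chols <- lapply(covariances, chol_of)
  ghost_center <- ghost_center %||% typical_center
  ghost_center <- ghost_center + c(0, 0, caudal_shift)

  set.seed(seed)
  draw <- function(n, center, ch) {
    if (n == 0) {
      return(matrix(numeric(0), 0, 3))
    }
    z <- matrix(rnorm(n * 3), n, 3)
    sweep(z %*% ch, 2, center, `+`)
  }
  pts_t <- draw(n_typical, typical_center, chols$typical)
  pts_g <- draw(n_ghost, ghost_center, chols$ghost)
  animal_of <- function(n) {
    if (n == 0) character(0)
    else sprintf("animal%02d", ((seq_len(n) - 1L) %% n_animals) + 1L)
  }
  cloud <- tibble::tibble(
    x = c(pts_t[, 1], pts_g[, 1]),
    y = c(pts_t[, 2], pts_g[, 2]),
    z = c(pts_t[, 3], pts_g[, 3]),
    subpop = rep(c("typical", "ghost"), c(n_typical, n_ghost)),
    animal_id = c(animal_of(n_typical), animal_of(n_ghost))
  )
  attr(cloud, "axis_names") <- axis_names
  cloud
}
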