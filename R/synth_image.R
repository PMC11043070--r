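#' Multichannel image stack container
#'
#' A lightweight in-memory representation of a multichannel 3D stack: a
#' named list of 3D arrays (dimensions x, y, z in voxels), all of equal
#' shape, plus the physical voxel size in micrometres.
#'
#' @param channels Named list of 3D numeric arrays of identical dimension.
#' @param voxel_size Numeric length-3 vector, micrometres per voxel along
#'   (x, y, z).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size = c(1, 1, 1)) {
  if (length(channels) == 0 || is.null(names(channels))) {
    stop_ghostmap("channels must be a non-empty named list",
                  "ghostmap_value_error")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      length(unique(dims)) != 1L) {
    stop_ghostmap("all channels must be 3D arrays of identical dimension",
                  "ghostmap_value_error")
  }
  structure(
    list(channels = channels, voxel_size = as.numeric(voxel_size)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d voxels, channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Simulate a lineage-reporter image stack with known ground truth
#'
#' Generates a multichannel 3D stack containing `n_cells` non-overlapping
#' spheroidal cells. All cells are bright in the reporter channel
#' (emulating a permanent lineage label); in each marker channel a cell's
#' added intensity is the channel's `typical` or `ghost` level according to
#' the cell's ground-truth label, so that with `ghost = 0` a ghost cell is
#' indistinguishable from background in that channel. Additive Gaussian
#' noise (per-channel `noise_sd`) is clipped at zero. The ghost count is
#' the deterministic `round(n_cells * ghost_fraction)` so fixture sizes are
#' exact.
#'
#' @param shape Stack shape in voxels along (x, y, z).
#' @param voxel_size Micrometres per voxel along (x, y, z).
#' @param n_cells Number of cells to place.
#' @param ghost_fraction Fraction of cells with the ghost label, in \[0, 1\].
#' @param cell_radius Mean and sd of cell radius in micrometres,
#'   `c(mean, sd)`.
#' @param channels Named list; each element is
#'   `list(typical = , ghost = , noise_sd = )` giving the added mean
#'   intensity for each class and the channel noise sd. The first channel
#'   is conventionally the reporter (equal typical and ghost levels).
#' @param background Baseline intensity added everywhere.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param separate_in_xy Also enforce non-overlap of the cells' xy
#'   projections (use for fixtures meant for 2D projected segmentation).
#' @param max_retries Rejection-sampling budget for non-overlapping
#'   placement before a packing error is raised.
#' @return A list with `stack` (an [image_stack]) and `cells`, the
#'   ground-truth tibble (`cell_id`, centroid `x`, `y`, `z` in um,
#'   `radius_um`, `true_label`).
#' @export
#' @examples
#' sim <- gen_image_stack(shape = c(48, 48, 12), n_cells = 8, seed = 1)
#' sim$cells
gen_image_stack <- function(shape = c(128, 128, 32),
                            voxel_size = c(1, 1, 1),
                            n_cells = 50,
                            ghost_fraction = 0.1,
                            cell_radius = c(3, 0.3),
                            channels = list(
                              reporter = list(typical = 150, ghost = 150,
                                              noise_sd = 0),
                              pomc = list(typical = 120, ghost = 0,
                                          noise_sd = 0)
                            ),
                            background = 10,
                            seed = 1,
                            separate_in_xy = FALSE,
                            max_retries = 1e4) {
  if (ghost_fraction < 0 || ghost_fraction > 1) {
    stop_ghostmap("ghost_fraction must lie in [0, 1]", "ghostmap_value_error")
  }
  set.seed(seed)
  extent <- shape * voxel_size
  n_ghost <- round_half_up(n_cells * ghost_fraction)
  labels <- sample(rep(c("ghost", "typical"),
                       c(n_ghost, n_cells - n_ghost)))

  radii <- pmax(abs(rnorm(n_cells, cell_radius[1], cell_radius[2])),
                voxel_size[1])
  centers <- matrix(NA_real_, n_cells, 3)
  tries <- 0L
  i <- 1L
  while (i <= n_cells) {
    lo <- radii[i] + voxel_size
    hi <- extent - radii[i] - voxel_size
    if (any(hi <= lo)) {
      stop_ghostmap("cell radius too large for the volume",
                    "ghostmap_packing_error")
    }
    cand <- runif(3, lo, hi)
    ok <- TRUE
    if (i > 1L) {
      prev <- centers[seq_len(i - 1L), , drop = FALSE]
      min_gap2 <- (radii[seq_len(i - 1L)] + radii[i] + 1)^2
      d2 <- colSums((t(prev) - cand)^2)
      ok <- all(d2 >= min_gap2)
      if (ok && separate_in_xy) {
        dxy2 <- colSums((t(prev[, 1:2, drop = FALSE]) - cand[1:2])^2)
        ok <- all(dxy2 >= min_gap2)
      }
    }
    if (ok) {
      centers[i, ] <- cand
      i <- i + 1L
    } else {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop_ghostmap(
          sprintf("could not place %d non-overlapping cells in %s retries",
                  n_cells, format(max_retries)),
          "ghostmap_packing_error"
        )
      }
    }
  }

  arrs <- lapply(channels, function(ch) {
    arr <- array(background, dim = shape)
    arr
  })
  # voxel-centre coordinates in um, per axis
  ax <- lapply(1:3, function(j) (seq_len(shape[j]) - 0.5) * voxel_size[j])
  for (i in seq_len(n_cells)) {
    r <- radii[i]
    ctr <- centers[i, ]
    idx <- lapply(1:3, function(j) {
      which(abs(ax[[j]] - ctr[j]) <= r)
    })
    dx2 <- (ax[[1]][idx[[1]]] - ctr[1])^2
    dy2 <- (ax[[2]][idx[[2]]] - ctr[2])^2
    dz2 <- (ax[[3]][idx[[3]]] - ctr[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    for (nm in names(channels)) {
      lvl <- if (labels[i] == "ghost") channels[[nm]]$ghost
             else channels[[nm]]$typical
      sub <- arrs[[nm]][idx[[1]], idx[[2]], idx[[3]]]
      sub[inside] <- background + lvl
      arrs[[nm]][idx[[1]], idx[[2]], idx[[3]]] <- sub
    }
  }
  for (nm in names(channels)) {
    nsd <- channels[[nm]]$noise_sd %||% 0
    if (nsd > 0) {
      arrs[[nm]] <- pmax(arrs[[nm]] + rnorm(length(arrs[[nm]]), 0, nsd), 0)
      arrs[[nm]] <- array(arrs[[nm]], dim = shape)
    }
  }

  truth <- tibble::tibble(
    cell_id = sprintf("cell%03d", seq_len(n_cells)),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius_um = radii,
    true_label = labels
  )
  list(stack = image_stack(arrs, voxel_size = voxel_size), cells = truth)
}

#' Write / read an image stack as a multi-page TIFF
#'
#' Pages are ordered channel-major (all z-planes of channel 1, then channel
#' 2, ...). Intensities are stored as 32-bit floats; channel names, shape
#' and voxel size are written to a JSON sidecar so the round trip is
#' lossless.
#'
#' @param x An [image_stack].
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(x, path) {
  stopifnot(inherits(x, "image_stack"))
  d <- dim(x$channels[[1]])
  # TIFF samples live in [0, 1]; store intensities scaled by the stack
  # maximum and keep the scale in the sidecar
  scale <- max(1, vapply(x$channels, max, 1))
  pages <- list()
  for (nm in names(x$channels)) {
    for (k in seq_len(d[3])) {
      # tiff stores row-major planes: rows = y, cols = x
      pages[[length(pages) + 1L]] <- t(x$channels[[nm]][, , k]) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = names(x$channels), shape = d,
         voxel_size = x$voxel_size, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  scale <- meta$intensity_scale %||% 1
  chans <- list()
  p <- 1L
  for (nm in meta$channels) {
    arr <- array(0, dim = d)
    for (k in seq_len(d[3])) {
      arr[, , k] <- t(pages[[p]]) * scale
      p <- p + 1L
    }
    chans[[nm]] <- arr
  }
  image_stack(chans, voxel_size = as.numeric(meta$voxel_size))
}
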