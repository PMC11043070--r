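# Connected-component labelling of a logical mask (2D or 3D) on the voxel
# adjacency graph: 8-connectivity in 2D, 26-connectivity in 3D. Returns an
# integer array of component labels (0 = background).
label_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  idx <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) {
    return(idx)
  }
  idx[fg] <- seq_along(fg)
  offsets <- if (nd == 2L) {
    list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  } else {
    out <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      v <- c(dx, dy, dz)
      if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))) {
        out[[length(out) + 1L]] <- v
      }
    }
    out
  }
  slice_range <- function(len, off) {
    list(src = max(1, 1 - off):min(len, len - off),
         dst = (max(1, 1 - off):min(len, len - off)) + off)
  }
  edges <- list()
  for (off in offsets) {
    rngs <- lapply(seq_len(nd), function(j) slice_range(d[j], off[j]))
    src <- do.call(`[`, c(list(idx), lapply(rngs, `[[`, "src"),
                          list(drop = FALSE)))
    dst <- do.call(`[`, c(list(idx), lapply(rngs, `[[`, "dst"),
                          list(drop = FALSE)))
    both <- src > 0L & dst > 0L
    if (any(both)) {
      edges[[length(edges) + 1L]] <- rbind(src[both], dst[both])
    }
  }
  g <- igraph::make_graph(
    edges = if (length(edges)) c(do.call(cbind, edges)) else numeric(0),
    n = length(fg), directed = FALSE
  )
  comp <- igraph::components(g)$membership
  idx[fg] <- as.integer(comp)
  idx
}

segment_core <- function(stack, reporter_channel, params, mode) {
  stopifnot(inherits(stack, "image_stack"))
  params <- modify_defaults(ghost_config()$segmentation, params %||% list())
  if (!reporter_channel %in% names(stack$channels)) {
    stop_ghostmap(
      paste0("reporter channel not found: ", reporter_channel,
             " (available: ", paste(names(stack$channels), collapse = ", "),
             ")"),
      "ghostmap_value_error"
    )
  }
  arr <- stack$channels[[reporter_channel]]
  d <- dim(arr)
  if (any(d == 0)) {
    stop_ghostmap("empty stack", "ghostmap_value_error")
  }
  vx <- stack$voxel_size
  if (mode == "2d") {
    img <- apply(arr, c(1, 2), max) # maximum-intensity projection over z
    unit_size <- vx[1] * vx[2]     # um^2 per pixel
  } else {
    img <- arr
    unit_size <- prod(vx)          # um^3 per voxel
  }
  thr <- if (identical(params$threshold_method, "fixed")) {
    params$fixed_threshold
  } else {
    otsu_threshold(as.numeric(img))
  }
  if (is.na(thr %||% NA_real_)) {
    warn("degenerate intensity distribution: no threshold found, zero ROIs")
    labels <- array(0L, dim = dim(img))
  } else {
    labels <- label_components(img >= thr)
  }
  # size filter in physical units
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L]) * unit_size
    keep <- which(sizes >= params$min_size & sizes <= params$max_size)
    relab <- integer(max(labels))
    relab[keep] <- seq_along(keep)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
  }
  n_roi <- max(labels)
  cells <- if (n_roi == 0L) {
    tibble::tibble(cell_id = character(), x = numeric(), y = numeric(),
                   z = numeric(), size = numeric())
  } else {
    lab <- labels[labels > 0L]
    pos <- arrayInd(which(labels > 0L), dim(labels))
    cx <- as.numeric(rowsum((pos[, 1] - 0.5) * vx[1], lab)) / tabulate(lab)
    cy <- as.numeric(rowsum((pos[, 2] - 0.5) * vx[2], lab)) / tabulate(lab)
    cz <- if (mode == "2d") {
      rep(d[3] * vx[3] / 2, n_roi) # projected: mid-plane convention
    } else {
      as.numeric(rowsum((pos[, 3] - 0.5) * vx[3], lab)) / tabulate(lab)
    }
    tibble::tibble(
      cell_id = sprintf("roi%04d", seq_len(n_roi)),
      x = cx, y = cy, z = cz,
      size = tabulate(lab) * unit_size
    )
  }
  structure(
    list(labels = labels, cells = cells, mode = mode,
         threshold = if (is.na(thr %||% NA_real_)) NA_real_ else thr,
         voxel_size = vx),
    class = "roi_map"
  )
}

#' Segment reporter-positive cells
#'
#' Thresholds the reporter channel (Otsu by default, or a fixed value) and
#' labels connected components as single-cell ROIs, discarding components
#' outside the `min_size`/`max_size` physical-size window.
#' `segment_cells_2d()` works on the maximum-intensity projection over z
#' with 8-connected pixels and an area filter in um^2 (the projected
#' centroid z is the stack mid-plane); `segment_cells_3d()` labels
#' 26-connected voxels with a volume filter in um^3 and true 3D centroids.
#'
#' @param stack An [image_stack].
#' @param reporter_channel Name of the lineage-reporter channel.
#' @param params Segmentation parameter overrides
#'   ([ghost_config()]`$segmentation`).
#' @return An object of class `roi_map`: the integer label array, a cell
#'   skeleton tibble (`cell_id`, centroid `x`/`y`/`z` in um, `size`), the
#'   resolved threshold and the mode. Zero ROIs yield an empty tibble, not
#'   an error.
#' @export
segment_cells_2d <- function(stack, reporter_channel, params = NULL) {
  segment_core(stack, reporter_channel, params, mode = "2d")
}

#' @rdname segment_cells_2d
#' @export
segment_cells_3d <- function(stack, reporter_channel, params = NULL) {
  segment_core(stack, reporter_channel, params, mode = "3d")
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("<roi_map> mode %s, %d ROIs, threshold %.4g\n",
              x$mode, nrow(x$cells), x$threshold))
  invisible(x)
}

#' Quantify per-cell channel intensities over segmented ROIs
#'
#' For every ROI and channel, records the mean and maximum intensity over
#' the ROI's voxels (3D mode) or over the channel's maximum-intensity
#' projection at the ROI's pixels (2D mode), appending `mean_<channel>`
#' and `max_<channel>` columns to the ROI skeleton.
#'
#' @param stack The [image_stack] the ROIs were segmented from.
#' @param rois An `roi_map` from [segment_cells_2d()] /
#'   [segment_cells_3d()].
#' @return A cell-table tibble with one row per ROI, `lineage_positive`
#'   set to `TRUE`.
#' @export
quantify_rois <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"), inherits(rois, "roi_map"))
  cells <- rois$cells
  if (!identical(dim(rois$labels),
                 if (rois$mode == "2d") dim(stack$channels[[1]])[1:2]
                 else dim(stack$channels[[1]]))) {
    stop_ghostmap("ROI map does not match the stack dimensions",
                  "ghostmap_value_error")
  }
  if (nrow(cells) == 0L) {
    return(dplyr::mutate(cells, lineage_positive = logical(0)))
  }
  in_roi <- rois$labels > 0L
  lab <- rois$labels[in_roi]
  n <- tabulate(lab)
  for (nm in names(stack$channels)) {
    arr <- stack$channels[[nm]]
    img <- if (rois$mode == "2d") apply(arr, c(1, 2), max) else arr
    vals <- img[in_roi]
    cells[[paste0("mean_", nm)]] <- as.numeric(rowsum(vals, lab)) / n
    cells[[paste0("max_", nm)]] <-
      as.numeric(tapply(vals, lab, max))
  }
  cells$lineage_positive <- TRUE
  cells
}
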