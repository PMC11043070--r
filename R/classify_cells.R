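#' Classify lineage-traced cells as typical or ghost
#'
#' Splits reporter-positive cells on the identity-marker channel (mean
#' intensity by convention): cells at or above the resolved threshold are
#' `typical`, below it `ghost`. The threshold can be fixed, a quantile of
#' a supplied negative-control intensity distribution, or Otsu's method on
#' the cells' own intensity distribution. The resolved threshold is
#' attached as the `pomc_threshold` attribute so runs are auditable.
#' A degenerate Otsu split (constant or unimodal input) assigns all cells
#' `typical` with a warning rather than failing.
#'
#' @param cells A cell table containing the marker intensity column.
#' @param pomc_channel Channel name of the identity marker (the column
#'   used is `<statistic>_<pomc_channel>`).
#' @param rule Threshold rule: `list(type = "otsu_on_cells")`,
#'   `list(type = "fixed", value = )`, or
#'   `list(type = "quantile_of_negative_control", q = ,
#'   negative_control = <numeric intensities>)`.
#' @param statistic Intensity statistic, `"mean"` (the convention for the
#'   identity marker).
#' @return The cell table with `class_label` filled for lineage-positive
#'   rows (others `unassigned`), `pomc_threshold` attribute set.
#' @export
classify_lineage_cells <- function(cells,
                                   pomc_channel = "pomc",
                                   rule = list(type = "otsu_on_cells"),
                                   statistic = "mean") {
  cells <- tibble::as_tibble(cells)
  col <- paste0(statistic, "_", pomc_channel)
  if (!col %in% names(cells)) {
    stop_ghostmap(
      paste0("identity-marker column not found: ", col, " (available: ",
             paste(grep("^(mean|max)_", names(cells), value = TRUE),
                   collapse = ", "), ")"),
      "ghostmap_value_error"
    )
  }
  vals <- cells[[col]]
  lineage <- if ("lineage_positive" %in% names(cells)) {
    cells$lineage_positive
  } else {
    rep(TRUE, nrow(cells))
  }
  thr <- switch(
    rule$type,
    fixed = {
      if (!is_scalar_number(rule$value %||% NA)) {
        stop_ghostmap("fixed rule requires a numeric `value`",
                      "ghostmap_config_error")
      }
      rule$value
    },
    quantile_of_negative_control = {
      nc <- rule$negative_control
      if (is.null(nc) || length(nc) == 0) {
        stop_ghostmap(
          "quantile_of_negative_control rule requires negative-control intensities",
          "ghostmap_config_error"
        )
      }
      as.numeric(quantile(nc, rule$q %||% 0.99))
    },
    otsu_on_cells = otsu_threshold(vals[lineage]),
    stop_ghostmap(paste0("unknown threshold rule: ", rule$type),
                  "ghostmap_config_error")
  )
  if (is.na(thr)) {
    warn("degenerate intensity distribution: all cells classified typical")
    label <- rep("typical", nrow(cells))
  } else {
    label <- ifelse(vals >= thr, "typical", "ghost")
  }
  cells$class_label <- ifelse(lineage, label, "unassigned")
  attr(cells, "pomc_threshold") <- if (is.na(thr)) NA_real_ else thr
  cells
}

#' Call marker co-positivity per cell
#'
#' Applies a per-marker threshold to the configured intensity statistic
#' (maximum intensity by convention for co-expression markers) and records
#' a logical `marker_<name>` column. The boundary is inclusive: a value
#' exactly at the threshold is positive.
#'
#' @param cells A cell table.
#' @param marker Channel name of the marker.
#' @param threshold Intensity threshold; `statistic >= threshold` is
#'   positive.
#' @param statistic `"max"` (default) or `"mean"`.
#' @return The cell table with the `marker_<marker>` column added.
#' @export
call_marker_positivity <- function(cells, marker, threshold,
                                   statistic = "max") {
  cells <- tibble::as_tibble(cells)
  col <- paste0(statistic, "_", marker)
  if (!col %in% names(cells)) {
    avail <- unique(sub("^(mean|max)_", "",
                        grep("^(mean|max)_", names(cells), value = TRUE)))
    stop_ghostmap(
      paste0("unknown marker channel: ", marker, " (available: ",
             paste(avail, collapse = ", "), ")"),
      "ghostmap_value_error"
    )
  }
  cells[[paste0("marker_", marker)]] <- cells[[col]] >= threshold
  cells
}
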