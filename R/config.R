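#' Default analysis configuration
#'
#' A single configuration list governs all pipeline stages: segmentation,
#' cell classification, 3D density estimation, the electrophysiology response
#' rule and clustering. [validate_config()] fills unset entries with these
#' defaults and range-checks every numeric parameter.
#'
#' @return A nested named list of parameters with all defaults filled.
#' @export
#' @examples
#' cfg <- ghost_config()
#' cfg$ephys$delta_rmp_threshold
ghost_config <- function() {
  list(
    seed = 1L,
    segmentation = list(
      threshold_method = "otsu",   # or "fixed"
      fixed_threshold = NULL,      # intensity, used when method == "fixed"
      min_size = 10,               # um^2 (2D) or um^3 (3D)
      max_size = 5000,
      projection = "max"           # or "none"
    ),
    classification = list(
      pomc_channel = "pomc",
      statistic = "mean",
      threshold_rule = list(type = "otsu_on_cells"),
      marker_statistic = "max"
    ),
    kde = list(
      bandwidth_rule = "scott",    # scott | silverman | fixed
      fixed_bandwidth = NULL,      # um, per axis (scalar or length 3)
      grid_spacing = 25,           # um
      occupancy_quantile = 0.25
    ),
    ephys = list(
      delta_rmp_threshold = 2,     # mV
      delta_ri_threshold_pct = 10, # percent, magnitude
      pre_window = 30,             # s, ends at application onset
      post_offset = 300,           # s after onset
      post_window = 30,            # s
      dvdt_threshold = 20,         # mV/ms, AP threshold criterion
      spike_mask_ms = 5,           # mask half-width around dV/dt crossings
      fahp_window_ms = 5,
      mahp_window_ms = c(50, 200),
      combine_rule = "and"         # or "or" (sensitivity analysis)
    ),
    cluster = list(
      n_pcs = 20L,
      knn_k = 10L,
      resolution_grid = seq(0.1, 2, by = 0.1),
      min_silhouette = 0.05
    )
  )
}

range_spec <- function() {
  list(
    "segmentation.min_size"            = c(0, Inf),
    "segmentation.max_size"            = c(0, Inf),
    "kde.grid_spacing"                 = c(1e-12, Inf),
    "kde.occupancy_quantile"           = c(1e-12, 1 - 1e-12),
    "ephys.delta_rmp_threshold"        = c(1e-12, Inf),
    "ephys.delta_ri_threshold_pct"     = c(1e-12, Inf),
    "ephys.pre_window"                 = c(1e-12, Inf),
    "ephys.post_offset"                = c(0, Inf),
    "ephys.post_window"                = c(1e-12, Inf),
    "ephys.dvdt_threshold"             = c(1e-12, Inf),
    "cluster.n_pcs"                    = c(1, Inf),
    "cluster.knn_k"                    = c(1, Inf),
    "cluster.min_silhouette"           = c(-1, 1)
  )
}

#' Validate and normalise a configuration
#'
#' Accepts a (possibly partial) configuration as a nested list or a path to a
#' YAML file, merges it over [ghost_config()] defaults, and checks every
#' numeric parameter against its documented legal range. Validation is
#' deterministic: the same input always yields the same normalised output.
#'
#' @param config A nested list of overrides, a path to a YAML file, or `NULL`
#'   for the full default set.
#' @return The normalised configuration list (all defaults filled).
#' @export
#' @examples
#' validate_config(list(ephys = list(delta_rmp_threshold = 3)))$ephys$delta_rmp_threshold
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_ghostmap(paste0("config file not found: ", config),
                    "ghostmap_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  if (!is.list(config)) {
    stop_ghostmap("config must be a list or a YAML file path",
                  "ghostmap_config_error")
  }
  cfg <- modify_defaults(ghost_config(), config)
  if (!is.null(cfg$segmentation$fixed_threshold) &&
      cfg$segmentation$fixed_threshold < 0) {
    stop_ghostmap("segmentation.fixed_threshold out of range: must be >= 0",
                  "ghostmap_config_error")
  }
  if (cfg$segmentation$min_size >= cfg$segmentation$max_size) {
    stop_ghostmap("segmentation.min_size must be < segmentation.max_size",
                  "ghostmap_config_error")
  }
  for (key in names(range_spec())) {
    rng <- range_spec()[[key]]
    val <- cfg[[strsplit(key, ".", fixed = TRUE)[[1]][1]]][[
      strsplit(key, ".", fixed = TRUE)[[1]][2]]]
    if (!is.numeric(val) || any(!is.finite(val)) ||
        any(val < rng[1]) || any(val > rng[2])) {
      stop_ghostmap(
        sprintf("parameter %s out of range: legal range is [%s, %s]",
                key, format(rng[1]), format(rng[2])),
        "ghostmap_config_error"
      )
    }
  }
  grid <- cfg$cluster$resolution_grid
  if (length(grid) == 0L || any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop_ghostmap(
      "parameter cluster.resolution_grid out of range: must be a non-empty strictly increasing positive sequence",
      "ghostmap_config_error"
    )
  }
  w <- cfg$ephys$mahp_window_ms
  if (length(w) != 2L || w[1] <= 0 || w[2] <= w[1]) {
    stop_ghostmap(
      "parameter ephys.mahp_window_ms out of range: must be an increasing positive pair",
      "ghostmap_config_error"
    )
  }
  cfg
}

# Recursively overlay user values on defaults, keeping unknown keys.
modify_defaults <- function(defaults, x) {
  for (nm in names(x)) {
    if (is.list(x[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], x[[nm]])
    } else {
      defaults[[nm]] <- x[[nm]]
    }
  }
  defaults
}
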