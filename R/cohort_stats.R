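#' Per-animal cohort summary of cell classes and marker shares
#'
#' Pools sections within each animal, then computes per-animal counts and
#' percentage shares: the typical/ghost split among lineage-positive cells
#' and, for every `marker_*` column, the marker-positive share within each
#' class. Percentages are reported both raw and integer-rounded
#' (half away from zero), matching how cohort shares are conventionally
#' printed. The animal is the statistical unit everywhere downstream,
#' avoiding pseudo-replication across sections or cells.
#'
#' @param cells A classified cell table (see [classify_lineage_cells()]).
#' @param by Extra grouping columns carried through (e.g. `"group"` for
#'   diet condition).
#' @return A tibble with one row per animal x class: `n`, `pct` (share of
#'   lineage-positive cells), `pct_int`, and one `pct_<marker>` column per
#'   marker call (share of marker-positive cells within the class).
#'   Animals without lineage-positive cells are dropped with a warning.
#' @export
summarize_cohort <- function(cells, by = "group") {
  cells <- tibble::as_tibble(cells)
  if (!"class_label" %in% names(cells)) {
    stop_ghostmap("class_label missing: classify cells first",
                  "ghostmap_value_error")
  }
  by <- intersect(by, names(cells))
  lin <- if ("lineage_positive" %in% names(cells)) {
    dplyr::filter(cells, .data$lineage_positive)
  } else {
    cells
  }
  empty <- setdiff(unique(cells$animal_id), unique(lin$animal_id))
  if (length(empty) > 0) {
    warn(paste0("animal(s) without lineage-positive cells excluded: ",
                paste(empty, collapse = ", ")))
  }
  marker_cols <- grep("^marker_", names(lin), value = TRUE)
  out <- lin |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "animal_id")))) |>
    dplyr::group_modify(function(df, key) {
      total <- nrow(df)
      per_class <- df |>
        dplyr::group_by(.data$class_label) |>
        dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
        dplyr::mutate(pct = 100 * .data$n / total,
                      pct_int = percent_shares(.data$n))
      for (mc in marker_cols) {
        shares <- df |>
          dplyr::group_by(.data$class_label) |>
          dplyr::summarise(p = 100 * mean(.data[[mc]]), .groups = "drop")
        per_class[[sub("^marker_", "pct_", mc)]] <-
          shares$p[match(per_class$class_label, shares$class_label)]
      }
      per_class
    }) |>
    dplyr::ungroup()
  out
}

#' Group mean and standard error of a per-animal summary variable
#'
#' @param per_animal Output of [summarize_cohort()] (or any per-animal
#'   tibble).
#' @param var Column to summarise.
#' @param by Grouping columns.
#' @return Tibble with `n`, `mean`, `sem` per group.
#' @export
group_mean_sem <- function(per_animal, var, by = "group") {
  per_animal |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = sum(is.finite(.data[[var]])),
      mean = mean(.data[[var]], na.rm = TRUE),
      sem = sd(.data[[var]], na.rm = TRUE) /
        sqrt(sum(is.finite(.data[[var]]))),
      .groups = "drop"
    )
}

#' Compare a per-animal variable between groups
#'
#' Two groups are compared with an unpaired two-tailed Student's t-test.
#' Three or more groups go through a Shapiro-Wilk normality gate per group
#' (alpha = 0.05, reported, not enforced), then a one-way ANOVA followed by
#' Tukey's honest-significant-difference pairwise table.
#'
#' @param per_animal Per-animal summary tibble.
#' @param var Response column name.
#' @param group Grouping column name.
#' @return An object of class `group_comparison`: design, the normality
#'   gate table, the test statistic tibble and (multi-group) the Tukey
#'   table. Use [tidy()] for a flat view.
#' @export
compare_groups <- function(per_animal, var, group = "group") {
  df <- tibble::tibble(
    y = per_animal[[var]],
    g = factor(per_animal[[group]])
  )
  df <- df[is.finite(df$y), ]
  sizes <- table(df$g)
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2) {
    stop_ghostmap("need at least two groups", "ghostmap_value_error")
  }
  if (any(sizes < 2)) {
    stop_ghostmap("every group needs >= 2 animals (variance undefined)",
                  "ghostmap_value_error")
  }
  df$g <- droplevels(df$g)
  shapiro_tbl <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(
      W = tryCatch(shapiro.test(.data$y)$statistic, error = function(e) NA_real_),
      p = tryCatch(shapiro.test(.data$y)$p.value, error = function(e) NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(normal = is.na(.data$p) | .data$p >= 0.05) |>
    dplyr::rename(group = "g")
  if (length(sizes) == 2) {
    tt <- t.test(y ~ g, data = df, var.equal = TRUE)
    res <- structure(
      list(
        design = "two_group",
        shapiro = shapiro_tbl,
        test = tibble::tibble(method = "Student t",
                              statistic = unname(tt$statistic),
                              df = unname(tt$parameter),
                              p = tt$p.value),
        tukey = NULL
      ),
      class = "group_comparison"
    )
  } else {
    fit <- aov(y ~ g, data = df)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    res <- structure(
      list(
        design = "multi_group",
        shapiro = shapiro_tbl,
        test = tibble::tibble(method = "one-way ANOVA",
                              statistic = an[["F value"]][1],
                              df = an[["Df"]][1],
                              df_resid = an[["Df"]][2],
                              p = an[["Pr(>F)"]][1]),
        tukey = tibble::as_tibble(tk, rownames = "contrast")
      ),
      class = "group_comparison"
    )
  }
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s = %.4g, p = %.4g\n",
              x$design, x$test$method, x$test$statistic, x$test$p))
  if (any(!x$shapiro$normal)) {
    cat("note: Shapiro-Wilk gate failed for group(s):",
        paste(x$shapiro$group[!x$shapiro$normal], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  x$test
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    design = x$design,
    statistic = x$test$statistic,
    p.value = x$test$p,
    shapiro_all_normal = all(x$shapiro$normal)
  )
}

#' Correlate a per-animal summary variable with a covariate
#'
#' Pearson correlation with a two-tailed p-value (e.g. ghost-cell share
#' against body weight). Rows with a missing covariate are dropped and
#' counted.
#'
#' @param per_animal Per-animal tibble.
#' @param var Response column.
#' @param covariate Covariate column (e.g. body weight).
#' @return Tibble with `r`, `p`, `n`, `n_dropped`.
#' @export
correlate_with_covariate <- function(per_animal, var, covariate) {
  x <- per_animal[[var]]
  yv <- per_animal[[covariate]]
  keep <- is.finite(x) & is.finite(yv)
  n_dropped <- sum(!keep)
  x <- x[keep]
  yv <- yv[keep]
  if (length(x) < 3) {
    stop_ghostmap("need >= 3 paired observations", "ghostmap_value_error")
  }
  if (sd(x) == 0 || sd(yv) == 0) {
    stop_ghostmap("zero variance: correlation undefined",
                  "ghostmap_value_error")
  }
  ct <- cor.test(x, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), n_dropped = n_dropped)
}
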