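#' Empirical cumulative distribution of cells along an anatomical axis
#'
#' Pools points of the selected subpopulation across animals and returns
#' the empirical CDF along one axis: each sorted position with cumulative
#' fraction k/n.
#'
#' @param cloud Point-cloud tibble.
#' @param subpop `"typical"`, `"ghost"` or `"all"`.
#' @param axis `"x"`, `"y"` or `"z"` (the rostro-caudal axis is `"z"` by
#'   convention), or an anatomical axis name matching the cloud's
#'   `axis_names` attribute.
#' @return Tibble with `position` (um, sorted) and `cum_frac` in (0, 1\].
#' @export
cumulative_axis_distribution <- function(cloud, subpop = "all",
                                         axis = "z") {
  axis_names <- attr(cloud, "axis_names") %||%
    c("medio-lateral", "dorso-ventral", "rostro-caudal")
  if (axis %in% axis_names) {
    axis <- c("x", "y", "z")[match(axis, axis_names)]
  }
  if (!axis %in% c("x", "y", "z")) {
    stop_ghostmap("axis must be x, y, z or an anatomical axis name",
                  "ghostmap_value_error")
  }
  sel <- cloud
  if (!identical(subpop, "all")) {
    sel <- dplyr::filter(sel, .data$subpop == .env$subpop)
  }
  v <- sort(sel[[axis]])
  if (length(v) < 2) {
    stop_ghostmap("need at least 2 points for a cumulative distribution",
                  "ghostmap_value_error")
  }
  tibble::tibble(position = v,
                 cum_frac = seq_along(v) / length(v))
}

#' Fit a Gaussian CDF to an empirical cumulative distribution
#'
#' Least-squares fit of `Phi((x - mu) / sigma)` to the cumulative
#' fractions (Levenberg-Marquardt, with perturbed restarts on failure).
#' This is the curve-fit form behind "Gaussian" cumulative-distribution
#' comparisons: `mu` locates the distribution along the axis, `sigma` its
#' spread.
#'
#' @param cdf Tibble from [cumulative_axis_distribution()] (`position`,
#'   `cum_frac`).
#' @param n_restarts Perturbed restarts before giving up.
#' @return Object of class `cdf_fit` with `mu`, `sigma`, `rss`,
#'   `n_points`, `model = "separate"` and the data.
#' @export
fit_gaussian_cdf <- function(cdf, n_restarts = 5) {
  if (nrow(cdf) < 5) {
    stop_ghostmap("need >= 5 CDF points to fit", "ghostmap_value_error")
  }
  if (diff(range(cdf$position)) == 0) {
    stop_ghostmap("degenerate CDF: all positions equal", "ghostmap_fit_error")
  }
  mu0 <- as.numeric(cdf$position[which.min(abs(cdf$cum_frac - 0.5))])
  q16 <- as.numeric(cdf$position[which.min(abs(cdf$cum_frac - 0.16))])
  q84 <- as.numeric(cdf$position[which.min(abs(cdf$cum_frac - 0.84))])
  s0 <- max((q84 - q16) / 2, diff(range(cdf$position)) / 20)
  fit <- NULL
  for (k in 0:n_restarts) {
    start <- list(
      mu = mu0 + if (k == 0) 0 else rnorm(1, 0, s0),
      sigma = s0 * if (k == 0) 1 else exp(rnorm(1, 0, 0.5))
    )
    fit <- tryCatch(
      minpack.lm::nlsLM(
        cum_frac ~ pnorm(position, mu, sigma),
        data = cdf, start = start,
        lower = c(mu = -Inf, sigma = .Machine$double.eps),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop_ghostmap(
      sprintf("Gaussian CDF fit failed after %d restarts (n = %d, range = [%.3g, %.3g])",
              n_restarts, nrow(cdf), min(cdf$position), max(cdf$position)),
      "ghostmap_fit_error"
    )
  }
  cf <- coef(fit)
  structure(
    list(mu = unname(cf["mu"]), sigma = unname(cf["sigma"]),
         rss = sum(resid(fit)^2), n_points = nrow(cdf),
         model = "separate", data = cdf),
    class = "cdf_fit"
  )
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat(sprintf("<cdf_fit> mu = %.4g um, sigma = %.4g um, rss = %.4g (n = %d)\n",
              x$mu, x$sigma, x$rss, x$n_points))
  invisible(x)
}

#' @export
tidy.cdf_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @export
glance.cdf_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, rss = x$rss,
                 n = x$n_points)
}

#' Extra-sum-of-squares F-test between two Gaussian CDF fits
#'
#' Compares a pooled model (one shared mu, sigma fitted to the
#' concatenated CDFs; 2 parameters) against separate per-distribution fits
#' (4 parameters): `F = ((RSS_pooled - RSS_sep) / (df_pooled - df_sep)) /
#' (RSS_sep / df_sep)` with `df = n - n_params`, referred to the F
#' distribution (upper tail). Cumulative fractions are treated as
#' independent observations, as the graphing convention underlying such
#' comparisons does; this is a documented approximation, not an exact
#' test.
#'
#' @param cdf_a,cdf_b CDF tibbles (or `cdf_fit` objects, whose data are
#'   reused).
#' @return Object of class `ess_ftest`: `F`, `df1`, `df2`, `p`,
#'   `rss_pooled`, `rss_separate`, the two separate fits and the pooled
#'   fit. A perfect separate fit (`RSS_sep = 0`) reports `F = Inf`,
#'   `p = 0`, flagged degenerate.
#' @export
compare_fits_extra_ss <- function(cdf_a, cdf_b) {
  dat <- function(x) if (inherits(x, "cdf_fit")) x$data else x
  a <- dat(cdf_a)
  b <- dat(cdf_b)
  fa <- fit_gaussian_cdf(a)
  fb <- fit_gaussian_cdf(b)
  pooled_data <- dplyr::bind_rows(a, b)
  fp <- fit_gaussian_cdf(pooled_data)
  n_tot <- nrow(pooled_data)
  rss_sep <- fa$rss + fb$rss
  rss_pool <- fp$rss
  df_sep <- n_tot - 4
  df_pool <- n_tot - 2
  degenerate <- rss_sep <= .Machine$double.eps * n_tot
  if (degenerate) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- max(0, ((rss_pool - rss_sep) / (df_pool - df_sep)) /
                    (rss_sep / df_sep))
    p <- pf(f_stat, df_pool - df_sep, df_sep, lower.tail = FALSE)
  }
  fp$model <- "pooled"
  structure(
    list(F = f_stat, df1 = df_pool - df_sep, df2 = df_sep, p = p,
         rss_pooled = rss_pool, rss_separate = rss_sep,
         fit_a = fa, fit_b = fb, fit_pooled = fp,
         degenerate = degenerate),
    class = "ess_ftest"
  )
}

#' @export
print.ess_ftest <- function(x, ...) {
  cat(sprintf("<ess_ftest> F(%d, %d) = %.4g, p = %.3g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$degenerate) " [degenerate: RSS_sep = 0]" else ""))
  invisible(x)
}

#' @export
tidy.ess_ftest <- function(x, ...) {
  tibble::tibble(statistic = x$F, df1 = x$df1, df2 = x$df2, p.value = x$p,
                 mu_a = x$fit_a$mu, mu_b = x$fit_b$mu,
                 sigma_a = x$fit_a$sigma, sigma_b = x$fit_b$sigma)
}

#' @export
glance.ess_ftest <- function(x, ...) {
  tibble::tibble(statistic = x$F, p.value = x$p,
                 rss_pooled = x$rss_pooled, rss_separate = x$rss_separate,
                 degenerate = x$degenerate)
}
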