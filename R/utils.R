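# Shared internal helpers.

# Round half away from zero, matching how cohort percentages are reported
# (e.g. 9/24 -> 38%, not the IEEE round-to-even 37%).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage shares of a count vector, integer-rounded for reporting.
percent_shares <- function(counts) {
  round_half_up(100 * counts / sum(counts))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_ghostmap <- function(msg, class) {
  abort(msg, class = c(class, "ghostmap_error"))
}

# Otsu's threshold on a numeric vector: maximise between-class variance over
# a binned histogram. Returns NA (degenerate) when the input carries no
# separable structure (constant input or a single occupied bin).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) {
    return(NA_real_)
  }
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(
    findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = n_bins
  )
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mu_t <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  if (!any(valid)) {
    return(NA_real_)
  }
  between <- rep(-Inf, n_bins)
  between[valid] <- (mu_t * cw[valid] - cm[valid])^2 /
    (cw[valid] * (1 - cw[valid]))
  k <- which.max(between)
  # threshold between the two classes; `>= threshold` is the positive side
  breaks[k + 1L]
}

# Pearson chi-squared on a count matrix, no continuity correction.
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop_ghostmap("contingency table must contain non-negative integers",
                  "ghostmap_value_error")
  }
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_tab == 0)) {
    stop_ghostmap("degenerate margin: an expected cell count is zero",
                  "ghostmap_value_error")
  }
  chi2 <- sum((tab - exp_tab)^2 / exp_tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
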