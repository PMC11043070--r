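#' Normalise a count matrix to log counts-per-10k
#'
#' Scales each cell's counts to a library size of 10^4, then applies
#' log(1 + x). This is the conventional normalisation for small
#' full-length single-cell libraries; the normalised vector of a cell is
#' invariant to scaling all its counts.
#'
#' @param x A [count_matrix] (or a bare integer matrix, genes x cells).
#' @return A numeric genes x cells matrix of normalised expression.
#' @export
normalize_counts <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop_ghostmap(
      paste0("cell(s) with zero total count: ",
             paste(head(bad, 5), collapse = ", "),
             if (length(bad) > 5) ", ..." else ""),
      "ghostmap_value_error"
    )
  }
  log1p(sweep(counts, 2, totals, `/`) * 1e4)
}
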