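#' Nonparanormal (rank-Gaussian) transformation
#'
#' Column-wise rank-based Gaussianization: each value is mapped to the
#' standard-normal quantile of \eqn{(\mathrm{rank} - 0.5)/n}, with
#' average ranks for ties. The transform is invariant to monotone
#' transformations of each column and makes the marginals compatible
#' with the Gaussian graphical model assumption.
#'
#' @param Y `n x p` numeric data matrix, `n >= 3`, no constant columns.
#' @return transformed matrix of the same dimension.
#' @examples
#' nonparanormal(cbind(a = c(1, 2, 3), b = c(10, 1, 5)))
#' @export
nonparanormal <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 3) stop("the nonparanormal transform needs at least 3 rows")
  out <- apply(Y, 2, function(col) {
    if (length(unique(col)) == 1L)
      stop("constant column: the nonparanormal transform is undefined")
    qnorm((rank(col, ties.method = "average") - 0.5) / n)
  })
  dimnames(out) <- dimnames(Y)
  out
}

#' Trailing moving average
#'
#' Mean over the last `window` observations; the first `window - 1`
#' outputs average over the available prefix (expanding window), so the
#' output has the same length as the input. The daily-surveillance
#' convention of a trailing (not centered) window is used.
#'
#' @param x ordered numeric series.
#' @param window window length (default 7, one week of daily data).
#' @return smoothed numeric vector, same length as `x`.
#' @examples
#' moving_average(1:7)  # last value is 4
#' @export
moving_average <- function(x, window = 7) {
  if (length(x) == 0) stop("'x' must be non-empty")
  if (window < 1) stop("'window' must be at least 1")
  cs <- cumsum(x)
  n <- length(x)
  k <- pmin(seq_len(n), window)
  lead <- c(rep(0, min(window, n)), cs[seq_len(max(0, n - window))])
  (cs - lead) / k
}
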