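#' Pearson correlation
#'
#' Linear dependence between two equal-length series, the classical
#' normalized covariance in [-1, 1].
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list of class `correlation_result` with `rho` and `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  structure(list(rho = stats::cor(x, y), n = length(x)),
            class = "correlation_result")
}

#' Time-lagged cross-correlation
#'
#' Pearson correlation as a function of integer lag. At lag `k >= 0` the
#' series `x[t]` is paired with `y[t + k]` over the overlapping support
#' (overlap truncation, no zero padding), so `best_lag = k` means `y` is a
#' copy of `x` delayed by `k` samples. Ties are broken toward the smallest
#' absolute lag.
#'
#' @param x,y numeric vectors.
#' @param max_lag maximum absolute lag in samples, below `length/2`.
#' @return list of class `tlcc_result` with `lags`, `rho_at_lag`,
#'   `best_lag`, `best_rho`.
#' @export
tlcc <- function(x, y, max_lag) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- min(length(x), length(y))
  if (max_lag >= n / 2) stop("max_lag must be below half the series length")
  lags <- (-max_lag):max_lag
  rho <- vapply(lags, function(k) {
    if (k >= 0) {
      xs <- x[1:(n - k)]; ys <- y[(k + 1L):n]
    } else {
      xs <- x[(1L - k):n]; ys <- y[1:(n + k)]
    }
    if (length(xs) < 3L) stop("overlap shorter than 3 samples at extreme lag")
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  ord <- order(-rho, abs(lags))  # ties toward smallest |lag|
  best <- ord[1]
  structure(list(lags = lags, rho_at_lag = rho,
                 best_lag = lags[best], best_rho = rho[best]),
            class = "tlcc_result")
}

#' Export a lag-correlation curve to CSV
#'
#' @param res a `tlcc_result`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_tlcc_csv <- function(res, path) {
  utils::write.csv(data.frame(lag = res$lags, rho = res$rho_at_lag),
                   path, row.names = FALSE)
  invisible(path)
}
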