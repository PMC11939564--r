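#' Uniformly sampled signal container
#'
#' Lightweight container for a real-valued, uniformly sampled series: radar
#' displacement in mm, arterial pressure in mmHg, or unitless values after
#' normalization.
#'
#' @param samples numeric vector of finite samples.
#' @param fs sampling rate in Hz (> 0).
#' @param t_start time of the first sample in seconds.
#' @param unit free-text unit label ("mm", "mmHg", "1").
#' @return An object of class `bp_signal` with fields `samples`, `fs`, `Ts`
#'   (= 1/fs), `t_start` and `unit`.
#' @examples
#' s <- bp_signal(sin(2 * pi * seq(0, 1, by = 0.01)), fs = 100)
#' s
#' @export
bp_signal <- function(samples, fs, t_start = 0, unit = "1") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (length(samples) && !all(is.finite(samples))) {
    stop("all samples must be finite")
  }
  structure(
    list(samples = samples, fs = fs, Ts = 1 / fs,
         t_start = as.numeric(t_start), unit = unit),
    class = "bp_signal"
  )
}

#' @export
print.bp_signal <- function(x, ...) {
  cat(sprintf("<bp_signal> %d samples @ %g Hz (%.2f s), unit '%s'\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$unit))
  invisible(x)
}

#' @export
length.bp_signal <- function(x) length(x$samples)

#' Sample times of a signal
#'
#' @param x a `bp_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "bp_signal"))
  x$t_start + (seq_along(x$samples) - 1) / x$fs
}

as_bp_signal <- function(x, fs) {
  if (inherits(x, "bp_signal")) x else bp_signal(x, fs)
}
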