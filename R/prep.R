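#' Preprocessing configuration
#'
#' Tunables of the radar preprocessing chain: arctangent demodulation,
#' band-pass filtering, resampling, per-window detrending, derivative channel
#' and L2 normalization.
#'
#' @param band numeric length-2 passband in Hz. Default `c(0.5, 15)`: wide
#'   enough to retain cardiac micro-vibrations and their harmonics while
#'   rejecting the respiratory band.
#' @param butter_order Butterworth order of the (single-direction) filter;
#'   applied forward and backward, so the effective magnitude response is the
#'   squared order-`butter_order` response. Default 4.
#' @param target_fs resampling target in Hz. Default 150.
#' @param derivative_order order of the second input channel's derivative:
#'   1, 2 or 3. Default 2 (acceleration-like channel).
#' @param guard_s seconds trimmed from each segment edge before windowing, to
#'   discard filter/demodulation edge transients. Default 0.25.
#' @param window_s analysis window duration in seconds. Default 2.
#' @return A validated list of class `prep_config`.
#' @export
prep_config <- function(band = c(0.5, 15), butter_order = 4L,
                        target_fs = 150, derivative_order = 2L,
                        guard_s = 0.25, window_s = 2) {
  stopifnot(length(band) == 2L, all(is.finite(band)))
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < target_fs / 2)) {
    stop("need 0 < band_low < band_high < target_fs/2")
  }
  if (!derivative_order %in% 1:3) stop("derivative_order must be 1, 2 or 3")
  stopifnot(butter_order >= 1, guard_s >= 0, window_s > 0)
  structure(
    list(band = as.numeric(band), butter_order = as.integer(butter_order),
         target_fs = as.numeric(target_fs),
         derivative_order = as.integer(derivative_order),
         guard_s = as.numeric(guard_s), window_s = as.numeric(window_s)),
    class = "prep_config"
  )
}

#' Arctangent demodulation of radar I/Q channels
#'
#' Recovers chest displacement from quadrature radar channels as
#' `unwrap(atan2(Q, I)) * wavelength / (4 pi)`, referenced so the first
#' sample is zero displacement.
#'
#' @param i,q `bp_signal` (or numeric) in-phase and quadrature channels of
#'   equal length and sampling rate.
#' @param wavelength radar carrier wavelength in meters.
#' @param fs sampling rate in Hz, required when `i`/`q` are plain vectors.
#' @return displacement `bp_signal` in mm.
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' d <- 0.2e-3 * sin(2 * pi * 1 * t)      # 0.2 mm vibration
#' phi <- 4 * pi * d / 0.0125
#' disp <- demodulate(cos(phi), sin(phi), wavelength = 0.0125, fs = 200)
#' @export
demodulate <- function(i, q, wavelength, fs = NULL) {
  if (!inherits(i, "bp_signal")) i <- bp_signal(i, fs)
  if (!inherits(q, "bp_signal")) q <- bp_signal(q, fs)
  if (length(i$samples) != length(q$samples)) stop("I/Q length mismatch")
  if (abs(i$fs - q$fs) > 1e-9) stop("I/Q sampling-rate mismatch")
  stopifnot(is.finite(wavelength), wavelength > 0)
  r2 <- i$samples^2 + q$samples^2
  if (any(r2 < .Machine$double.eps)) {
    stop("zero-magnitude I/Q sample: phase undefined")
  }
  phi <- signal::unwrap(atan2(q$samples, i$samples))
  d_m <- (phi - phi[1]) * wavelength / (4 * pi)
  bp_signal(d_m * 1000, fs = i$fs, t_start = i$t_start, unit = "mm")
}

# Design the band-pass used throughout (second-order sections).
design_bandpass <- function(fs, cfg) {
  nyq <- fs / 2
  if (cfg$band[2] >= nyq) stop("band edge at or above Nyquist")
  butter_sos(cfg$butter_order, cfg$band, fs, type = "pass")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Bidirectional (forward-backward) application of an order-`butter_order`
#' Butterworth band-pass, isolating the cardiac micro-vibration band. The
#' two passes cancel the phase response exactly, so band-interior components
#' come out with zero lag. Edges are odd-reflection padded (3x the filter
#' length) before filtering.
#'
#' @param x a `bp_signal`.
#' @param cfg a [prep_config()].
#' @return filtered `bp_signal`, same length and rate as the input.
#' @export
bandpass <- function(x, cfg = prep_config()) {
  stopifnot(inherits(x, "bp_signal"))
  flt <- design_bandpass(x$fs, cfg)
  y <- sos_filtfilt(flt, x$samples)
  bp_signal(y, fs = x$fs, t_start = x$t_start, unit = x$unit)
}

# Squared magnitude response of the bidirectional filter at frequency f (Hz):
# analytic oracle for the filtering contract.
bandpass_gain <- function(fs, f, cfg = prep_config()) {
  Mod(sos_resp(design_bandpass(fs, cfg), f))^2
}

#' Resample a signal to a lower rate
#'
#' Anti-alias filters with a zero-phase low-pass Butterworth (cutoff at 45%
#' of the target rate), then evaluates the band-limited series on the target
#' grid by interpolation. Duration is preserved within one output sample.
#'
#' @param x a `bp_signal`.
#' @param target_fs target sampling rate in Hz, below `x$fs`.
#' @return `bp_signal` at `target_fs`.
#' @export
resample_to <- function(x, target_fs) {
  stopifnot(inherits(x, "bp_signal"))
  if (target_fs >= x$fs) stop("resample_to only downsamples (target_fs < fs)")
  lp <- butter_sos(8L, 0.45 * target_fs, x$fs, type = "low")
  y <- sos_filtfilt(lp, x$samples)
  n_out <- floor(length(x$samples) * target_fs / x$fs)
  t_in <- (seq_along(y) - 1) / x$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  bp_signal(out, fs = target_fs, t_start = x$t_start, unit = x$unit)
}

#' Linear detrend by ordinary least squares
#'
#' Fits `x_i = alpha0 + alpha1 * t_i + xi_i` over the window by OLS on the
#' sample index and returns the residual series together with the fitted
#' trend model. Removes residual low-frequency/DC drift left after the wide
#' band-pass.
#'
#' @param x a `bp_signal` or numeric vector of length >= 2.
#' @return list with `signal` (residual `bp_signal`) and `trend`
#'   (class `trend_model`: `alpha0`, `alpha1` per sample index, `residual`).
#' @examples
#' detrend(bp_signal(c(1, 3, 2, 5), fs = 1))$trend$alpha1  # 1.1
#' @export
detrend <- function(x) {
  sig <- if (inherits(x, "bp_signal")) x else bp_signal(x, fs = 1)
  v <- sig$samples
  n <- length(v)
  if (n < 2L) stop("detrend needs at least 2 samples")
  ti <- seq_len(n) - 1
  tbar <- mean(ti)
  stt <- sum((ti - tbar)^2)
  alpha1 <- sum((ti - tbar) * (v - mean(v))) / stt
  alpha0 <- mean(v) - alpha1 * tbar
  res <- v - (alpha0 + alpha1 * ti)
  list(
    signal = bp_signal(res, fs = sig$fs, t_start = sig$t_start, unit = sig$unit),
    trend = structure(list(alpha0 = alpha0, alpha1 = alpha1, residual = res),
                      class = "trend_model")
  )
}

#' Finite-difference derivative channel
#'
#' Order 2 uses the central second difference
#' `(y[n+1] - 2 y[n] + y[n-1]) / Ts^2` (exact for quadratics); orders 1 and 3
#' apply the central first difference `(y[n+1] - y[n-1]) / (2 Ts)`
#' iteratively. Length is preserved by replicate-edge padding.
#'
#' @param x a `bp_signal`.
#' @param order derivative order, 1, 2 or 3.
#' @return `bp_signal` of the derivative series.
#' @export
nth_derivative <- function(x, order = 2L) {
  stopifnot(inherits(x, "bp_signal"))
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  v <- x$samples
  if (length(v) < order + 1L) stop("input too short for derivative order")
  Ts <- x$Ts
  central1 <- function(y) {
    yp <- c(y[1], y, y[length(y)])  # replicate-edge padding
    (yp[3:(length(y) + 2L)] - yp[1:length(y)]) / (2 * Ts)
  }
  out <- if (order == 2L) {
    yp <- c(v[1], v, v[length(v)])
    (yp[3:(length(v) + 2L)] - 2 * v + yp[1:length(v)]) / Ts^2
  } else {
    y <- v
    for (k in seq_len(order)) y <- central1(y)
    y
  }
  bp_signal(out, fs = x$fs, t_start = x$t_start, unit = paste0(x$unit, "/s^", order))
}

#' L2 normalization
#'
#' Scales a vector to unit Euclidean norm, preserving direction. Degenerate
#' (zero-norm) windows are an error; callers drop them.
#'
#' @param x numeric vector with nonzero norm.
#' @return numeric vector with `sqrt(sum(x^2)) == 1`.
#' @examples
#' l2_normalize(c(3, 4))  # 0.6 0.8
#' @export
l2_normalize <- function(x) {
  x <- as.numeric(x)
  nrm <- sqrt(sum(x^2))
  if (!is.finite(nrm) || nrm == 0) stop("zero or non-finite norm")
  x / nrm
}

#' Preprocess a subject record into the radar chest micro-vibration signal
#'
#' Applies the fixed chain demodulate -> band-pass -> resample -> guard trim.
#' Per-window detrending, the derivative channel and L2 normalization happen
#' at segmentation time (see [segment_windows()]), which completes the chain
#' in the order demodulate, band-pass, resample, segment, detrend,
#' derivative, normalize.
#'
#' @param record a `subject_record` from [simulate_subject()].
#' @param cfg a [prep_config()].
#' @return list with `rcmv` (`bp_signal` at `cfg$target_fs`) and `bp`
#'   (reference pressure `bp_signal`, guard-trimmed to the same time span).
#' @export
preprocess_record <- function(record, cfg = prep_config()) {
  stopifnot(inherits(record, "subject_record"))
  disp <- demodulate(bp_signal(record$radar_i, record$radar_fs),
                     bp_signal(record$radar_q, record$radar_fs),
                     wavelength = record$wavelength)
  filt <- bandpass(disp, cfg)
  rcmv <- resample_to(filt, cfg$target_fs)
  bp <- bp_signal(record$bp_wave, record$bp_fs, unit = "mmHg")
  if (cfg$guard_s > 0) {
    rcmv <- trim_guard(rcmv, cfg$guard_s)
    bp <- trim_guard(bp, cfg$guard_s)
  }
  list(rcmv = rcmv, bp = bp)
}

trim_guard <- function(x, guard_s) {
  n <- length(x$samples)
  k <- round(guard_s * x$fs)
  if (2 * k >= n) stop("guard interval longer than record")
  bp_signal(x$samples[(k + 1L):(n - k)], fs = x$fs,
            t_start = x$t_start + k / x$fs, unit = x$unit)
}
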