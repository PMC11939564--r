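# Butterworth design in second-order sections (SOS).
#
# At this pipeline's sampling rates the band edges sit at ~5e-4 of the
# sampling rate; an order-4 band-pass expanded into a single transfer
# function is numerically degenerate there (rooting the direct-form
# denominator puts poles outside the unit circle). Cascaded biquads keep
# every section well conditioned, so the design is done analytically:
# analog Butterworth prototype -> band transform -> bilinear transform,
# poles paired into conjugate biquads.

butter_sos <- function(order, edges, fs, type = c("pass", "low")) {
  type <- match.arg(type)
  if (order %% 2L != 0L) stop("even filter order required")
  stopifnot(all(edges > 0), all(edges < fs / 2))
  # analog prototype poles (left half plane, unit cutoff)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "low") {
    Wc <- warp(edges[1])
    s_poles <- p_proto * Wc
    n_z1 <- 0L                      # no zeros at z = 1
    f_ref <- 0                      # unit gain at DC
  } else {
    stopifnot(length(edges) == 2L, edges[1] < edges[2])
    W1 <- warp(edges[1]); W2 <- warp(edges[2])
    BW <- W2 - W1; W0 <- sqrt(W1 * W2)
    s_poles <- c()
    for (p in p_proto) {
      disc <- sqrt(as.complex((p * BW)^2 - 4 * W0^2))
      s_poles <- c(s_poles, (p * BW + disc) / 2, (p * BW - disc) / 2)
    }
    n_z1 <- order                   # zeros at z = 1 (from s = 0)
    f_ref <- fs / pi * atan(W0 / (2 * fs))  # geometric center, unit gain
  }
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  if (any(Mod(z_poles) >= 1)) stop("internal: unstable pole in SOS design")
  # pair each pole with its conjugate
  up <- z_poles[Im(z_poles) >= 0]
  up <- up[order(Mod(up))]
  n_sec <- length(up)
  secs <- vector("list", n_sec)
  for (j in seq_len(n_sec)) {
    p <- up[j]
    a <- c(1, -2 * Re(p), Mod(p)^2)
    b <- if (j <= n_z1) c(1, 0, -1) else c(1, 2, 1)
    secs[[j]] <- list(b = b, a = a)
  }
  # normalize each section to unit magnitude at the reference frequency
  for (j in seq_len(n_sec)) {
    g <- Mod(sos_section_resp(secs[[j]], f_ref, fs))
    secs[[j]]$b <- secs[[j]]$b / g
  }
  structure(list(sections = secs, fs = fs, f_low = min(edges),
                 type = type), class = "sos_filter")
}

sos_section_resp <- function(sec, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (0:2))
  sum(sec$b * z) / sum(sec$a * z)
}

# Complex frequency response of the one-directional cascade at f (Hz).
sos_resp <- function(flt, f) {
  vapply(f, function(ff) {
    prod(vapply(flt$sections, sos_section_resp, complex(1), ff, flt$fs))
  }, complex(1))
}

sos_apply <- function(flt, x) {
  for (sec in flt$sections) {
    x <- as.numeric(signal::filter(sec$b, sec$a, x))
  }
  x
}

# Zero-phase forward-backward cascade with odd-reflection edge padding.
# The pad must outlast the slowest transient, which for a band-pass is set
# by the low corner: use three corner time constants (at least 3x the
# filter length), capped at the signal length. A band-pass rejects DC, so
# the series is centred first to keep the edge transient of any large
# offset out of the pass band.
sos_filtfilt <- function(flt, x) {
  n <- length(x)
  mu <- 0
  if (flt$type == "pass") {
    mu <- mean(x)
    x <- x - mu
  }
  npad <- max(3L * (2L * length(flt$sections) + 1L),
              ceiling(3 * flt$fs / flt$f_low))
  npad <- min(npad, n - 1L)
  if (npad < 2L * length(flt$sections) + 1L) {
    stop("input too short for filter edge padding")
  }
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- sos_apply(flt, xp)
  y <- rev(sos_apply(flt, rev(y)))
  y[(npad + 1L):(npad + n)]
}
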