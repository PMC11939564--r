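test_that("demodulation inverts the phase model", {
  n <- 400
  # constant (i, q) = (1, 0): zero phase, zero displacement
  z <- demodulate(rep(1, n), rep(0, n), wavelength = 0.0125, fs = 100)
  expect_close(z$samples, rep(0, n))
  # linear phase ramp phi(t) = 2 pi t with lambda = 0.01 m:
  # displacement slope = 2 pi * 0.01 / (4 pi) = 0.005 m/s = 5 mm/s
  t <- (0:(n - 1)) / 100
  phi <- 2 * pi * t
  d <- demodulate(cos(phi), sin(phi), wavelength = 0.01, fs = 100)
  slope <- stats::coef(stats::lm(d$samples ~ t))[2]
  expect_close(slope, 5, tol = 1e-6)
  expect_error(demodulate(rep(0, n), rep(0, n), 0.01, fs = 100), "zero")
  expect_error(demodulate(rep(1, n), rep(0, n - 1), 0.01, fs = 100),
               "mismatch")
})

test_that("band-pass matches its analytic magnitude response and is zero-phase", {
  fs <- 2000
  t <- seq(0, 20, by = 1 / fs)
  mid <- 10000:30000  # away from edges
  # 5 Hz probe, inside the band
  s5 <- bp_signal(sin(2 * pi * 5 * t), fs)
  f5 <- bandpass(s5)
  g5 <- radbp:::bandpass_gain(fs, 5)
  amp5 <- max(abs(f5$samples[mid]))
  expect_lt(abs(amp5 - 1), 0.02)            # within 2% of input
  expect_lt(abs(amp5 - sqrt(g5)^2) / amp5, 0.02)  # oracle: |H|^2 response
  cc <- stats::ccf(f5$samples, s5$samples, lag.max = 50, plot = FALSE)
  expect_identical(as.integer(cc$lag[which.max(cc$acf)]), 0L)
  # 0.05 Hz probe (respiration band): attenuated by far more than 20 dB
  s_lo <- bp_signal(sin(2 * pi * 0.05 * t), fs)
  f_lo <- bandpass(s_lo)
  expect_lt(20 * log10(max(abs(f_lo$samples[mid]))), -20)
  expect_lt(10 * log10(radbp:::bandpass_gain(fs, 0.05)), -20)
  # all-zero input stays zero
  expect_close(bandpass(bp_signal(numeric(5000), fs))$samples,
               numeric(5000), tol = 1e-12)
})

test_that("zero-phase holds across band-interior frequencies", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  for (f in c(1, 3, 8, 12)) {
    s <- bp_signal(sin(2 * pi * f * t), fs)
    y <- bandpass(s)
    cc <- stats::ccf(y$samples, s$samples, lag.max = 30, plot = FALSE)
    lag0 <- cc$acf[cc$lag == 0]
    # the zero-lag correlation is (numerically) the maximum: any apparent
    # argmax offset on these slow tones is below 1e-9 in correlation
    expect_lt(max(cc$acf) - lag0, 1e-9)
  }
})

test_that("resampling preserves duration, amplitude and DC level", {
  fs <- 2000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  r <- resample_to(bp_signal(sin(2 * pi * 1 * t), fs), 150)
  expect_identical(length(r$samples), 1500L)
  expect_equal(r$fs, 150)
  expect_lt(abs(max(abs(r$samples[200:1300])) - 1), 0.02)
  dc <- resample_to(bp_signal(rep(3.5, 20000), fs), 150)
  expect_close(dc$samples[100:1400], rep(3.5, 1301), tol = 1e-6)
  expect_error(resample_to(bp_signal(rnorm(100), 100), 200), "downsample")
})

test_that("detrend equals the closed-form OLS fit", {
  # constant series
  d1 <- detrend(bp_signal(c(5, 5, 5, 5), 1))
  expect_close(d1$signal$samples, rep(0, 4))
  expect_close(d1$trend$alpha0, 5)
  expect_close(d1$trend$alpha1, 0)
  # exact line
  d2 <- detrend(bp_signal(c(1, 2, 3, 4), 1))
  expect_close(d2$signal$samples, rep(0, 4))
  expect_close(d2$trend$alpha1, 1)
  # general case against hand-computed OLS on index t in {0..3}:
  # alpha1 = 5.5/5 = 1.1, alpha0 = 2.75 - 1.1*1.5 = 1.1
  d3 <- detrend(bp_signal(c(1, 3, 2, 5), 1))
  expect_close(d3$trend$alpha1, 1.1)
  expect_close(d3$trend$alpha0, 1.1)
  expect_close(d3$signal$samples, c(-0.1, 0.8, -1.3, 0.6))
  # residual is centred and uncorrelated with the index
  expect_lt(abs(mean(d3$signal$samples)), 1e-9)
  expect_lt(abs(sum(d3$signal$samples * (0:3))), 1e-9)
  expect_error(detrend(bp_signal(1, 1)), "2 samples")
})

test_that("detrend is idempotent", {
  set.seed(11)
  x <- bp_signal(cumsum(rnorm(200)), 50)
  once <- detrend(x)$signal
  twice <- detrend(once)$signal
  expect_close(twice$samples, once$samples, tol = 1e-9)
})

test_that("derivative channel implements the central difference scheme", {
  n <- 0:20
  # quadratic with Ts = 1: interior second derivative exactly 2
  d <- nth_derivative(bp_signal(n^2, 1), 2L)
  expect_close(d$samples[2:20], rep(2, 19))
  # linear series: interior second derivative 0
  dl <- nth_derivative(bp_signal(3 * n + 1, 1), 2L)
  expect_close(dl$samples[2:20], rep(0, 19))
  # Ts = 0.1 rescales by 1/Ts^2: 2 / 0.01 = 200
  ds <- nth_derivative(bp_signal((n / 10)^2 * 100, 10), 2L)
  expect_close(ds$samples[2:20], rep(200, 19))
  expect_identical(length(d$samples), 21L)  # length preserved
  expect_error(nth_derivative(bp_signal(c(1, 2), 1), 2L), "short")
})

test_that("second derivative equals first derivative applied twice on interior", {
  set.seed(4)
  x <- bp_signal(rnorm(100), 10)
  d2 <- nth_derivative(x, 2L)
  d11 <- nth_derivative(nth_derivative(x, 1L), 1L)
  # central-first-difference twice spans +/-2 samples; compare away from edges
  # and at matching stencils: d1(d1) uses (y[n+2]-2y[n]+y[n-2])/(2Ts)^2, so
  # compare on a quadratic where both are exact
  q <- bp_signal((0:99)^2, 1)
  a <- nth_derivative(q, 2L)$samples[3:98]
  b <- nth_derivative(nth_derivative(q, 1L), 1L)$samples[3:98]
  expect_close(a, b, tol = 1e-9)
  expect_identical(length(d11$samples), length(d2$samples))
})

test_that("L2 normalization scales to the unit sphere", {
  expect_close(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(1, 0, 0)
  expect_close(l2_normalize(u), u)
  set.seed(2)
  for (k in 1:5) {
    v <- rnorm(20)
    expect_close(sqrt(sum(l2_normalize(v)^2)), 1, tol = 1e-12)
  }
  expect_error(l2_normalize(numeric(3)), "norm")
})

test_that("preprocess_record applies the full front end coherently", {
  rec <- clean_record()
  pre <- clean_prep()
  expect_equal(pre$rcmv$fs, 150)
  # guard trim: both streams shifted by the same guard interval (to the
  # nearest sample of each stream's rate)
  expect_equal(pre$rcmv$t_start, round(0.25 * 150) / 150)
  expect_equal(pre$bp$t_start, round(0.25 * 200) / 200)
  # band-passed micro-vibration correlates with the band-passed truth pulses
  truth_d <- bp_signal(rec$displacement_mm, rec$radar_fs)
  truth_f <- resample_to(bandpass(truth_d), 150)
  k <- round(0.25 * 150)
  tf <- truth_f$samples[(k + 1):(length(truth_f$samples) - k)]
  expect_gt(stats::cor(pre$rcmv$samples, tf), 0.999)
})
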