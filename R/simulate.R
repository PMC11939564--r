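#' Co-simulator configuration
#'
#' Conditions for the synthetic radar / arterial-pressure co-simulation: a
#' chest-displacement signal (respiration sinusoid + per-beat cardiac pulse
#' train + Gaussian noise) wrapped into radar I/Q phase, and a beat-resolved
#' pressure waveform whose systolic peaks and diastolic troughs drift over
#' time and modulate the radar pulse morphology.
#'
#' @param duration_s record duration in seconds.
#' @param radar_fs radar sampling rate in Hz (default 2000).
#' @param bp_fs pressure-waveform sampling rate in Hz (default 200).
#' @param wavelength radar carrier wavelength in meters (default 0.0125,
#'   a 24 GHz continuous-wave carrier).
#' @param hr_range heart-rate interval in beats/min from which the subject
#'   baseline is drawn.
#' @param resp_rate respiration rate in Hz.
#' @param resp_amp_mm respiration chest-displacement amplitude in mm.
#' @param sbp_range,dbp_range systolic/diastolic baseline intervals in mmHg;
#'   must lie inside the physiologic band (40, 180].
#' @param bp_drift_sd per-beat random-walk step SD in mmHg driving slow
#'   within-record pressure drift.
#' @param bp_couple desired correlation of the systolic and diastolic drift
#'   steps (default 0.7, matching the strong systolic-diastolic coupling seen
#'   in clinical recordings).
#' @param pulse_amp_gain cardiac pulse displacement amplitude in mm per mmHg
#'   of pulse pressure (SBP - DBP).
#' @param noise_sd additive displacement noise SD in mm.
#' @param scenario one of "rest", "valsalva", "apnea", "tilt". Apnea zeroes
#'   the respiration amplitude; valsalva/tilt inject a transient +20/-20 mmHg
#'   ramp mid-record (a labelled emulation, not a hemodynamic model).
#' @param t0_offset radar-vs-pressure clock offset in seconds (radar events
#'   appear `t0_offset` later); nonzero only for lag-analysis tests.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 300, radar_fs = 2000, bp_fs = 200,
                       wavelength = 0.0125, hr_range = c(55, 95),
                       resp_rate = 0.25, resp_amp_mm = 2,
                       sbp_range = c(100, 140), dbp_range = c(60, 90),
                       bp_drift_sd = 0.5, bp_couple = 0.7,
                       pulse_amp_gain = 0.005, noise_sd = 0.02,
                       scenario = c("rest", "valsalva", "apnea", "tilt"),
                       t0_offset = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  num <- c(duration_s, radar_fs, bp_fs, wavelength, hr_range, resp_rate,
           resp_amp_mm, sbp_range, dbp_range, bp_drift_sd, bp_couple,
           pulse_amp_gain, noise_sd, t0_offset, seed)
  if (!all(is.finite(num))) stop("non-finite configuration value")
  if (duration_s <= 0) stop("duration_s must be positive")
  stopifnot(radar_fs > 0, bp_fs > 0, wavelength > 0, resp_rate > 0,
            all(hr_range > 0), hr_range[1] <= hr_range[2])
  if (!(sbp_range[1] > 40 && sbp_range[2] <= 180)) {
    stop("sbp_range must lie within (40, 180]")
  }
  if (!(dbp_range[1] >= 40 && dbp_range[2] < 180)) {
    stop("dbp_range must lie within [40, 180)")
  }
  stopifnot(sbp_range[1] <= sbp_range[2], dbp_range[1] <= dbp_range[2],
            bp_drift_sd >= 0, bp_couple >= 0, bp_couple <= 1,
            pulse_amp_gain >= 0, noise_sd >= 0, resp_amp_mm >= 0)
  structure(as.list(environment())[c(
    "duration_s", "radar_fs", "bp_fs", "wavelength", "hr_range", "resp_rate",
    "resp_amp_mm", "sbp_range", "dbp_range", "bp_drift_sd", "bp_couple",
    "pulse_amp_gain", "noise_sd", "scenario", "t0_offset", "seed")],
    class = "sim_config")
}

# Evaluate `expr` under a local RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Cardiac pulse displacement amplitude (mm) as a function of pulse pressure.
# Strictly increasing by construction: the learnable link the regressor uses.
pulse_amplitude <- function(config, pulse_pressure) {
  config$pulse_amp_gain * pulse_pressure
}

reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(rep(lo, length(x)))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate one subject record
#'
#' Deterministic given the seed in `config`. Chest displacement is the sum of
#' a respiration sinusoid, a per-beat raised-cosine cardiac pulse train whose
#' amplitude is proportional to the instantaneous pulse pressure, and white
#' Gaussian noise; the radar channels are `cos(4 pi d / lambda)` and
#' `sin(4 pi d / lambda)`. The reference pressure waveform rises linearly to
#' the systolic value over 15% of each beat interval and decays
#' exponentially to the diastolic value.
#'
#' @param config a [sim_config()].
#' @param subject_id identifier stored with the record.
#' @return object of class `subject_record` with radar I/Q, the stored true
#'   displacement, the pressure waveform, a per-beat truth table
#'   (`beat_time`, `sbp`, `dbp`), scenario segment table and the seed.
#' @export
simulate_subject <- function(config = sim_config(), subject_id = "S01") {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    dur <- config$duration_s
    # -- per-subject baselines ------------------------------------------------
    base_hr <- stats::runif(1, config$hr_range[1], config$hr_range[2])
    base_dbp <- stats::runif(1, config$dbp_range[1], config$dbp_range[2])
    base_sbp <- stats::runif(1, config$sbp_range[1], config$sbp_range[2])
    base_sbp <- min(max(base_sbp, base_dbp + 25), config$sbp_range[2])

    # -- beat process ---------------------------------------------------------
    n_max <- ceiling(dur * config$hr_range[2] / 60) + 8L
    hr_steps <- stats::rnorm(n_max, 0, 0.3)
    hr <- reflect_into(base_hr + cumsum(hr_steps),
                       config$hr_range[1], config$hr_range[2])
    intervals <- 60 / hr
    beat_time <- 0.4 + cumsum(c(0, intervals[-n_max]))
    keep <- beat_time <= dur - 0.2
    beat_time <- beat_time[keep]
    intervals <- intervals[keep]
    nb <- length(beat_time)
    if (nb < 1L) stop("duration too short for a single beat")
    # snap systolic peak times to the pressure grid so sampled maxima equal
    # the truth exactly
    beat_time <- round(beat_time * config$bp_fs) / config$bp_fs

    # -- coupled SBP/DBP drift ------------------------------------------------
    w <- sqrt(config$bp_couple)
    e_c <- stats::rnorm(nb, 0, config$bp_drift_sd)
    e_s <- stats::rnorm(nb, 0, config$bp_drift_sd)
    e_d <- stats::rnorm(nb, 0, config$bp_drift_sd)
    sqc <- sqrt(max(0, 1 - w^2))
    sbp <- reflect_into(base_sbp + cumsum(w * e_c + sqc * e_s),
                        config$sbp_range[1], config$sbp_range[2])
    dbp <- reflect_into(base_dbp + cumsum(w * e_c + sqc * e_d),
                        config$dbp_range[1], config$dbp_range[2])

    # -- scenario block -------------------------------------------------------
    segments <- data.frame(start = 0, end = dur, label = config$scenario,
                           stringsAsFactors = FALSE)
    resp_amp <- if (config$scenario == "apnea") 0 else config$resp_amp_mm
    if (config$scenario %in% c("valsalva", "tilt")) {
      sgn <- if (config$scenario == "valsalva") 1 else -1
      b0 <- 0.4 * dur; b1 <- 0.6 * dur
      ramp <- 20 * sgn * pmax(0, 1 - abs(beat_time - (b0 + b1) / 2) / ((b1 - b0) / 2))
      sbp <- pmin(pmax(sbp + ramp, 41), 180)
      dbp <- pmin(pmax(dbp + ramp, 40), 179)
      segments <- data.frame(start = c(0, b0, b1), end = c(b0, b1, dur),
                             label = c("rest", config$scenario, "rest"),
                             stringsAsFactors = FALSE)
    }
    dbp <- pmin(dbp, sbp - 10)  # physiologic ordering, generous margin

    # -- displacement on the radar grid --------------------------------------
    n_r <- round(dur * config$radar_fs)
    t_r <- (seq_len(n_r) - 1) / config$radar_fs - config$t0_offset
    resp_phase <- stats::runif(1, 0, 2 * pi)
    d <- resp_amp * sin(2 * pi * config$resp_rate * t_r + resp_phase)
    amp <- pulse_amplitude(config, sbp - dbp)
    width <- 0.3 * intervals
    for (b in seq_len(nb)) {
      lo <- beat_time[b] - width[b] / 2
      i0 <- max(1L, ceiling((lo + config$t0_offset) * config$radar_fs) + 1L)
      i1 <- min(n_r, floor((lo + width[b] + config$t0_offset) * config$radar_fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      d[idx] <- d[idx] + amp[b] * 0.5 *
        (1 + cos(2 * pi * (t_r[idx] - beat_time[b]) / width[b]))
    }
    if (config$noise_sd > 0) d <- d + stats::rnorm(n_r, 0, config$noise_sd)
    phi <- 4 * pi * (d / 1000) / config$wavelength

    # -- pressure waveform on the bp grid ------------------------------------
    n_bp <- round(dur * config$bp_fs)
    t_bp <- (seq_len(n_bp) - 1) / config$bp_fs
    bp <- rep(dbp[1], n_bp)
    onset <- beat_time - 0.15 * intervals
    cycle_end <- c(onset[-1], min(dur, beat_time[nb] + 0.85 * intervals[nb]))
    prev_level <- dbp[1]
    for (b in seq_len(nb)) {
      i_on <- max(1L, ceiling(onset[b] * config$bp_fs) + 1L)
      i_pk <- round(beat_time[b] * config$bp_fs) + 1L
      i_end <- min(n_bp, floor(cycle_end[b] * config$bp_fs) + 1L)
      if (i_pk > n_bp) break
      if (i_pk > i_on) {
        fr <- (t_bp[i_on:i_pk] - onset[b]) / (beat_time[b] - onset[b])
        bp[i_on:i_pk] <- prev_level + (sbp[b] - prev_level) * pmin(pmax(fr, 0), 1)
      }
      bp[i_pk] <- sbp[b]
      if (i_end > i_pk) {
        tau <- (cycle_end[b] - beat_time[b]) / 6
        bp[i_pk:i_end] <- dbp[b] +
          (sbp[b] - dbp[b]) * exp(-(t_bp[i_pk:i_end] - beat_time[b]) / tau)
      }
      prev_level <- bp[min(i_end, n_bp)]
      if (b == nb && i_end < n_bp) bp[(i_end + 1L):n_bp] <- bp[i_end]
    }

    structure(list(
      subject_id = subject_id,
      radar_i = cos(phi), radar_q = sin(phi), radar_fs = config$radar_fs,
      displacement_mm = d,
      bp_wave = bp, bp_fs = config$bp_fs,
      wavelength = config$wavelength, t0_offset = config$t0_offset,
      truth = data.frame(beat_time = beat_time, sbp = sbp, dbp = dbp),
      scenario = config$scenario, segments = segments,
      seed = config$seed, config = config
    ), class = "subject_record")
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "<subject_record> %s: %.0f s radar @ %g Hz, pressure @ %g Hz, %d beats, scenario '%s', seed %d\n",
    x$subject_id, length(x$radar_i) / x$radar_fs, x$radar_fs, x$bp_fs,
    nrow(x$truth), x$scenario, as.integer(x$seed)))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived reproducibly from the master seed;
#' inter-subject variation of baseline pressure and heart rate arises from
#' the per-subject draws inside [simulate_subject()].
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base a [sim_config()] used for every subject (its `seed` field is
#'   replaced by the derived per-subject seed).
#' @param seed master integer seed.
#' @param scenarios optional character vector recycled across subjects to
#'   vary the scenario label per subject.
#' @return list of `subject_record`, one per subject.
#' @export
simulate_cohort <- function(n_subjects, base = sim_config(), seed = 1L,
                            scenarios = NULL) {
  stopifnot(n_subjects >= 1)
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n_subjects))
  lapply(seq_len(n_subjects), function(k) {
    cfg <- base
    cfg$seed <- seeds[k]
    if (!is.null(scenarios)) {
      cfg$scenario <- scenarios[((k - 1L) %% length(scenarios)) + 1L]
    }
    simulate_subject(cfg, subject_id = sprintf("S%02d", k))
  })
}
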