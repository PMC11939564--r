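#' Construct a window-sample set
#'
#' Container for the model-ready dataset: dual-channel fixed-length windows
#' (row 1: detrended, L2-normalized chest micro-vibration; row 2: its
#' derivative channel) with per-window systolic/diastolic labels and
#' provenance.
#'
#' @param channels numeric array `N x 2 x L`.
#' @param sbp,dbp numeric label vectors (mmHg) of length `N`.
#' @param subject_id character vector of length `N`.
#' @param scenario character vector of length `N`.
#' @param window_start_s numeric vector of window start times (s).
#' @return object of class `window_set`.
#' @export
window_set <- function(channels, sbp, dbp, subject_id, scenario,
                       window_start_s) {
  stopifnot(length(dim(channels)) == 3L, dim(channels)[2] == 2L)
  n <- dim(channels)[1]
  stopifnot(length(sbp) == n, length(dbp) == n, length(subject_id) == n,
            length(scenario) == n, length(window_start_s) == n)
  structure(list(channels = channels, sbp = sbp, dbp = dbp,
                 subject_id = subject_id, scenario = scenario,
                 window_start_s = window_start_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of length %d, %d subject(s)\n",
              n_windows(x), dim(x$channels)[3],
              length(unique(x$subject_id))))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @export
n_windows <- function(ws) dim(ws$channels)[1]

#' Subset a window set by index
#' @param ws a `window_set`.
#' @param idx integer indices of windows to keep.
#' @export
window_subset <- function(ws, idx) {
  window_set(ws$channels[idx, , , drop = FALSE], ws$sbp[idx], ws$dbp[idx],
             ws$subject_id[idx], ws$scenario[idx], ws$window_start_s[idx])
}

#' Concatenate window sets
#' @param ... `window_set` objects with equal window length.
#' @export
window_bind <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "window_set")) parts <- parts[[1]]
  parts <- Filter(function(p) n_windows(p) > 0L, parts)
  if (!length(parts)) stop("no non-empty window sets to bind")
  L <- dim(parts[[1]]$channels)[3]
  ntot <- sum(vapply(parts, n_windows, integer(1)))
  ch <- array(0, c(ntot, 2, L))
  at <- 0L
  for (p in parts) {
    np <- n_windows(p)
    ch[(at + 1L):(at + np), , ] <- p$channels
    at <- at + np
  }
  window_set(ch,
             unlist(lapply(parts, `[[`, "sbp")),
             unlist(lapply(parts, `[[`, "dbp")),
             unlist(lapply(parts, `[[`, "subject_id")),
             unlist(lapply(parts, `[[`, "scenario")),
             unlist(lapply(parts, `[[`, "window_start_s")))
}

#' Segment a record into labelled, peak-anchored windows
#'
#' The first window starts at the first valid systolic peak; subsequent
#' windows tile forward without overlap. Each window carries the detrended,
#' L2-normalized micro-vibration channel and its derivative channel. Window
#' labels are the mean systolic/diastolic values of the valid beats whose
#' peak falls inside the window. Windows containing any invalid beat, or no
#' complete beat, are dropped.
#'
#' @param rcmv preprocessed chest micro-vibration `bp_signal`.
#' @param bp arterial pressure `bp_signal` time-aligned with `rcmv`.
#' @param beats `beat_annotation` from [detect_beats()] on `bp`.
#' @param cfg a [prep_config()] (window length, derivative order).
#' @param subject_id,scenario provenance labels.
#' @param segments optional data.frame (`start`, `end`, `label`) assigning a
#'   scenario label per window from its midpoint.
#' @return list with `windows` (a `window_set`) and `counts`
#'   (`tiled`, `emitted`, `dropped`).
#' @export
segment_windows <- function(rcmv, bp, beats, cfg = prep_config(),
                            subject_id = "S01", scenario = "rest",
                            segments = NULL) {
  stopifnot(inherits(rcmv, "bp_signal"), inherits(bp, "bp_signal"))
  L <- round(cfg$window_s * rcmv$fs)
  t_end <- rcmv$t_start + length(rcmv$samples) / rcmv$fs
  if (cfg$window_s > length(rcmv$samples) / rcmv$fs) {
    stop("window longer than record")
  }
  valid_first <- which(beats$valid)
  if (!nrow(beats) || !length(valid_first)) {
    return(list(windows = empty_window_set(L),
                counts = c(tiled = 0L, emitted = 0L, dropped = 0L)))
  }
  peak_time <- bp$t_start + (beats$peak_index - 1) / bp$fs
  t0 <- peak_time[valid_first[1]]
  starts <- seq(t0, t_end - cfg$window_s, by = cfg$window_s)
  if (!length(starts)) {
    return(list(windows = empty_window_set(L),
                counts = c(tiled = 0L, emitted = 0L, dropped = 0L)))
  }
  keep <- logical(length(starts))
  sbp_lab <- dbp_lab <- numeric(length(starts))
  for (w in seq_along(starts)) {
    inw <- peak_time >= starts[w] & peak_time < starts[w] + cfg$window_s
    if (any(inw) && all(beats$valid[inw])) {
      keep[w] <- TRUE
      sbp_lab[w] <- mean(beats$sbp[inw])
      dbp_lab[w] <- mean(beats$dbp[inw])
    }
  }
  kept <- which(keep)
  ch <- array(0, c(length(kept), 2, L))
  ok <- logical(length(kept))
  for (j in seq_along(kept)) {
    w <- kept[j]
    i0 <- round((starts[w] - rcmv$t_start) * rcmv$fs) + 1L
    seg <- rcmv$samples[i0:(i0 + L - 1L)]
    det <- detrend(bp_signal(seg, rcmv$fs))$signal
    der <- nth_derivative(det, cfg$derivative_order)
    n1 <- sqrt(sum(det$samples^2)); n2 <- sqrt(sum(der$samples^2))
    if (n1 == 0 || n2 == 0) next  # degenerate flat window
    ch[j, 1, ] <- det$samples / n1
    ch[j, 2, ] <- der$samples / n2
    ok[j] <- TRUE
  }
  kept <- kept[ok]
  scen <- rep(scenario, length(kept))
  if (!is.null(segments) && length(kept)) {
    mid <- starts[kept] + cfg$window_s / 2
    for (j in seq_along(kept)) {
      hit <- which(segments$start <= mid[j] & mid[j] < segments$end)
      if (length(hit)) scen[j] <- segments$label[hit[1]]
    }
  }
  ws <- window_set(ch[ok, , , drop = FALSE], sbp_lab[kept], dbp_lab[kept],
                   rep(subject_id, length(kept)), scen, starts[kept])
  list(windows = ws,
       counts = c(tiled = length(starts), emitted = length(kept),
                  dropped = length(starts) - length(kept)))
}

#' Rebuild the derivative channel of a window set at a different order
#'
#' The stored channels are L2-normalized, and differentiation commutes with
#' scaling, so the derivative channel at any order can be recomputed from
#' the normalized micro-vibration channel without returning to the raw
#' record. Channel 1 is left untouched.
#'
#' @param ws a `window_set`.
#' @param order derivative order 1, 2 or 3.
#' @param fs sampling rate the windows were built at (only fixes the
#'   derivative's physical scale, which renormalization removes).
#' @return the `window_set` with channel 2 replaced.
#' @export
set_derivative_channel <- function(ws, order, fs = 150) {
  stopifnot(inherits(ws, "window_set"))
  for (i in seq_len(n_windows(ws))) {
    d <- nth_derivative(bp_signal(ws$channels[i, 1, ], fs), order)
    ws$channels[i, 2, ] <- l2_normalize(d$samples)
  }
  ws
}

empty_window_set <- function(L) {
  window_set(array(0, c(0, 2, L)), numeric(), numeric(), character(),
             character(), numeric())
}

#' Preprocess and window a whole cohort
#'
#' Runs the full front end (demodulation, band-pass, resampling, guard trim,
#' beat detection, outlier flagging, peak-anchored windowing) over a list of
#' subject records and binds the results.
#'
#' @param cohort list of `subject_record`.
#' @param cfg a [prep_config()].
#' @return list with `windows` (combined `window_set`) and `counts`
#'   (per-subject matrix of tiled/emitted/dropped).
#' @export
build_windows <- function(cohort, cfg = prep_config()) {
  if (!length(cohort)) stop("empty cohort")
  parts <- vector("list", length(cohort))
  counts <- matrix(0L, length(cohort), 3,
                   dimnames = list(NULL, c("tiled", "emitted", "dropped")))
  for (k in seq_along(cohort)) {
    rec <- cohort[[k]]
    pre <- preprocess_record(rec, cfg)
    beats <- detect_beats(pre$bp)
    seg <- segment_windows(pre$rcmv, pre$bp, beats, cfg,
                           subject_id = rec$subject_id,
                           scenario = rec$scenario, segments = rec$segments)
    parts[[k]] <- seg$windows
    counts[k, ] <- seg$counts
  }
  rownames(counts) <- vapply(cohort, `[[`, character(1), "subject_id")
  list(windows = window_bind(parts), counts = counts)
}

#' Split specification
#'
#' @param fractions train/validation/test fractions summing to 1
#'   (default 0.65/0.15/0.20).
#' @param mode `"window"` for a seeded window-level shuffle (default) or
#'   `"subject"` to keep all of a subject's windows in one partition.
#' @param seed integer seed for the shuffle.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.65, 0.15, 0.20),
                       mode = c("window", "subject"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(fractions = fractions, mode = mode, seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition a window set into train/validation/test
#'
#' Seeded shuffle followed by partition at the fraction boundaries; counts
#' are within one window of the exact fractions. In subject-level mode whole
#' subjects are assigned to partitions (fractions then hold only as closely
#' as subject sizes allow).
#'
#' @param ws a `window_set` with at least 10 windows.
#' @param spec a [split_spec()].
#' @return list with `train`, `val`, `test` (`window_set`s) and
#'   `assignment` (factor of length `n_windows(ws)`).
#' @export
make_splits <- function(ws, spec = split_spec()) {
  n <- n_windows(ws)
  if (n < 10L) stop("need at least 10 windows to split")
  labels <- c("train", "val", "test")
  assignment <- character(n)
  if (spec$mode == "window") {
    ord <- with_local_seed(spec$seed, sample.int(n))
    cuts <- diff(round(cumsum(c(0, spec$fractions)) * n))
    assignment[ord] <- rep(labels, times = cuts)
  } else {
    subjects <- unique(ws$subject_id)
    ord <- with_local_seed(spec$seed, sample(subjects))
    sizes <- vapply(ord, function(s) sum(ws$subject_id == s), integer(1))
    # greedy: each subject goes to the partition with the largest deficit
    got <- c(train = 0, val = 0, test = 0)
    tgt <- spec$fractions * n
    subj_part <- character(length(ord))
    for (k in seq_along(ord)) {
      deficit <- (tgt - got) / pmax(tgt, 1)
      subj_part[k] <- labels[which.max(deficit)]
      got[subj_part[k]] <- got[subj_part[k]] + sizes[k]
    }
    assignment <- subj_part[match(ws$subject_id, ord)]
  }
  assignment <- factor(assignment, levels = labels)
  out <- lapply(labels, function(l) window_subset(ws, which(assignment == l)))
  names(out) <- labels
  c(out, list(assignment = assignment))
}
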