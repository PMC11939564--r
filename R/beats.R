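#' Detect beats in an arterial pressure waveform
#'
#' Systolic peaks are local maxima with a minimum inter-peak distance of
#' 0.33 s and topographic prominence of at least 10 mmHg (one pulse pressure
#' order of magnitude above waveform ripple); the diastolic trough is the
#' minimum between consecutive peaks. Beats whose values fall outside the
#' physiologic band [40, 180] mmHg are flagged invalid.
#'
#' @param bp a `bp_signal` of arterial pressure in mmHg, at least 1 s long.
#' @param min_distance_s minimum systolic inter-peak distance in seconds.
#' @param min_prominence minimum peak prominence in mmHg.
#' @return data.frame of class `beat_annotation` with columns `peak_index`,
#'   `sbp`, `trough_index`, `dbp`, `valid`. Zero rows when no beat is found.
#' @export
detect_beats <- function(bp, min_distance_s = 0.33, min_prominence = 10) {
  stopifnot(inherits(bp, "bp_signal"))
  v <- bp$samples
  if (length(v) < bp$fs) stop("need at least 1 s of pressure samples")
  peaks <- find_peaks(v, min_dist = round(min_distance_s * bp$fs),
                      min_prom = min_prominence)
  empty <- data.frame(peak_index = integer(), sbp = numeric(),
                      trough_index = integer(), dbp = numeric(),
                      valid = logical())
  class(empty) <- c("beat_annotation", "data.frame")
  if (!length(peaks)) return(empty)
  # trough between consecutive peaks; the final peak closes at end of record
  n_beats <- length(peaks)
  bounds <- c(peaks[-1L], length(v))
  trough_index <- integer(n_beats)
  dbp <- numeric(n_beats)
  for (b in seq_len(n_beats)) {
    span <- peaks[b]:bounds[b]
    trough_index[b] <- span[which.min(v[span])]
    dbp[b] <- v[trough_index[b]]
  }
  out <- data.frame(peak_index = peaks[seq_len(n_beats)],
                    sbp = v[peaks[seq_len(n_beats)]],
                    trough_index = trough_index, dbp = dbp,
                    valid = TRUE)
  out$valid <- out$dbp < out$sbp
  class(out) <- c("beat_annotation", "data.frame")
  flag_outliers(out)
}

# Local maxima with minimum distance and prominence. Prominence of a peak is
# its height above the higher of the two deepest valleys separating it from
# the nearest higher ground (standard topographic definition on a series).
find_peaks <- function(v, min_dist = 1L, min_prom = 0) {
  n <- length(v)
  if (n < 3L) return(integer())
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  # plateaus: diff sign 0; take strict maxima only, adequate for waveforms
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(p) {
    # walk left until a sample higher than v[p] (or the edge); the deepest
    # point on that walk is the left base, same on the right
    left <- if (p == 1L) v[p] else {
      seg <- v[1:(p - 1L)]
      higher <- which(seg > v[p])
      min(seg[(if (length(higher)) max(higher) else 1L):(p - 1L)])
    }
    right <- if (p == n) v[p] else {
      seg <- v[(p + 1L):n]
      higher <- which(seg > v[p])
      min(seg[1:(if (length(higher)) min(higher) else length(seg))])
    }
    v[p] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  promk <- prom[prom >= min_prom]
  if (!length(keep)) return(integer())
  # enforce min distance greedily, highest prominence first
  ord <- order(-promk, keep)
  sel <- logical(length(keep))
  taken <- integer()
  for (j in ord) {
    if (!length(taken) || all(abs(taken - keep[j]) >= min_dist)) {
      sel[j] <- TRUE
      taken <- c(taken, keep[j])
    }
  }
  sort(keep[sel])
}

#' Flag physiologically implausible beats as outliers
#'
#' Marks beats invalid when any pressure label exceeds 180 mmHg or drops
#' below 40 mmHg, the outlier band for recordings from healthy subjects.
#' Order is preserved; no beat is removed.
#'
#' @param beats a `beat_annotation` data.frame.
#' @return the same data.frame with `valid` updated.
#' @export
flag_outliers <- function(beats) {
  stopifnot(is.data.frame(beats))
  if (!nrow(beats)) return(beats)
  ok <- beats$sbp <= 180 & beats$sbp >= 40 & beats$dbp >= 40 & beats$dbp <= 180
  beats$valid <- beats$valid & ok & (beats$dbp < beats$sbp)
  beats
}
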