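#' Detect cycle onsets from the signal's speed and acceleration
#'
#' A standard pulse-foot detector: the systolic upstroke of each beat is
#' located as a prominent maximum of the first derivative (speed), then the
#' detector walks backward along the upstroke to the preceding local minimum
#' of the signal — the foot of the pulse, where the second derivative
#' (acceleration) peaks.  A refractory distance of `60 / hr_band[2]` seconds
#' between accepted onsets enforces the physiological heart-rate band.
#'
#' Derivatives are centred differences on the band-passed signal; the 48 Hz
#' cut of the pretreatment already limits derivative noise, so no extra
#' smoothing is applied.
#'
#' @param signal band-passed sample vector.
#' @param fs sampling rate in Hz.
#' @param hr_band plausible heart-rate range in beats per minute
#'   (default `c(40, 180)`).
#' @param min_rel_slope fraction of the largest derivative peak below which
#'   an upstroke candidate is ignored (default 0.3).
#' @return integer vector of onset sample indices (1-based), strictly
#'   increasing.  Fewer than 3 detected onsets is an error (record
#'   unusable).
#' @export
detect_onsets <- function(signal, fs, hr_band = c(40, 180), min_rel_slope = 0.3) {
  n <- length(signal)
  if (n < 5L) stop("segmentation error: signal too short")
  d <- c(signal[2L] - signal[1L],
         (signal[3:n] - signal[1:(n - 2L)]) / 2,
         signal[n] - signal[n - 1L])
  dmax <- max(d)
  if (!is.finite(dmax) || dmax <= 0)
    stop("segmentation error: no rising slope found (flat or degenerate signal)")
  refr <- max(2L, floor(fs * 60 / hr_band[2L]))
  # local maxima of the derivative above the slope threshold
  is_pk <- c(FALSE, d[2:(n - 1L)] > d[1:(n - 2L)] & d[2:(n - 1L)] >= d[3:n], FALSE)
  cand <- which(is_pk & d >= min_rel_slope * dmax)
  if (!length(cand)) stop("segmentation error: no upstroke candidates")
  # greedy refractory suppression, strongest slope first
  cand <- cand[order(d[cand], decreasing = TRUE)]
  acc <- integer(0)
  for (u in cand) {
    if (!length(acc) || all(abs(acc - u) >= refr)) acc <- c(acc, u)
  }
  ups <- sort(acc)
  # foot localization: the signal minimum in the pre-upstroke window, on a
  # lightly smoothed copy (5-point binomial) so band-limited noise does not
  # displace the minimum; the smoothing is symmetric and leaves the foot
  # location unbiased
  ker <- c(1, 4, 6, 4, 1) / 16
  xs <- stats::filter(signal, ker, sides = 2)
  xs[is.na(xs)] <- signal[is.na(xs)]
  onsets <- vapply(ups, function(u) {
    w <- max(1L, u - refr):u
    w[which.min(xs[w])]
  }, integer(1))
  onsets <- sort(unique(onsets))
  # prune spurious onsets fired by a strong dicrotic upstroke: a true beat
  # rises by the full pulse amplitude after its foot, a dicrotic rebound by
  # a small fraction of it
  if (length(onsets) >= 3L) {
    rise <- vapply(seq_along(onsets), function(i) {
      hi <- if (i < length(onsets)) onsets[i + 1L] else min(n, onsets[i] + 2L * refr)
      max(signal[onsets[i]:hi]) - signal[onsets[i]]
    }, numeric(1))
    onsets <- onsets[rise >= 0.6 * stats::quantile(rise, 0.75)]
  }
  if (length(onsets) < 3L)
    stop("segmentation error: fewer than 3 onsets detected (record unusable)")
  onsets
}

#' Segment a signal into heart cycles
#'
#' Cycles are the half-open intervals `[onset_i, onset_{i+1})`; the partial
#' cycle before the first onset and the tail after the last are discarded.
#' Cycles whose period falls outside the heart-rate band are dropped (and
#' counted) unless `permissive = TRUE`.
#'
#' @param signal sample vector the onsets refer to.
#' @param onsets onset indices from [detect_onsets()].
#' @param fs sampling rate in Hz.
#' @param hr_band heart-rate band in bpm used for the period rule.
#' @param permissive keep out-of-band cycles instead of dropping them.
#' @return an object of class `cycle_set`: list with `start` (onset index of
#'   each kept cycle), `L` (length in samples), `T_i` (periods in seconds),
#'   `T` (total covered duration), `fs`, `dropped` (number of out-of-band
#'   cycles removed) and `onsets` (all detected onsets).
#' @export
segment_cycles <- function(signal, onsets, fs, hr_band = c(40, 180),
                           permissive = FALSE) {
  onsets <- sort(unique(as.integer(onsets)))
  if (length(onsets) < 3L) stop("need at least 3 onsets to segment")
  start <- onsets[-length(onsets)]
  L <- diff(onsets)
  T_i <- L / fs
  lo <- 60 / hr_band[2L]
  hi <- 60 / hr_band[1L]
  ok <- T_i >= lo & T_i <= hi
  dropped <- sum(!ok)
  if (!permissive) {
    start <- start[ok]; L <- L[ok]; T_i <- T_i[ok]
  }
  if (!length(L)) stop("segmentation error: no cycles within the heart-rate band")
  structure(list(start = start, L = L, T_i = T_i, T = sum(T_i), fs = fs,
                 dropped = dropped, onsets = onsets),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat("<cycle_set> ", length(x$L), " cycles covering ", round(x$T, 2), " s",
      if (x$dropped) paste0(" (", x$dropped, " dropped)"), "\n", sep = "")
  cat("  period: mean ", round(mean(x$T_i), 3), " s, range [",
      round(min(x$T_i), 3), ", ", round(max(x$T_i), 3), "] s\n", sep = "")
  invisible(x)
}
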