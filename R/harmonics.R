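#' Fit one pulse cycle to a p-harmonic Fourier model
#'
#' For a cycle of length `L` samples the model is
#' \deqn{y_t = a_0 + \sum_{k=1}^{p} a_k \cos(2 k t \pi / L) +
#'       b_k \sin(2 k t \pi / L), \quad t = 0, \dots, L-1,}
#' fitted by ordinary least squares.  Every cycle is fitted separately with
#' its own length, so cycles of a quasi-periodic record with unequal periods
#' are all modelled on a common harmonic scale.
#'
#' @param y numeric samples of one cycle.
#' @param p harmonic order (default 12).
#' @return object of class `cycle_fit`: list with `a0`, `a`, `b` (length
#'   `p`), `p`, `L` and `rmse`.
#' @export
fit_cycle <- function(y, p = 12) {
  L <- length(y)
  if (L < 2 * p + 1)
    stop("cycle of ", L, " samples cannot identify ", p, " harmonics (need >= ",
         2 * p + 1, " samples)")
  t <- 0:(L - 1L)
  ang <- outer(t, 1:p) * (2 * pi / L)
  X <- cbind(1, cos(ang), sin(ang))
  fit <- stats::.lm.fit(X, y)
  cf <- fit$coefficients
  structure(list(a0 = cf[1L], a = cf[2:(p + 1L)], b = cf[(p + 2L):(2L * p + 1L)],
                 p = p, L = L, rmse = sqrt(mean(fit$residuals^2))),
            class = "cycle_fit")
}

#' Aggregate per-cycle fits with period-length weights
#'
#' Coefficients of the separate per-cycle fits are combined as
#' \deqn{a_k = \sum_i (T_i / T)\, a_{i,k}, \qquad b_k = \sum_i (T_i / T)\, b_{i,k},}
#' where \eqn{T_i} is the period of cycle i and \eqn{T = \sum_i T_i}; longer
#' cycles therefore contribute proportionally more.  Harmonic amplitudes
#' \eqn{C_k = \sqrt{a_k^2 + b_k^2}} and phases
#' \eqn{F_k = \mathrm{atan2}(b_k, a_k) \in (-\pi, \pi]} are derived.
#'
#' @param fits list of [fit_cycle()] results, all with the same order `p`.
#' @param T_i per-cycle periods (seconds), same length as `fits`.
#' @return object of class `channel_harmonics`: list with `a0`, `a`, `b`,
#'   `C`, `F`, `p` and `mean_L` (period-weighted mean cycle length, samples).
#' @export
aggregate_fits <- function(fits, T_i) {
  if (!length(fits)) stop("no cycle fits to aggregate")
  if (length(fits) != length(T_i)) stop("length(fits) != length(T_i)")
  p <- fits[[1L]]$p
  if (!all(vapply(fits, function(f) f$p, numeric(1)) == p))
    stop("cycle fits have differing harmonic order")
  w <- T_i / sum(T_i)
  A <- vapply(fits, function(f) f$a, numeric(p))
  B <- vapply(fits, function(f) f$b, numeric(p))
  a <- drop(A %*% w)
  b <- drop(B %*% w)
  a0 <- sum(w * vapply(fits, function(f) f$a0, numeric(1)))
  mean_L <- sum(w * vapply(fits, function(f) f$L, numeric(1)))
  structure(list(a0 = a0, a = a, b = b,
                 C = sqrt(a^2 + b^2), F = atan2(b, a),
                 p = p, mean_L = mean_L),
            class = "channel_harmonics")
}

#' @export
print.channel_harmonics <- function(x, ...) {
  cat("<channel_harmonics> order", x$p, "\n")
  cat("  C:", paste(signif(x$C, 4), collapse = " "), "\n")
  cat("  F:", paste(signif(x$F, 3), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct a representative cycle from aggregated coefficients
#'
#' Forward evaluation of the harmonic model at `L` sample points.
#'
#' @param ch a `channel_harmonics` (or `cycle_template`) object with fields
#'   `a0`, `a`, `b`.
#' @param L output length in samples (>= 25 so 12 harmonics are resolvable).
#' @return numeric vector of length `L`.
#' @export
reconstruct_cycle <- function(ch, L) {
  render_harmonics(ch$a0, ch$a, ch$b, L)
}

# shared forward evaluation of a0 + sum_k a_k cos + b_k sin on t = 0..L-1
render_harmonics <- function(a0, a, b, L) {
  p <- length(a)
  if (L < 2 * p + 1)
    stop("cycle length ", L, " too small to carry ", p,
         " harmonics (need >= ", 2 * p + 1, ")")
  t <- 0:(L - 1L)
  ang <- outer(t, 1:p) * (2 * pi / L)
  drop(a0 + cos(ang) %*% a + sin(ang) %*% b)
}

#' Time-domain landmarks of a reconstructed cycle
#'
#' Landmarks are read off the smooth band-limited reconstruction of the
#' aggregated cycle: the percussion (main) wave is the global maximum
#' (`h1`, `t1`); the next local maximum on the falling limb is the tidal
#' wave (`h3`); the local minimum after it is the dicrotic notch
#' (`h4`, `t4`); the following local maximum is the dicrotic wave
#' (`h5`, `t5`).  `w` is the width (s) of the region around the main peak
#' where the amplitude exceeds `2/3 * h1` — i.e. the width at one third from
#' the top.  All amplitudes are measured above the cycle-onset value.
#'
#' When the notch and dicrotic wave are absent (e.g. a nearly sinusoidal
#' cycle), the two strongest inflection points of the falling limb are used
#' in their place and the result is flagged via the `fallback` field, never
#' an error; a flat cycle with no main peak is an error.
#'
#' @param ch `channel_harmonics` object.
#' @param mean_L representative cycle length in samples (defaults to
#'   `ch$mean_L`).
#' @param fs sampling rate in Hz.
#' @param prominence minimum relative amplitude (fraction of h1) for a
#'   local extremum to count as a landmark; suppresses harmonic-truncation
#'   ripple (default 0.004).
#' @return list with `h1`, `t1`, `h3`, `h4`, `h5`, `h3h1`, `h4h1`, `h5h1`,
#'   `w`, `t4`, `t5`, `period` and logical `fallback`.
#' @export
time_features <- function(ch, mean_L = ch$mean_L, fs, prominence = 0.004) {
  L <- as.integer(round(mean_L))
  # landmarks are read off an 8x oversampled reconstruction so their
  # timing is not quantized to the acquisition grid
  up <- 8L
  y <- reconstruct_cycle(ch, up * L)
  fs <- up * fs
  base <- y[1L]
  rel <- y - base
  i1 <- which.max(rel)
  h1 <- rel[i1]
  if (!(h1 > 0) || diff(range(rel)) < .Machine$double.eps^0.5 * max(1, abs(base)))
    stop("feature error: cycle has no main peak (flat reconstruction)")
  t1 <- (i1 - 1L) / fs
  # extrema after the main peak, filtered by prominence
  n <- length(rel)
  ext <- list(idx = integer(0), type = character(0))
  if (i1 + 2L <= n) {
    d <- diff(rel)
    sgn <- sign(d)
    turns <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-length(sgn)] != 0) + 1L
    turns <- turns[turns > i1]
    if (length(turns)) {
      typ <- ifelse(sgn[turns - 1L] > 0, "max", "min")
      # keep alternating extrema whose amplitude step exceeds the prominence
      keep <- logical(length(turns))
      last_val <- rel[i1]
      for (j in seq_along(turns)) {
        if (abs(rel[turns[j]] - last_val) >= prominence * h1) {
          keep[j] <- TRUE
          last_val <- rel[turns[j]]
        }
      }
      ext <- list(idx = turns[keep], type = typ[keep])
    }
  }
  fallback <- FALSE
  i3 <- i4 <- i5 <- NA_integer_
  types <- ext$type; idxs <- ext$idx
  # the dicrotic notch is the deepest kept minimum on the falling limb that
  # still has a rebound (dicrotic wave) after it; "first min after the main
  # peak" alone would grab the shallow main-tidal dip when the tidal wave
  # rises into a true local maximum
  # The notch lies in early diastole (<= 0.7 of the cycle); late-diastolic
  # oscillations are not candidates.  Prefer the deepest minimum backed by
  # a dicrotic rebound; a subject whose rebound is too flat to survive the
  # prominence filter still gets the deepest bare minimum as notch, with a
  # degenerate dicrotic wave (t5 = t4), rather than a discontinuous jump
  # to a different landmark family.
  # dips inside the systolic complex (before the last prominent maximum of
  # the first half-cycle, i.e. the tidal wave) are not notch candidates
  sys_max <- which(types == "max" & idxs <= 0.5 * n &
                     rel[idxs] >= 0.5 * h1)
  after_sys <- if (length(sys_max)) seq_along(types) > max(sys_max) else
    rep(TRUE, length(types))
  in_window <- types == "min" & idxs <= 0.70 * n & after_sys
  with_reb <- which(in_window &
                      vapply(seq_along(types), function(j)
                        any(types == "max" & seq_along(types) > j), logical(1)))
  bare <- which(in_window)
  deepest_first <- function(cand) {
    # among minima of near-equal depth (within 2% of h1) the earliest one
    # is the notch: the dicrotic notch precedes any equally deep later dip
    v <- rel[idxs[cand]]
    cand[which(v <= min(v) + 0.02 * h1)[1L]]
  }
  j4 <- if (length(with_reb)) deepest_first(with_reb)
        else if (length(bare)) deepest_first(bare)
        else NA_integer_
  if (!is.na(j4)) {
    i4 <- idxs[j4]
    nxt <- which(types == "max" & seq_along(types) > j4)
    if (length(nxt)) {
      i5 <- idxs[nxt[1L]]
    } else {
      i5 <- i4
      fallback <- TRUE
    }
    prev_max <- which(types == "max" & seq_along(types) < j4)
    if (length(prev_max)) i3 <- idxs[prev_max[length(prev_max)]]
  }
  if (is.na(i4) || is.na(i5)) {
    # incipient notch flattened into a monotone falling limb: its location
    # survives as the curvature ridge (second-derivative maximum) of the
    # decay, the standard read-out for a hidden dicrotic notch
    fallback <- TRUE
    dd <- diff(rel, differences = 2)
    # skip the peak's own curvature: the ridge search starts well down the
    # falling limb
    lo <- min(i1 + max(2L, round(0.10 * n)), n - 1L)
    win <- seq.int(lo, max(lo + 1L, floor(0.7 * n)))
    win <- win[win >= 2L & win - 1L <= length(dd)]
    i4 <- if (length(win)) win[which.max(dd[win - 1L])] else
      min(n, i1 + as.integer(0.35 * n))
    i5 <- i4
  }
  if (is.na(i3)) {
    # tidal shoulder absent as a distinct maximum: use the inflection point
    # between main peak and notch
    if (i4 - i1 >= 3L) {
      dd <- diff(rel, differences = 2)
      seg <- seq.int(i1 + 1L, i4 - 1L)
      seg <- seg[seg <= length(dd)]
      i3 <- if (length(seg)) seg[which.max(dd[seg])] else i4
    } else i3 <- i4
  }
  h3 <- rel[i3]; h4 <- rel[i4]; h5 <- rel[i5]
  t4 <- (i4 - 1L) / fs
  t5 <- (i5 - 1L) / fs
  # width of the main wave at 2/3 h1, crossings by linear interpolation
  lev <- (2 / 3) * h1
  wl <- i1
  while (wl > 1L && rel[wl - 1L] >= lev) wl <- wl - 1L
  xl <- if (wl == 1L) 1 else
    (wl - 1) + (lev - rel[wl - 1L]) / (rel[wl] - rel[wl - 1L])
  wr <- i1
  while (wr < n && rel[wr + 1L] >= lev) wr <- wr + 1L
  xr <- if (wr == n) n else
    wr + (rel[wr] - lev) / (rel[wr] - rel[wr + 1L])
  w <- (xr - xl) / fs
  list(h1 = h1, t1 = t1, h3 = h3, h4 = h4, h5 = h5,
       h3h1 = h3 / h1, h4h1 = h4 / h1, h5h1 = h5 / h1,
       w = w, t4 = t4, t5 = t5, period = length(y) / fs,
       fallback = fallback)
}

#' Extract the 193-parameter feature vector of a recording
#'
#' Runs the full per-channel chain — band-pass pretreatment, onset
#' detection, zero alignment, cycle segmentation, separate per-cycle
#' 12-harmonic fits, period-weighted aggregation, and time-domain landmark
#' extraction — then assembles the named 193-entry vector
#' (32 parameters x 6 channels + the global mean period `t`).
#'
#' @param rec a [pulse_recording()] with all six channels present.
#' @param band filter band in Hz (default `c(0.5, 48)`).
#' @param hr_band heart-rate band in bpm.
#' @param p harmonic order (default 12).
#' @param preprocess apply [dct_bandpass()] before segmentation (default
#'   TRUE; disable only for already-filtered or noise-free input).
#' @return named numeric vector of length 193 (order of [feature_names()]),
#'   with attribute `qc`: per-channel list of cycles kept/dropped and
#'   landmark-fallback flags.
#' @export
extract_features <- function(rec, band = c(0.5, 48), hr_band = c(40, 180),
                             p = 12, preprocess = TRUE) {
  stopifnot(inherits(rec, "pulse_recording"))
  missing_ch <- setdiff(pulse_channels(), names(rec$channels))
  if (length(missing_ch))
    stop("extraction error for subject ", rec$subject_id,
         ": missing channel(s) ", paste(missing_ch, collapse = ", "))
  out <- numeric(0)
  qc <- list()
  periods <- numeric(0)
  for (chn in pulse_channels()) {
    x <- rec$channels[[chn]]
    res <- tryCatch({
      if (preprocess) x <- dct_bandpass(x, rec$fs, band[1L], band[2L])
      onsets <- detect_onsets(x, rec$fs, hr_band)
      x <- zero_align(x, onsets)
      cs <- segment_cycles(x, onsets, rec$fs, hr_band)
      fits <- lapply(seq_along(cs$start), function(i)
        fit_cycle(x[cs$start[i] + 0:(cs$L[i] - 1L)], p = p))
      ch <- aggregate_fits(fits, cs$T_i)
      tf <- time_features(ch, fs = rec$fs)
      list(ch = ch, tf = tf, cs = cs)
    }, error = function(e)
      stop("extraction error for subject ", rec$subject_id, ", channel ",
           chn, ": ", conditionMessage(e), call. = FALSE))
    ch <- res$ch; tf <- res$tf; cs <- res$cs
    v <- c(ch$C, ch$F,
           tf$h1, tf$t1, tf$h3h1, tf$h4h1, tf$h5h1, tf$w, tf$t4, tf$t5)
    names(v) <- paste0(channel_param_stems(), "_", chn)
    out <- c(out, v)
    periods <- c(periods, mean(cs$T_i))
    qc[[chn]] <- list(cycles = length(cs$L), dropped = cs$dropped,
                      fallback = tf$fallback)
  }
  out <- c(out, t = mean(periods))
  stopifnot(identical(names(out), feature_names()))
  attr(out, "qc") <- qc
  out
}
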