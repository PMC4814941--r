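#' Cycle template: one heart cycle as 12 Fourier harmonics
#'
#' A template stores the offset `a0` and the 12 cosine/sine coefficient
#' pairs of the harmonic cycle model; amplitudes `C_k` and phases `F_k` are
#' implied.  [render_cycle()] evaluates the model at an assigned cycle
#' length.
#'
#' @param a0 offset.
#' @param a,b numeric vectors of length 12 (cosine / sine coefficients).
#' @return object of class `cycle_template` (also `channel_harmonics`, so
#'   [reconstruct_cycle()] and [time_features()] apply).
#' @export
cycle_template <- function(a0, a, b) {
  if (length(a) != 12L || length(b) != 12L)
    stop("a cycle template carries exactly 12 harmonic orders")
  structure(list(a0 = a0, a = as.numeric(a), b = as.numeric(b),
                 C = sqrt(a^2 + b^2), F = atan2(b, a), p = 12L),
            class = c("cycle_template", "channel_harmonics"))
}

#' Render a cycle template at a given length
#'
#' Exact forward evaluation of the harmonic model at `t = 0, ..., L-1`; the
#' rendered segment is periodic with period `L`.
#'
#' @param template a [cycle_template()] (or any object with `a0`, `a`, `b`).
#' @param L segment length in samples; must be at least 25 so that the 12
#'   harmonic pairs plus offset remain identifiable.
#' @return numeric vector of length `L`.
#' @export
render_cycle <- function(template, L) {
  render_harmonics(template$a0, template$a, template$b, L)
}

# Canonical pulse-shape description: Gaussian bumps on the unit phase
# circle for the percussion (main), tidal and dicrotic waves.  Positions are
# phase fractions of the cycle, amplitudes are relative to the main wave.
default_shape_params <- function() {
  # the negative "foot" bump carves a sharp late-diastolic minimum so the
  # cycle onset is a well-defined landmark (real pulses decay to a foot
  # just before the systolic upstroke)
  # positions chosen so that no low-order harmonic phase of the anchored
  # template sits near the +-pi wrap boundary (phase features are reported
  # in (-pi, pi], and a population straddling the boundary would be
  # bimodal on a linear scale)
  # the deep, sharp foot also pins the cycle anchor, so phase effects on
  # one harmonic stay concentrated in that harmonic's measured phase
  # instead of leaking into the others through anchor displacement
  list(main   = list(pos = 0.17, amp = 1.00, sd = 0.062),
       tidal  = list(pos = 0.33, amp = 0.46, sd = 0.075),
       dicro  = list(pos = 0.49, amp = 0.30, sd = 0.042),
       foot   = list(pos = 0.88, amp = -0.55, sd = 0.046))
}

# Evaluate the bump-built shape at phase points x (Gaussian bumps wrapped
# onto the unit circle so the shape is periodic).
eval_shape <- function(shape, x) {
  s <- numeric(length(x))
  for (bp in shape)
    for (wrap in -1:1)
      s <- s + bp$amp * exp(-0.5 * ((x - bp$pos - wrap) / bp$sd)^2)
  s
}

# Smooth monotone local stretch: a raised-cosine displacement field,
# expressed in output phase, moves the landmark arriving at `center` by
# `delta`; the field vanishes identically at `left` and `right`, so
# neighbouring landmarks placed at the field edges stay exactly put.
# Smoothness matters: a kinked warp would inject spurious high-harmonic
# energy into the cycle spectrum.
make_warp <- function(center, delta, left, right) {
  if (!(left < center && center < right))
    stop("warp support does not bracket the target landmark")
  g <- function(x) {
    out <- numeric(length(x))
    ris <- x > left & x <= center
    out[ris] <- 0.5 * (1 - cos(pi * (x[ris] - left) / (center - left)))
    fal <- x > center & x < right
    out[fal] <- 0.5 * (1 + cos(pi * (x[fal] - center) / (right - center)))
    out
  }
  steep <- abs(delta) * pi / (2 * min(center - left, right - center))
  if (steep >= 1)
    stop("time-landmark shift too large: warp would not be monotone")
  function(x) x - delta * g(x)
}

# Project a (possibly warped) bump shape onto 12 harmonics, rotate the
# phase so the cycle foot (continuous minimum) sits at t = 0, and zero the
# onset value.
shape_to_template <- function(shape, scale = 1000, ngrid = 2048L,
                              warp = NULL) {
  x <- (0:(ngrid - 1L)) / ngrid
  s <- eval_shape(shape, if (is.null(warp)) x else warp(x))
  k <- 1:12
  a <- 2 * colMeans(s * cos(2 * pi * outer(x, k)))
  b <- 2 * colMeans(s * sin(2 * pi * outer(x, k)))
  # rotate so the reconstruction's minimum lies at phase 0 (the cycle foot)
  y <- drop(cos(2 * pi * outer(x, k)) %*% a + sin(2 * pi * outer(x, k)) %*% b)
  x0 <- x[which.min(y)]
  rot_a <- a * cos(2 * pi * k * x0) + b * sin(2 * pi * k * x0)
  rot_b <- b * cos(2 * pi * k * x0) - a * sin(2 * pi * k * x0)
  a <- rot_a * scale
  b <- rot_b * scale
  cycle_template(a0 = -sum(a), a = a, b = b)  # a0 such that y(0) = 0
}

#' Default healthy cycle template
#'
#' Harmonic amplitudes decay roughly as `1/k^2` and the phases produce a
#' single dominant systolic peak followed by a tidal shoulder, dicrotic
#' notch and dicrotic wave, so all time-domain landmarks (h1..h5) exist.
#' The amplitude scale (main-wave height about 1000 units) mimics raw ADC
#' counts.
#'
#' @param scale overall amplitude scale (arbitrary instrument units).
#' @return a [cycle_template()].
#' @export
default_cycle_template <- function(scale = 1000) {
  shape_to_template(default_shape_params(), scale = scale)
}

#' Synthetic cohort specification
#'
#' Defines the collection conditions the generator emulates: 40-second
#' six-channel records at 200 Hz, quasi-periodic cycle trains with per-cycle
#' period jitter, sinusoidal respiratory baseline wander (below the 0.5 Hz
#' filter edge, so pretreatment removes it) and additive white noise.
#' Group-dependent effects are planted in feature space on the generating
#' template (see [group_effect()]).
#'
#' @param n_healthy,n_fld,n_cirrhosis subjects per group.
#' @param fs sampling rate, Hz.
#' @param duration_s record length per channel, seconds.
#' @param mean_period_s mean heart period (default 0.8 s = 75 bpm).
#' @param jitter_sd_s SD of the i.i.d. Gaussian per-cycle period jitter,
#'   truncated to the physiological band 60/180 to 60/40 s.
#' @param wander_freq_hz,wander_amp respiratory wander frequency (must stay
#'   below 0.5 Hz) and amplitude (instrument units).
#' @param noise_sd additive white-noise SD (instrument units; default 20,
#'   about 2 percent of the ~1000-unit main wave).
#' @param subject_amp_sdlog between-subject log-SD of overall amplitude.
#' @param subject_shape_sd between-subject SD of bump positions (phase
#'   fraction) and relative bump-amplitude jitter.  The foot bump is
#'   jittered at a third of this value: it anchors the cycle, and anchor
#'   jitter is common-mode noise on every phase and time feature.
#' @param subject_harm_sdlog per-subject, per-channel log-SD of each
#'   harmonic amplitude (waveform micro-structure; default 0.08).
#' @param subject_harm_phase_sd per-subject, per-channel SD (radians) of
#'   each harmonic phase (default 0.06).
#' @param effects named list mapping group names to [group_effect()] lists
#'   applied to that group's generating template.
#' @param seed integer seed governing the whole cohort; per-subject
#'   substreams are derived deterministically from (seed, subject index).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 20, n_fld = 20, n_cirrhosis = 0,
                        fs = 200, duration_s = 40,
                        mean_period_s = 0.8, jitter_sd_s = 0.04,
                        wander_freq_hz = 0.25, wander_amp = 50,
                        noise_sd = 20,
                        subject_amp_sdlog = 0.08, subject_shape_sd = 0.006,
                        subject_harm_sdlog = 0.08,
                        subject_harm_phase_sd = 0.06,
                        effects = default_group_effects(), seed = 1L) {
  if (jitter_sd_s < 0 || noise_sd < 0 || wander_amp < 0)
    stop("noise/jitter/wander magnitudes must be non-negative")
  if (wander_freq_hz >= 0.5)
    stop("wander frequency must stay below 0.5 Hz so pretreatment removes it")
  if (mean_period_s < 60 / 180 || mean_period_s > 60 / 40)
    stop("mean period outside the physiological band [60/180, 60/40] s")
  for (g in names(effects)) validate_effects(effects[[g]])
  structure(list(n = c(healthy = n_healthy, fld = n_fld, cirrhosis = n_cirrhosis),
                 fs = fs, duration_s = duration_s,
                 mean_period_s = mean_period_s, jitter_sd_s = jitter_sd_s,
                 wander_freq_hz = wander_freq_hz, wander_amp = wander_amp,
                 noise_sd = noise_sd,
                 subject_amp_sdlog = subject_amp_sdlog,
                 subject_shape_sd = subject_shape_sd,
                 subject_harm_sdlog = subject_harm_sdlog,
                 subject_harm_phase_sd = subject_harm_phase_sd,
                 effects = effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Planted group effect on one feature
#'
#' An effect names a member of the 193-feature vocabulary and how the
#' generating template of a group is shifted on it: harmonic amplitudes
#' `C1..C12` support multiplicative (`mul`) or additive (`add`) shifts of
#' the coefficient pair; phases `F1..F12` support additive rotation
#' (radians); `t1`/`t4`/`t5` support additive shifts (seconds), realised by
#' moving the corresponding bump (main / notch region / dicrotic wave) of
#' the parametric shape before harmonic projection; `h1` supports
#' multiplicative amplitude scaling.
#'
#' @param feature feature name, e.g. `"C2_zuocun"`.
#' @param op `"mul"` or `"add"`.
#' @param value shift size (factor for `mul`; units of the feature for
#'   `add`).
#' @return a list describing the effect.
#' @export
group_effect <- function(feature, op = c("mul", "add"), value) {
  op <- match.arg(op)
  eff <- list(feature = feature, op = op, value = value)
  validate_effects(list(eff))
  eff
}

validate_effects <- function(effs) {
  for (e in effs) {
    if (!e$feature %in% feature_names())
      stop("effect feature '", e$feature, "' is not in the 193-name vocabulary")
    stem <- sub("_[a-z]+$", "", e$feature)
    ok <- grepl("^C[0-9]+$|^F[0-9]+$", stem) || stem %in% c("t1", "t4", "t5", "h1")
    if (!ok)
      stop("effects on '", stem, "' are not supported (use C*, F*, t1, t4, t5, h1)")
  }
  invisible(effs)
}

#' Default planted group effects
#'
#' The fatty-liver-like group shifts the canonical sparse-model feature set
#' C2_zuocun, t4_zuochi, F2_youchi; the cirrhosis-like group shifts
#' C2_youguan and F1_youchi.  Effect sizes are large (several
#' between-subject SDs) so that selection-recovery experiments have a known
#' strong target; they are not claims about real disease.
#'
#' @return named list of effect lists per group.
#' @export
default_group_effects <- function() {
  list(
    fld = list(group_effect("C2_zuocun", "mul", 1.6),
               group_effect("t4_zuochi", "add", -0.05),
               group_effect("F2_youchi", "add", 0.55)),
    cirrhosis = list(group_effect("C2_youguan", "mul", 0.6),
                     group_effect("F1_youchi", "add", 0.4))
  )
}

# deterministic sub-seed for subject `idx` of a cohort (kept below 2^31)
subject_seed <- function(seed, idx) {
  (as.numeric(seed) * 7919 + idx * 104729) %% 2147483647
}

# per-channel deterministic base variation so the six channels differ
channel_amp_factor <- function() {
  c(zuocun = 1.00, zuoguan = 0.95, zuochi = 0.88,
    youcun = 0.97, youguan = 0.92, youchi = 0.85)
}

# Build the generating template for one subject x channel: perturb the
# canonical bump shape, project to harmonics, then apply the group's
# planted effects for this channel.
build_subject_template <- function(spec, group, channel, amp_scale, shape_jit) {
  shape <- default_shape_params()
  effs <- spec$effects[[group]]
  period <- spec$mean_period_s
  # between-subject shape variation
  for (nm in names(shape)) {
    shape[[nm]]$pos <- shape[[nm]]$pos + shape_jit$pos[[nm]]
    shape[[nm]]$amp <- shape[[nm]]$amp * shape_jit$amp[[nm]]
    shape[[nm]]$sd <- shape[[nm]]$sd * shape_jit$width[[nm]]
  }
  # time-landmark effects: a smooth monotone phase warp moves the targeted
  # landmark while pinning the others, so amplitude features are untouched
  warp <- NULL
  for (e in effs) {
    stem <- sub("_[a-z]+$", "", e$feature)
    chn <- sub("^.*_", "", e$feature)
    if (chn != channel || !stem %in% c("t1", "t4", "t5")) next
    if (e$op != "add") stop("time-landmark effects must be additive (seconds)")
    dph <- e$value / period
    # notch phase: minimum of the shape between the tidal and dicrotic
    # bumps, kept clear of both bump peaks so the stretch stays monotone
    x1 <- shape$main$pos; x5 <- shape$dicro$pos
    grid <- seq(shape$tidal$pos, shape$dicro$pos, length.out = 200L)
    x4 <- grid[which.min(eval_shape(shape, grid))]
    x4 <- min(max(x4, shape$tidal$pos + 0.02), x5 - 0.05)
    w <- switch(stem,
      # field edges sit on the neighbouring landmarks so they are pinned
      t1 = make_warp(x1 + dph, dph, x1 + dph - 0.15, x4),
      t4 = make_warp(x4 + dph, dph, x4 + dph - 0.18, x5),
      t5 = make_warp(x5 + dph, dph, x4, x5 + dph + 0.18))
    warp <- if (is.null(warp)) w else local({ prev <- warp; function(x) prev(w(x)) })
  }
  tpl <- shape_to_template(shape, scale = 1000 * amp_scale *
                             channel_amp_factor()[[channel]], warp = warp)
  # harmonic-domain effects on the pair: C_k scaling is applied directly;
  # F_k rotation renormalizes the overall pulse height afterwards so it is
  # a pure redistribution of wave timing
  h1_renorm <- function(a, b, h1_target) {
    y <- render_harmonics(-sum(a), a, b, 400L)
    fac <- h1_target / (max(y) - min(y))
    list(a = a * fac, b = b * fac)
  }
  a <- tpl$a; b <- tpl$b
  for (e in effs) {
    stem <- sub("_[a-z]+$", "", e$feature)
    chn <- sub("^.*_", "", e$feature)
    if (chn != channel) next
    if (grepl("^C[0-9]+$", stem)) {
      k <- as.integer(sub("^C", "", stem))
      Ck <- sqrt(a[k]^2 + b[k]^2)
      fac <- if (e$op == "mul") e$value else (Ck + e$value) / Ck
      a[k] <- a[k] * fac; b[k] <- b[k] * fac
    } else if (grepl("^F[0-9]+$", stem)) {
      k <- as.integer(sub("^F", "", stem))
      dph <- if (e$op == "add") e$value else stop("phase effects must be additive")
      y0 <- render_harmonics(-sum(a), a, b, 400L)
      h1_pre <- max(y0) - min(y0)
      ca <- cos(dph); sa <- sin(dph)
      ak <- a[k]; bk <- b[k]
      # F_k = atan2(b, a); rotate the pair by dph
      a[k] <- ak * ca - bk * sa
      b[k] <- bk * ca + ak * sa
      rn <- h1_renorm(a, b, h1_pre)
      a <- rn$a; b <- rn$b
    } else if (stem == "h1") {
      fac <- if (e$op == "mul") e$value else stop("h1 effects must be multiplicative")
      a <- a * fac; b <- b * fac
    }
  }
  cycle_template(a0 = -sum(a), a = a, b = b)
}

#' Generate one synthetic pulse recording with ground truth
#'
#' Renders a train of jittered cycles from the subject's group-shifted
#' generating template (shared cycle onsets across the six channels, as one
#' heart drives them all), adds sinusoidal respiratory baseline wander and
#' white noise.
#'
#' @param spec a [cohort_spec()].
#' @param group group label.
#' @param subject_id subject identifier.
#' @param idx subject index used to derive the deterministic per-subject
#'   RNG substream from `spec$seed`.
#' @return list with `recording` (a [pulse_recording()]) and `truth`: true
#'   onset indices (1-based), per-cycle lengths `L_i` (samples), periods
#'   `T_i` (s), and the generating `templates` per channel.
#' @export
generate_recording <- function(spec, group = "healthy", subject_id = "S001",
                               idx = 1L) {
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed(spec$seed, idx))
  fs <- spec$fs
  n <- as.integer(round(fs * spec$duration_s))
  # per-cycle periods: truncated Gaussian jitter in the physiological band
  lo <- 60 / 180; hi <- 60 / 40
  n_cycles <- ceiling(spec$duration_s / max(spec$mean_period_s - 4 * spec$jitter_sd_s, lo)) + 2L
  T_i <- stats::rnorm(n_cycles, spec$mean_period_s, spec$jitter_sd_s)
  T_i <- pmin(pmax(T_i, lo), hi)
  L_i <- pmax(25L, as.integer(round(T_i * fs)))
  onsets <- cumsum(c(1L, L_i))
  keep <- which(onsets[-length(onsets)] <= n)
  L_i <- L_i[keep]
  onsets <- onsets[seq_len(length(keep) + 1L)]
  # subject-level amplitude, shared across channels
  amp_scale <- stats::rlnorm(1, 0, spec$subject_amp_sdlog)
  bump_names <- names(default_shape_params())
  # relative position variability differs by wave: the systolic upstroke and
  # foot are tightly timed by the ejection, while the dicrotic complex
  # drifts most between subjects
  pos_scale <- c(main = 0.4, tidal = 0.8, dicro = 0.8, foot = 0.33)
  pos_sd <- spec$subject_shape_sd * pos_scale[bump_names]
  # bump-width variation moves the spectral decay (high-harmonic content);
  # the sharp main wave and foot carry most of that energy and vary most,
  # while tidal/dicrotic widths (which set the notch position) stay steadier
  width_sd <- 0.2 * c(main = 1.2, tidal = 0.3, dicro = 0.3,
                      foot = 1.2)[bump_names]
  # gross waveform morphology (wave timing, relative amplitudes, sharpness)
  # is a subject-level trait shared by the six channels — one heart and one
  # arterial tree drive them all; per-channel micro-structure is added
  # separately below
  shape_jit <- list(
    pos = as.list(setNames(stats::rnorm(length(bump_names), 0, pos_sd),
                           bump_names)),
    amp = as.list(setNames(stats::rlnorm(length(bump_names), 0,
                                         5 * spec$subject_shape_sd),
                           bump_names)),
    width = as.list(setNames(stats::rlnorm(length(bump_names), 0, width_sd),
                             bump_names)))
  channels <- list()
  templates <- list()
  tvec <- seq_len(n) - 1L
  for (chn in pulse_channels()) {
    tpl <- build_subject_template(spec, group, chn, amp_scale, shape_jit)
    # per-channel waveform micro-structure: independent log-normal jitter
    # on each harmonic amplitude and Gaussian jitter on each phase
    if (spec$subject_harm_sdlog > 0 || spec$subject_harm_phase_sd > 0) {
      fac <- stats::rlnorm(12, 0, spec$subject_harm_sdlog)
      dph <- stats::rnorm(12, 0, spec$subject_harm_phase_sd)
      a <- fac * (tpl$a * cos(dph) - tpl$b * sin(dph))
      b <- fac * (tpl$b * cos(dph) + tpl$a * sin(dph))
      tpl <- cycle_template(a0 = -sum(a), a = a, b = b)
    }
    templates[[chn]] <- tpl
    x <- numeric(n)
    for (i in seq_along(L_i)) {
      seg <- render_cycle(tpl, L_i[i])
      s0 <- onsets[i]
      s1 <- min(n, s0 + L_i[i] - 1L)
      x[s0:s1] <- seg[seq_len(s1 - s0 + 1L)]
    }
    # pad the tail after the last complete cycle by continuing the template
    last_end <- onsets[length(L_i) + 1L]
    if (last_end <= n) {
      Lpad <- L_i[length(L_i)]
      seg <- render_cycle(tpl, Lpad)
      idxs <- last_end:n
      x[idxs] <- seg[((idxs - last_end) %% Lpad) + 1L]
    }
    if (spec$wander_amp > 0)
      x <- x + spec$wander_amp *
        sin(2 * pi * spec$wander_freq_hz * tvec / fs + stats::runif(1, 0, 2 * pi))
    if (spec$noise_sd > 0)
      x <- x + stats::rnorm(n, 0, spec$noise_sd)
    channels[[chn]] <- x
  }
  rec <- pulse_recording(channels, fs = fs, subject_id = subject_id, group = group)
  list(recording = rec,
       truth = list(onsets = onsets[seq_len(length(L_i) + 1L)],
                    L_i = L_i, T_i = L_i / fs, templates = templates))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with `manifest` (a `cohort_manifest` whose `file` column is
#'   empty — recordings live in memory), `recordings` (named list of
#'   [pulse_recording()]), and `truth` (named list of ground-truth lists).
#' @seealso [simulate_cohort()] to write a cohort to disk.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list(); recordings <- list(); truth <- list()
  idx <- 0L
  prefix <- c(healthy = "H", fld = "F", cirrhosis = "C")
  for (g in names(spec$n)) {
    ng <- spec$n[[g]]
    if (ng <= 0) next
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", prefix[[g]], i)
      gen <- generate_recording(spec, group = g, subject_id = sid, idx = idx)
      rows[[idx]] <- data.frame(subject_id = sid, group = g, file = "",
                                stringsAsFactors = FALSE)
      recordings[[sid]] <- gen$recording
      truth[[sid]] <- gen$truth
    }
  }
  manifest <- as_manifest(do.call(rbind, rows))
  list(manifest = manifest, recordings = recordings, truth = truth)
}
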