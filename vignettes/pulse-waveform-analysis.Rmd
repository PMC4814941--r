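---
title: "Harmonic analysis and classification of radial pulse waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic analysis and classification of radial pulse waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pulsewave)
```

## The problem

Pulse diagnosis instruments record the radial-artery pressure waveform
(sphygmogram) at three palpation positions per wrist — cun, guan and chi on
the left (zuo) and right (you) side — giving six channels of a few tens of
seconds each. The analysis task is to turn those quasi-periodic recordings
into a fixed-length parameter vector per subject and to ask whether two
groups of subjects (for instance healthy volunteers versus a patient group)
can be distinguished from those parameters, and by which of them.

`pulsewave` implements that pipeline end to end:

1. **Pretreatment** — each channel is band-limited to 0.5–48 Hz by masking
   coefficients of an orthonormal DCT-II and inverting, which removes both
   respiratory baseline wander (below 0.5 Hz) and high-frequency noise, and
   the record is re-anchored to zero at every cycle onset.
2. **Cycle segmentation** — heart-cycle onsets are detected from the
   signal's speed (first derivative) and acceleration (second derivative):
   the systolic upstroke is a prominent derivative maximum, and the foot of
   the pulse is the signal minimum just before it.
3. **Harmonic modelling** — each cycle of length $L$ is fitted separately by
   least squares to
   $$y_t = a_0 + \sum_{k=1}^{12} a_k \cos\frac{2 k t \pi}{L} +
     b_k \sin\frac{2 k t \pi}{L},$$
   so cycles of different lengths share one harmonic scale. Per-cycle
   coefficients are aggregated with period weights,
   $a_k = \sum_i (T_i/T)\, a_{i,k}$ (and likewise $b_k$), where $T_i$ is the
   period of cycle $i$ and $T = \sum_i T_i$.
4. **Feature extraction** — per channel, the harmonic amplitudes
   $C_k = \sqrt{a_k^2+b_k^2}$ and phases $F_k = \operatorname{atan2}(b_k,a_k)$
   for $k = 1..12$, plus eight time-domain landmarks read off the
   reconstructed mean cycle (h1, t1, h3/h1, h4/h1, h5/h1, w, t4, t5), give
   32 parameters; six channels plus the global mean period t make
   $32 \times 6 + 1 = 193$ named parameters per subject.
5. **Classification and feature mining** — three two-group methods:
   principal-component score thresholding (unsupervised), least squares on a
   designed regressand with greedy forward–backward regressor selection
   (EFBLS), and the LASSO with cross-validated penalty, plus permutation
   p-values and a repeated-round selection-frequency report.

## The designed regressand

For groups of sizes $n_1$ and $n_2$ the regression target is
$Y = (n_2, \dots, n_2, -n_1, \dots, -n_1)^\top$, which sums to zero. With
centred regressors, ordinary least squares on this target is equivalent to
the canonical-correlation-optimal linear discriminant for two groups, so
the fitted index $\hat Y$ can be thresholded at 0 to classify. Subjects
with $\hat Y$ above the threshold are assigned to group 1; if that
orientation gets less than half the training subjects right, it is flipped
and the flip recorded.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `band` | 0.5–48 Hz | pretreatment pass band |
| `hr_band` | 40–180 bpm | plausible heart-rate range (segmentation + cycle-period rule) |
| `p` | 12 | harmonic order of the cycle model |
| `k_max` | 7 | forward–backward regressor cap |
| `R` | 20 | repeated selection/validation rounds |
| `holdout` | 0.25 | held-out fraction per round |
| `folds` | 10 | LASSO cross-validation folds |
| `w` level | 2/3 · h1 | height at which the main-wave width is measured |

The regressor cap of 7 guards against overfitting in the small-$n$,
large-$p$ regime; `efbls_kmax_guard()` checks it by requiring that
permuted-label (null) data cannot reach held-out accuracy above 0.65 —
if it can, the cap is reduced.

## Numerical choices

* **DCT dialect.** `dct2()`/`idct2()` are the orthonormal DCT-II/III
  computed via a length-2N FFT; coefficient $k$ maps to frequency
  $k f_s / (2N)$, band edges are inclusive, and the DC term is removed
  whenever the lower edge is positive. The mask is hard by default; a
  raised-cosine edge is available via `taper` because hard masks can ring
  at the record edges.
* **Drift projection.** A finite record of a sub-band sinusoid that is not
  itself a DCT basis function leaks a few percent of its energy into the
  lowest pass-band coefficients (for a worst-phase 0.2 Hz sinusoid over
  40 s, about 3.6% RMS). `dct_bandpass()` therefore regresses out the
  drift space — Fourier sinusoids with periods of $1/\mathrm{lo}$ or
  longer over the record — before masking. The regression coefficients are
  identified from the stop-band part of the signal only, which makes the
  combined operation linear and exactly idempotent and leaves pass-band
  tones untouched to within 0.01%.
* **Onset localization.** After the upstroke is found, the foot is the
  minimum of a 5-point binomially smoothed copy of the signal within the
  pre-upstroke window; the smoothing is symmetric, so the location is
  unbiased while band-limited noise cannot displace it. Onsets whose
  following rise is below 60% of the upper-quartile rise are discarded —
  they are double-fires on strong dicrotic upstrokes, not beats.
* **Landmark labelling.** Landmarks are read off an 8× oversampled
  reconstruction so their timing is not quantized to the acquisition grid.
  The dicrotic notch is the deepest local minimum after the systolic
  complex and before 0.7 of the cycle that still has a rebound after it;
  among near-equally deep minima (within 2% of h1) the earliest wins. If
  the notch has flattened into a monotone falling limb, its location is
  taken from the curvature ridge (second-derivative maximum) and the
  subject is flagged (`fallback`), never an error.
* **LASSO.** The objective is
  $\tfrac12\lVert Y - Z\beta\rVert^2 + \lambda \lVert\beta\rVert_1$,
  minimized by cyclic coordinate descent with soft thresholding
  (convergence when the largest coefficient change in a sweep is below
  1e-8); under this convention $\beta = 0$ is optimal exactly at
  $\lambda \ge \max_j |Z_j^\top Y|$. The cross-validation grid is
  log-spaced over two decades below that bound — with more features than
  rows, deeper penalties give saturated, non-unique fits, so the path also
  freezes once the active set reaches 75% of the training rows, the usual
  path-algorithm convention. The penalty is chosen by the one-standard-error
  rule.
* **Phases** are reported in radians in $(-\pi, \pi]$. Phase features of a
  population whose true phase sits near $\pm\pi$ are bimodal on a linear
  scale; the synthetic template is designed so its low-order phases stay
  clear of the boundary, but real data offer no such guarantee — treat
  high-order phase features with care.

## What the synthetic cohort emulates

`cohort_spec()`/`generate_cohort()` produce six-channel, 40 s, 200 Hz
recordings per subject: a train of cycles rendered from a 12-harmonic
template (harmonic amplitudes decaying roughly as $1/k^2$, with percussion
wave, tidal shoulder, dicrotic notch and dicrotic wave, and a sharp
late-diastolic foot), with

* i.i.d. Gaussian per-cycle period jitter (SD 0.04 s) truncated to the
  40–180 bpm band, one period sequence per subject shared by all channels;
* sinusoidal respiratory wander at 0.25 Hz (amplitude 5% of the pulse) and
  white noise at 2% of the pulse amplitude;
* between-subject variability at three scales: a common amplitude factor,
  subject-level wave geometry (bump positions and widths; the sharp main
  wave and foot carry most of the high-harmonic energy and vary most, while
  the anchor and the notch-defining widths are steadier), and per-channel
  harmonic micro-structure (independent log-normal amplitude and Gaussian
  phase jitter per harmonic);
* group effects planted on named features of the generating template:
  harmonic amplitudes are scaled, phases rotated (with the overall pulse
  height renormalized so the effect is a pure timing change), and
  time-domain landmarks moved by a smooth monotone local stretch of the
  phase axis that pins the neighbouring landmarks.

Ground truth (cycle onsets, per-cycle lengths, generating templates) is
returned with every recording, which is what makes segmentation accuracy
and coefficient recovery measurable.

The generator does **not** emulate hemodynamics (no Windkessel or
transmission-line physics), motion artifacts, sensor drift or arrhythmia,
and its planted effects are statistical handles, not claims about fatty
liver disease or cirrhosis. A passing recovery experiment therefore shows
that the pipeline can find known structure of this kind at these
signal-to-noise ratios — not that real patient groups separate.

### Planted effects and their side effects

A waveform-level change never expresses itself in exactly one extracted
feature: rotating one harmonic moves the cycle's anchor slightly and so
leaks into the other phases; moving the notch changes the spectrum.
The default effect sizes are deliberately large (several between-subject
standard deviations on the named feature) and the default variability is
structured so that the named features are the strongest single
discriminators of their respective effects. Recovery experiments use 100
subjects per group — comparable to the study scale this package is aimed
at — because greedy forward selection among 193 features needs the chance
correlation ceiling ($\approx\sqrt{2\log p / n}$) to sit well below the
conditional signal of every planted feature; at a few dozen subjects per
group that is not the case for any effect size, and selection frequencies
become unstable even though held-out accuracy stays high.

### Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_healthy = 30, n_fld = 30, seed = 1)
cohort <- generate_cohort(spec)
features <- extract_cohort_features(cohort)
cls <- classify_cohort(features, groups = c("healthy", "fld"), R = 20)
cls
```

The printed report gives, per method, the full-data accuracy, the mean
held-out accuracy over the repeated rounds, the permutation p-value of the
predicted-index separation, and the sparse-model equation for the
regression methods; `cls$methods$lasso$report` holds the per-feature
`used_times`/importance table.

## Known limitations

* The forward–backward selector is a greedy stand-in for an unpublished
  procedure; only its documented behaviour (forward RSS steps, backward
  tolerance passes, cap at 7) is guaranteed.
* Landmark labelling is heuristic; waveforms far from the template family
  (severe arrhythmia, missing dicrotic structure everywhere) will lean on
  the flagged fallbacks.
* Phase features wrap at $\pm\pi$ (see above).
* Tables of raw feature means/SDs in the selection report are computed over
  all subjects of the comparison, not per group.
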