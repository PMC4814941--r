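test_that("onsets of a clean identical-cycle train are recovered exactly", {
  spec <- clean_spec(jitter_sd_s = 0)
  g <- generate_recording(spec, "healthy", "S1", 1)
  x <- g$recording$channels$zuocun
  onsets <- detect_onsets(x, spec$fs)
  truth <- g$truth$onsets
  truth <- truth[-length(truth)]
  err <- vapply(onsets, function(o) min(abs(truth - o)), numeric(1))
  expect_gte(length(onsets), length(truth) - 1L)
  expect_lte(max(err), 1)
})

test_that("flat or degenerate signals are a segmentation error", {
  expect_error(detect_onsets(rep(0, 1000), 200), "segmentation error")
  expect_error(detect_onsets(seq(1, 0, length.out = 1000), 200),
               "segmentation error")
})

test_that("cycles are half-open intervals with the period-band rule", {
  onsets <- seq(1L, by = 160L, length.out = 10L)
  cs <- segment_cycles(rnorm(2000), onsets, fs = 200)
  expect_length(cs$L, 9)                       # 10 onsets -> 9 cycles
  expect_true(all(cs$T_i == 0.8))
  expect_equal(cs$T, sum(cs$T_i))

  # a spurious onset creating a 0.1 s pseudo-cycle is dropped
  bad <- sort(c(onsets, 181L))
  cs2 <- segment_cycles(rnorm(2000), bad, fs = 200)
  expect_equal(cs2$dropped, 1L)
  expect_length(cs2$L, 9)
  expect_true(all(cs2$T_i >= 60 / 180 & cs2$T_i <= 60 / 40))
})

test_that("cycle intervals tile the span between first and last onset", {
  set.seed(4)
  g <- generate_recording(cohort_spec(seed = 10), "healthy", "S1", 1)
  x <- dct_bandpass(g$recording$channels$youguan, 200)
  on <- detect_onsets(x, 200)
  cs <- segment_cycles(x, on, 200, permissive = TRUE)
  expect_equal(cs$start + cs$L, cs$onsets[-1L])
  expect_equal(sum(cs$L), diff(range(cs$onsets)))
})

test_that("shifting the signal shifts all onsets equally", {
  g <- generate_recording(cohort_spec(seed = 6), "healthy", "S1", 1)
  x <- dct_bandpass(g$recording$channels$zuocun, 200)
  on1 <- detect_onsets(x, 200)
  s <- 37L
  on2 <- detect_onsets(x[-seq_len(s)], 200)
  common <- intersect(on1 - s, on2)
  expect_gt(length(common) / length(on2), 0.9)
})

test_that("onsets stay within 3 samples of truth under jitter and noise", {
  # 5% period jitter, noise at 2% of the main-wave amplitude
  spec <- cohort_spec(jitter_sd_s = 0.04, noise_sd = 20, seed = 13)
  hits <- 0L; total <- 0L
  for (i in 1:3) {
    g <- generate_recording(spec, "healthy", paste0("S", i), i)
    for (chn in c("zuocun", "youchi")) {
      x <- dct_bandpass(g$recording$channels[[chn]], spec$fs)
      on <- detect_onsets(x, spec$fs)
      truth <- g$truth$onsets
      truth <- truth[-length(truth)]
      err <- vapply(truth, function(o) min(abs(on - o)), numeric(1))
      hits <- hits + sum(err <= 3); total <- total + length(err)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("detected periods match ground-truth periods within 2 samples", {
  spec <- cohort_spec(seed = 21)
  g <- generate_recording(spec, "healthy", "S1", 1)
  x <- dct_bandpass(g$recording$channels$zuoguan, spec$fs)
  on <- detect_onsets(x, spec$fs)
  cs <- segment_cycles(x, on, spec$fs)
  truth_on <- g$truth$onsets
  # align detected cycles to true cycles by onset proximity
  match_idx <- vapply(cs$start, function(s) which.min(abs(truth_on - s)),
                      integer(1))
  ok <- abs(truth_on[match_idx] - cs$start) <= 3
  true_L <- g$truth$L_i
  valid <- ok & match_idx <= length(true_L)
  expect_gt(mean(valid), 0.9)
  expect_lte(mean(abs(cs$L[valid] - true_L[match_idx[valid]])), 2)
})
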