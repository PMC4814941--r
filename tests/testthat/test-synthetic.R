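test_that("render_cycle evaluates the harmonic model exactly", {
  a <- numeric(12); b <- numeric(12); a[1] <- 1
  wave <- render_cycle(cycle_template(0, a, b), 100)
  expect_equal(wave, cos(2 * pi * (0:99) / 100), tolerance = 1e-12)

  const <- render_cycle(cycle_template(5, numeric(12), numeric(12)), 50)
  expect_equal(const, rep(5, 50))

  # discrete Fourier analysis of the rendered segment recovers C2 = 5
  a <- numeric(12); b <- numeric(12); a[2] <- 3; b[2] <- 4
  seg <- render_cycle(cycle_template(0, a, b), 200)
  sp <- fft(seg)
  expect_equal(2 * Mod(sp[3]) / 200, 5, tolerance = 1e-10)

  expect_error(render_cycle(cycle_template(0, a, b), 24), "too small")
})

test_that("the default template has a physiological landmark structure", {
  tpl <- default_cycle_template()
  expect_length(tpl$C, 12)
  y <- render_cycle(tpl, 160)
  expect_equal(y[1], 0, tolerance = 1e-9)       # foot at zero
  expect_equal(which.min(y), 1L)                # foot is the minimum
  tf <- time_features(tpl, 160, fs = 200)
  expect_false(tf$fallback)
  expect_gt(tf$h1, 0)
  expect_true(tf$t1 < tf$t4 && tf$t4 < tf$t5)
})

test_that("the generator is deterministic and honours degenerate settings", {
  spec <- cohort_spec(seed = 99)
  g1 <- generate_recording(spec, "fld", "S1", 1)
  g2 <- generate_recording(spec, "fld", "S1", 1)
  expect_identical(g1$recording$channels, g2$recording$channels)

  nj <- clean_spec(jitter_sd_s = 0)
  g3 <- generate_recording(nj, "healthy", "S2", 2)
  expect_true(all(g3$truth$T_i == nj$mean_period_s))

  # zero noise and wander: the record is exactly the rendered cycle train
  g4 <- generate_recording(clean_spec(seed = 5), "healthy", "S3", 3)
  x <- g4$recording$channels$zuoguan
  tr <- g4$truth
  rebuilt <- numeric(length(x))
  for (i in seq_along(tr$L_i)) {
    seg <- render_cycle(tr$templates$zuoguan, tr$L_i[i])
    idx <- tr$onsets[i] + 0:(tr$L_i[i] - 1L)
    keep <- idx <= length(x)
    rebuilt[idx[keep]] <- seg[keep]
  }
  span <- seq_len(tr$onsets[length(tr$onsets)] - 1L)
  expect_equal(x[span], rebuilt[span], tolerance = 1e-12)
})

test_that("cohort specs validate physiological constraints", {
  expect_error(cohort_spec(wander_freq_hz = 0.6), "below 0.5 Hz")
  expect_error(cohort_spec(mean_period_s = 2), "physiological band")
  expect_error(group_effect("C2_nowhere", "mul", 2), "vocabulary")
  expect_error(group_effect("h3h1_zuocun", "mul", 2), "not supported")
})

test_that("cohort generation produces the requested group structure", {
  spec <- null_spec(n = 3, seed = 2)
  coh <- generate_cohort(spec)
  expect_equal(unname(attr(coh$manifest, "counts")), c(3, 3, 0))
  expect_length(coh$recordings, 6)
  expect_identical(names(coh$truth), coh$manifest$subject_id)
})

test_that("planted template effects surface in the extracted features", {
  spec <- cohort_spec(
    n_healthy = 6, n_fld = 6, seed = 27,
    effects = list(fld = list(group_effect("C2_zuocun", "mul", 1.5))))
  feats <- extract_cohort_features(generate_cohort(spec))
  X <- feature_matrix(feats)
  grp <- feats$group
  ratio <- mean(X[grp == "fld", "C2_zuocun"]) /
    mean(X[grp == "healthy", "C2_zuocun"])
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.8)
})

test_that("null cohorts show no systematic feature separation", {
  spec <- null_spec(n = 10, seed = 77)
  feats <- extract_cohort_features(generate_cohort(spec))
  X <- feature_matrix(feats)
  grp <- feats$group
  smd <- apply(X, 2L, function(v) {
    s <- sd(v)
    if (s == 0) 0 else abs(mean(v[grp == "fld"]) - mean(v[grp == "healthy"])) / s
  })
  # under the null the standardized differences concentrate near zero
  expect_lt(mean(smd > 4 / sqrt(length(grp))), 0.10)
  expect_lt(max(smd), 2)
})
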