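test_that("noiseless cycles are fitted exactly by least squares", {
  a <- numeric(12); b <- numeric(12)
  a[2] <- 3; b[2] <- 4
  tpl <- cycle_template(a0 = 1.5, a = a, b = b)
  y <- render_cycle(tpl, 200)
  fit <- fit_cycle(y)
  expect_lt(max(abs(fit$a - a)), 1e-8)
  expect_lt(max(abs(fit$b - b)), 1e-8)
  expect_lt(fit$rmse, 1e-8)

  const <- fit_cycle(rep(4.2, 100))
  expect_equal(const$a0, 4.2, tolerance = 1e-10)
  expect_lt(max(abs(c(const$a, const$b))), 1e-10)

  expect_error(fit_cycle(rnorm(20)), "identifiability|cannot identify")
})

test_that("coefficient noise matches the closed-form least-squares variance", {
  # independent oracle: for orthogonal trigonometric regressors the
  # coefficient standard error is sigma * sqrt(2 / L)
  set.seed(42)
  a <- numeric(12); b <- numeric(12); a[1] <- 50; b[3] <- 20
  tpl <- cycle_template(0, a, b)
  L <- 200; sigma <- 2
  base <- render_cycle(tpl, L)
  est <- replicate(400, fit_cycle(base + rnorm(L, 0, sigma))$a[1])
  expect_equal(sd(est), sigma * sqrt(2 / L), tolerance = 0.15)
})

test_that("aggregation is the period-weighted mean of per-cycle coefficients", {
  a <- numeric(12); b <- numeric(12); a[1] <- 1
  f1 <- fit_cycle(render_cycle(cycle_template(0, a, b), 160))
  a[1] <- 3
  f2 <- fit_cycle(render_cycle(cycle_template(0, a, b), 160))
  agg <- aggregate_fits(list(f1, f2), T_i = c(1, 3))
  expect_equal(agg$a[1], (1 * 1 + 3 * 3) / 4, tolerance = 1e-8)

  # identical cycles: the aggregate equals the common value
  agg2 <- aggregate_fits(list(f1, f1, f1), T_i = c(0.7, 0.9, 0.8))
  expect_equal(agg2$a, f1$a, tolerance = 1e-12)

  # amplitude/phase from the coefficient pair
  a <- numeric(12); b <- numeric(12); a[5] <- 3; b[5] <- 4
  f <- fit_cycle(render_cycle(cycle_template(0, a, b), 200))
  agg3 <- aggregate_fits(list(f), T_i = 1)
  expect_equal(agg3$C[5], 5, tolerance = 1e-8)
  expect_equal(agg3$F[5], atan2(4, 3), tolerance = 1e-8)

  expect_error(aggregate_fits(list(), numeric(0)), "no cycle fits")
})

test_that("jittered noiseless trains recover the template to 1e-6 relative", {
  # period jitter on, everything else clean
  spec <- clean_spec(jitter_sd_s = 0.04, seed = 31)
  g <- generate_recording(spec, "healthy", "S1", 1)
  tpl <- g$truth$templates$zuocun
  x <- g$recording$channels$zuocun
  on <- g$truth$onsets
  L_i <- g$truth$L_i
  full <- which(on[seq_along(L_i)] + L_i - 1L <= length(x))
  fits <- lapply(full, function(i) fit_cycle(x[on[i] + 0:(L_i[i] - 1L)]))
  agg <- aggregate_fits(fits, g$truth$T_i[full])
  expect_lt(max(abs(agg$a - tpl$a) / pmax(abs(tpl$a), 1e-6)), 1e-6)
  expect_lt(max(abs(agg$b - tpl$b) / pmax(abs(tpl$b), 1e-6)), 1e-6)
})

test_that("reconstruction inverts fitting and zero coefficients give a flat line", {
  tpl <- default_cycle_template()
  y <- render_cycle(tpl, 160)
  fit <- fit_cycle(y)
  agg <- aggregate_fits(list(fit), 0.8)
  expect_lt(max(abs(reconstruct_cycle(agg, 160) - y)), 1e-8)
  flat <- reconstruct_cycle(cycle_template(2.5, numeric(12), numeric(12)), 100)
  expect_equal(flat, rep(2.5, 100))
  expect_error(render_cycle(tpl, 20), "too small")
})

test_that("aggregation averages down per-cycle coefficient noise", {
  set.seed(11)
  tpl <- default_cycle_template()
  L <- 160; sigma <- 20
  fits <- lapply(1:40, function(i)
    fit_cycle(render_cycle(tpl, L) + rnorm(L, 0, sigma)))
  agg <- aggregate_fits(fits, T_i = rep(0.8, 40))
  err_agg <- max(abs(agg$a - tpl$a))
  err_single <- min(vapply(fits, function(f) max(abs(f$a - tpl$a)), numeric(1)))
  expect_lt(err_agg, err_single)
})

test_that("time-domain landmarks agree with a dense independent search", {
  tpl <- default_cycle_template()
  fs <- 200; L <- 160
  tf <- time_features(tpl, L, fs = fs)
  # oracle: direct extrema search on a 100x dense rendering
  dense <- 100L * L
  y <- render_cycle(tpl, dense)
  rel <- y - y[1]
  i1 <- which.max(rel)
  expect_equal(tf$h1, rel[i1], tolerance = 0.01 * rel[i1])
  expect_equal(tf$t1, (i1 - 1) / dense * (L / fs), tolerance = 2 / fs)
  # the notch is a local minimum with a rebound, not the global minimum of
  # the falling limb (the decay toward the foot goes lower)
  d1 <- diff(rel)
  mins <- which(d1[-1] > 0 & d1[-length(d1)] <= 0) + 1L
  mins <- mins[mins > i1 & mins < 0.7 * dense]
  i4 <- mins[which.min(rel[mins])]
  expect_equal(tf$t4, (i4 - 1) / dense * (L / fs), tolerance = 2 / fs)
  expect_equal(tf$h4h1, rel[i4] / rel[i1], tolerance = 0.02)
  i5 <- i4 + which.max(rel[i4:floor(0.75 * dense)]) - 1L
  expect_equal(tf$t5, (i5 - 1) / dense * (L / fs), tolerance = 2 / fs)
  expect_false(tf$fallback)
  expect_true(tf$t1 < tf$t4 && tf$t4 < tf$t5 && tf$t5 < tf$period)
  expect_true(tf$w < tf$period)
})

test_that("landmark extraction falls back gracefully on notchless cycles", {
  a <- numeric(12); b <- numeric(12); b[1] <- 100
  sine <- cycle_template(0, a, b)
  tf <- time_features(sine, 160, fs = 200)
  expect_true(tf$fallback)
  expect_true(is.finite(tf$h4h1) && is.finite(tf$h5h1))
  expect_error(time_features(cycle_template(5, a * 0, b * 0), 160, fs = 200),
               "no main peak")
})

test_that("amplitude features scale with the waveform; time features do not", {
  tpl <- default_cycle_template()
  big <- cycle_template(tpl$a0 * 10, tpl$a * 10, tpl$b * 10)
  tf1 <- time_features(tpl, 160, fs = 200)
  tf10 <- time_features(big, 160, fs = 200)
  expect_equal(tf10$h1, 10 * tf1$h1, tolerance = 1e-8)
  expect_equal(tf10$t1, tf1$t1)
  expect_equal(tf10$t4, tf1$t4)
  expect_equal(tf10$t5, tf1$t5)
  expect_equal(tf10$w, tf1$w, tolerance = 1e-8)
  expect_equal(tf10$h4h1, tf1$h4h1, tolerance = 1e-8)
})

test_that("extract_features yields the fixed 193-name vector regardless of file order", {
  spec <- cohort_spec(seed = 17)
  g <- generate_recording(spec, "healthy", "S1", 1)
  fv <- extract_features(g$recording)
  expect_length(fv, 193)
  expect_identical(names(fv), feature_names())

  rec2 <- g$recording
  rec2$channels <- rec2$channels[rev(pulse_channels())]
  fv2 <- extract_features(rec2)
  expect_equal(fv2, fv, ignore_attr = TRUE)

  rec3 <- g$recording
  rec3$channels$youchi <- NULL
  expect_error(extract_features(rec3), "youchi")
})
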