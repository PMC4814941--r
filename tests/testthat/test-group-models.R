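test_that("the designed regressand sums to zero with values {n2, -n1}", {
  expect_equal(design_regressand(2, 3), c(3, 3, -2, -2, -2), ignore_attr = TRUE)
  expect_equal(design_regressand(4, 4), c(rep(4, 4), rep(-4, 4)),
               ignore_attr = TRUE)
  y <- design_regressand(98, 38)
  expect_length(y, 136)
  expect_setequal(unique(y), c(38, -98))
  expect_equal(sum(y), 0)
  expect_error(design_regressand(1, 5), "at least 2")
})

test_that("standardization centres, scales, flags constants, and transfers", {
  set.seed(1)
  X <- cbind(a = rnorm(30, 100, 10), b = rnorm(30, -2, 0.1), c = rep(7, 30))
  st <- standardize_features(X)
  expect_equal(unname(colMeans(st$Z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(st$Z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_true(st$constant[["c"]])
  expect_equal(st$scale[["c"]], 1)

  st2 <- standardize_features(st$Z)
  expect_equal(unname(st2$center[1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(st2$scale[1:2]), c(1, 1), tolerance = 1e-12)

  held <- matrix(c(120, -2, 7), 1, dimnames = list(NULL, colnames(X)))
  z <- apply_standardization(held, st)
  expect_equal(unname(z[1, 1]), (120 - st$center[["a"]]) / st$scale[["a"]])
})

test_that("forward-backward selection finds exact and planted predictors", {
  set.seed(3)
  n <- 60; p <- 40
  Z <- scale(matrix(rnorm(n * p), n, p))
  colnames(Z) <- paste0("f", seq_len(p))
  Y <- 2 * Z[, 17] + rnorm(n, 0, 1e-6)
  fit <- efbls_select(Z, Y)
  expect_identical(fit$features[1], "f17")
  expect_length(fit$features, 1)

  # a planted 3-feature signal among many is recovered at high SNR
  set.seed(4)
  n <- 120; p <- 193
  Z <- scale(matrix(rnorm(n * p), n, p))
  colnames(Z) <- paste0("f", seq_len(p))
  Y <- Z[, 5] - 1.5 * Z[, 50] + 2 * Z[, 150] + rnorm(n, 0, 0.3)
  fit <- efbls_select(Z, Y)
  expect_true(all(c("f5", "f50", "f150") %in% fit$features))

  # pure noise: never more than k_max regressors
  Yn <- rnorm(n)
  fitn <- efbls_select(Z, Yn, k_max = 7)
  expect_lte(length(fitn$features), 7)
})

test_that("forward-backward RSS path is non-increasing", {
  set.seed(5)
  Z <- scale(matrix(rnorm(50 * 30), 50, 30))
  colnames(Z) <- paste0("f", 1:30)
  fit <- efbls_select(Z, rnorm(50))
  expect_true(all(diff(fit$rss_path) <= 1e-8))
})

test_that("lasso matches the null bound, the LS limit, and the KKT oracle", {
  set.seed(6)
  n <- 30; p <- 5
  Z <- scale(matrix(rnorm(n * p), n, p))
  colnames(Z) <- paste0("x", 1:p)
  beta_true <- c(2, 0, -1.5, 0, 0.5)
  Y <- drop(Z %*% beta_true) + rnorm(n, 0, 0.5)
  Y <- Y - mean(Y)

  lam_max <- max(abs(crossprod(Z, Y)))
  expect_equal(unname(lasso_fit(Z, Y, lam_max * 1.001)$beta), rep(0, p))

  ls <- qr.solve(Z, Y)
  expect_equal(unname(lasso_fit(Z, Y, 0)$beta), unname(ls), tolerance = 1e-6)

  for (lam in c(0.5, 5, 25)) {
    cd <- lasso_fit(Z, Y, lam)
    oracle <- lasso_kkt_oracle(Z, Y, lam)
    expect_equal(unname(cd$beta), oracle, tolerance = 1e-4)
  }
})

test_that("lasso agrees with an independent implementation on a shared instance", {
  set.seed(8)
  n <- 40; p <- 8
  Z <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))
  colnames(Z) <- paste0("x", 1:p)
  Y <- drop(Z %*% c(3, -2, rep(0, 6))) + rnorm(n)
  Y <- Y - mean(Y)
  lam <- 15
  mine <- lasso_fit(Z, Y, lam)
  # glmnet minimizes (1/2n)||y - Xb||^2 + lambda_g * |b|_1
  gn <- glmnet::glmnet(Z, Y, lambda = lam / n, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-12)
  expect_equal(unname(mine$beta), as.numeric(gn$beta), tolerance = 1e-4)
})

test_that("lasso nonzero count never grows as the penalty increases", {
  set.seed(9)
  n <- 40; p <- 25
  Z <- scale(matrix(rnorm(n * p), n, p))
  colnames(Z) <- paste0("x", 1:p)
  Y <- drop(Z %*% c(rep(2, 5), rep(0, 20))) + rnorm(n)
  Y <- Y - mean(Y)
  lam_max <- max(abs(crossprod(Z, Y)))
  grid <- 10^seq(log10(lam_max), log10(lam_max) - 2, length.out = 30)
  nz <- vapply(grid, function(l) length(lasso_fit(Z, Y, l)$nonzero), integer(1))
  expect_true(all(diff(nz) >= 0))  # grid descends, so nonzeros ascend
})

test_that("cross-validated lasso is sparse on null data and recovers planted signals", {
  set.seed(10)
  n <- 60; p <- 50
  Z <- scale(matrix(rnorm(n * p), n, p))
  colnames(Z) <- paste0("x", 1:p)
  Yn <- rnorm(n); Yn <- Yn - mean(Yn)
  fit_null <- lasso_cv(Z, Yn)
  expect_lte(length(fit_null$nonzero), 3)
  cv_at_sel <- fit_null$cv$cvm[fit_null$cv$lambda == fit_null$lambda]
  expect_equal(cv_at_sel, var(Yn), tolerance = 0.5 * var(Yn))

  Y <- drop(Z %*% c(3, -3, 2, rep(0, 47))) + rnorm(n, 0, 0.5)
  Y <- Y - mean(Y)
  fit <- lasso_cv(Z, Y)
  expect_true(all(1:3 %in% fit$nonzero))
  expect_true(fit$beta[1] > 0 && fit$beta[2] < 0 && fit$beta[3] > 0)
  expect_match(fit$equation, "^Y =")

  # leave-one-out on a 12-row toy still returns a model
  Zt <- Z[1:12, 1:6]; Yt <- Y[1:12] - mean(Y[1:12])
  expect_s3_class(lasso_cv(Zt, Yt, folds = 12), "lasso_model")
})

test_that("PCA score thresholding separates clusters and respects rank limits", {
  set.seed(12)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 5), n / 2, 5),
             matrix(rnorm(n / 2 * 5, mean = 10), n / 2, 5))
  labels <- factor(rep(c("a", "b"), each = n / 2))
  st <- standardize_features(X)
  out <- pca_classify(st$Z, labels, component = 1)
  expect_equal(out$result$accuracy, 1.0)
  expect_error(pca_classify(st$Z, labels, component = 40), "rank")

  # loadings orthonormal; full back-projection reproduces the data
  R <- out$pca$rotation
  expect_equal(crossprod(R), diag(ncol(R)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(out$pca$scores %*% t(R), st$Z, tolerance = 1e-8,
               ignore_attr = TRUE)

  # two-component mode: Fisher discriminant on a score pair
  two <- pca_classify(st$Z, labels, component = c(1, 2))
  expect_gte(two$result$accuracy, 0.95)
})

test_that("the brute-force threshold search finds the documented optimum", {
  scores <- c(1, 2, 3, 2.5, 4, 5)
  labels <- factor(rep(c("g1", "g2"), each = 3), levels = c("g1", "g2"))
  ts <- pulsewave:::threshold_search(scores, labels)
  expect_equal(ts$mis, 1 / 6)
})

test_that("index classification reports accuracy = 1 - misclassification", {
  labels <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
  yhat <- c(rnorm(10, 3), rnorm(10, -3))
  res <- classify_by_index(yhat, labels)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$accuracy + res$misclassification, 1.0)

  # random labels: accuracy near the majority-class baseline
  set.seed(13)
  accs <- replicate(300, {
    classify_by_index(yhat, sample(labels))$accuracy
  })
  expect_equal(mean(accs), 0.55, tolerance = 0.07)
})

test_that("permutation p-values are exact at the extremes and calibrated under the null", {
  set.seed(14)
  labels <- factor(rep(c("a", "b"), each = 15), levels = c("a", "b"))
  strong <- c(rnorm(15, 10), rnorm(15, -10))
  expect_equal(separation_pvalue(strong, labels, n_perm = 500), 1 / 501)
  expect_error(separation_pvalue(strong, labels, n_perm = 0), "at least 1")

  pvals <- replicate(200, separation_pvalue(rnorm(30), labels, n_perm = 199))
  expect_gte(mean(pvals < 0.05), 0.02 - 0.02)
  expect_lte(mean(pvals < 0.05), 0.09)
})

test_that("repeated rounds bound used_times by R and need stratifiable groups", {
  set.seed(15)
  n <- 40; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  labels <- factor(rep(c("a", "b"), each = n / 2))
  X[labels == "b", 3] <- X[labels == "b", 3] + 4
  rep <- repeated_rounds_report(X, labels, "efbls", R = 20, seed = 1)
  expect_true(all(rep$used_times <= 20))
  expect_equal(rep$feature[1], "f3")
  expect_gte(attr(rep, "mean_accuracy"), 0.8)

  labels2 <- factor(c(rep("a", 37), rep("b", 3)))
  expect_error(repeated_rounds_report(X, labels2, "efbls"), "at least 4")
})

test_that("the permutation guard keeps the regressor cap honest", {
  set.seed(16)
  n <- 48; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  labels <- factor(rep(c("a", "b"), each = n / 2))
  k <- efbls_kmax_guard(X, labels, k_max = 7, rounds = 10, seed = 2)
  expect_lte(k, 7)
  expect_gte(k, 1)
})
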