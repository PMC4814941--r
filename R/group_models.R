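#' Standardize a feature matrix
#'
#' Centers every column; optionally scales to unit SD (used for PCA and
#' LASSO, whose results depend on column scale — harmonic amplitudes run to
#' hundreds of instrument units while phases are order-1 radians).  The
#' centers and scales are returned so held-out rows can be transformed with
#' the training parameters.  Constant columns get scale 1 and are flagged.
#'
#' @param X numeric matrix (subjects x features).
#' @param center,scale logical.
#' @return list with `Z` (transformed matrix), `center`, `scale` and
#'   `constant` (logical per column).
#' @export
standardize_features <- function(X, center = TRUE, scale = TRUE) {
  X <- as.matrix(X)
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  sds <- apply(X, 2L, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  scl <- if (scale) ifelse(constant, 1, sds) else rep(1, ncol(X))
  Z <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  list(Z = Z, center = ctr, scale = scl, constant = constant)
}

#' @rdname standardize_features
#' @param st a standardization as returned by `standardize_features()`.
#' @export
apply_standardization <- function(X, st) {
  sweep(sweep(as.matrix(X), 2L, st$center, "-"), 2L, st$scale, "/")
}

#' Designed regressand for two-group least squares
#'
#' The regressand `Y = (n2, ..., n2, -n1, ..., -n1)` (n1 copies of `n2`
#' followed by n2 copies of `-n1`) sums to zero and makes ordinary least
#' squares on centered regressors equivalent to the canonical-correlation
#' optimal two-group discriminant.
#'
#' @param n1,n2 group sizes (both >= 2).
#' @return numeric vector of length `n1 + n2` with attribute `n` = c(n1, n2).
#' @examples
#' design_regressand(2, 3)   # 3 3 -2 -2 -2
#' @export
design_regressand <- function(n1, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 subjects")
  Y <- c(rep(n2, n1), rep(-n1, n2))
  attr(Y, "n") <- c(n1 = n1, n2 = n2)
  Y
}

# RSS of the least-squares fit of Y on the columns `S`, from precomputed
# Gram pieces; returns NA for a numerically singular subset.
rss_subset <- function(G, g, yy, S) {
  sol <- tryCatch(solve(G[S, S, drop = FALSE], g[S]),
                  error = function(e) NULL)
  if (is.null(sol)) return(list(rss = NA_real_, beta = NULL))
  list(rss = yy - sum(sol * g[S]), beta = sol)
}

#' Forward-backward least-squares regressor selection
#'
#' Greedy forward selection on the residual sum of squares of the
#' least-squares fit of the designed regressand: at each step the feature
#' giving the largest RSS reduction is added; after each addition a
#' backward pass removes any included feature whose removal increases RSS
#' by at most `tol` (as a fraction of the current RSS).  Selection stops at
#' `k_max` features or when no addition reduces RSS by more than the
#' tolerance.  Numerically singular candidate sets are skipped and logged.
#'
#' The cap defaults to 7 regressors — for cohorts of this size, more
#' regressors invite overfitting; see [efbls_kmax_guard()] for the
#' permutation-based check of the cap.
#'
#' @param Z centered (or standardized) regressor matrix with column names.
#' @param Y designed regressand (see [design_regressand()]).
#' @param k_max maximum number of regressors (default 7).
#' @param tol relative RSS tolerance for both the forward stop rule and the
#'   backward elimination (default 1e-4).
#' @return list with `features` (selected column names, in selection
#'   order), `idx`, `beta` (LS coefficients of the final fit, no intercept
#'   — `Y` sums to zero and `Z` is centered), `rss`, `rss_path` and
#'   `skipped` (names dropped for rank deficiency).
#' @export
efbls_select <- function(Z, Y, k_max = 7, tol = 1e-4) {
  Z <- as.matrix(Z)
  if (nrow(Z) <= k_max + 1)
    stop("need more rows than k_max + 1 = ", k_max + 1)
  p <- ncol(Z)
  G <- crossprod(Z)
  g <- drop(crossprod(Z, Y))
  yy <- sum(Y^2)
  selected <- integer(0)
  skipped <- integer(0)
  rss_cur <- yy
  rss_path <- yy
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > 4L * k_max) break  # cycle guard
    if (length(selected) >= k_max) break
    # forward: best single addition
    cand <- setdiff(seq_len(p), c(selected, skipped))
    if (!length(cand)) break
    best_j <- NA_integer_; best_rss <- Inf
    for (j in cand) {
      r <- rss_subset(G, g, yy, c(selected, j))
      if (is.na(r$rss)) next
      if (r$rss < best_rss) { best_rss <- r$rss; best_j <- j }
    }
    if (is.na(best_j)) break
    if (rss_cur - best_rss <= tol * rss_cur) break
    if (best_rss <= 1e-12 * yy) {  # essentially perfect fit
      selected <- c(selected, best_j)
      rss_path <- c(rss_path, best_rss)
      rss_cur <- best_rss
      break
    }
    selected <- c(selected, best_j)
    rss_cur <- best_rss
    rss_path <- c(rss_path, rss_cur)
    # backward: drop features that no longer earn their keep
    repeat {
      if (length(selected) < 2L) break
      worst_i <- NA_integer_; worst_rss <- Inf
      for (i in seq_along(selected)) {
        r <- rss_subset(G, g, yy, selected[-i])
        if (is.na(r$rss)) next
        if (r$rss < worst_rss) { worst_rss <- r$rss; worst_i <- i }
      }
      if (!is.na(worst_i) && worst_rss - rss_cur <= tol * rss_cur &&
          selected[worst_i] != best_j) {
        selected <- selected[-worst_i]
        rss_cur <- worst_rss
        rss_path <- c(rss_path, rss_cur)
      } else break
    }
  }
  if (!length(selected)) {
    return(list(features = character(0), idx = integer(0),
                beta = numeric(0), rss = yy, rss_path = rss_path,
                skipped = colnames(Z)[skipped]))
  }
  fin <- rss_subset(G, g, yy, selected)
  list(features = colnames(Z)[selected], idx = selected,
       beta = stats::setNames(fin$beta, colnames(Z)[selected]),
       rss = fin$rss, rss_path = rss_path,
       skipped = colnames(Z)[skipped])
}

#' Permutation guard for the regressor cap
#'
#' Reduces `k_max` until the mean held-out accuracy of forward-backward
#' selection on permuted (null) labels stays below the overfit ceiling:
#' with labels carrying no information, a trustworthy cap should not let
#' the selector manufacture out-of-sample accuracy.
#'
#' @param X raw feature matrix.
#' @param labels two-level factor.
#' @param k_max starting cap (default 7).
#' @param rounds permuted-label rounds per candidate cap (default 20).
#' @param ceiling maximum tolerated mean null accuracy (default 0.65).
#' @param holdout held-out fraction per round.
#' @param seed RNG seed.
#' @return the accepted cap (integer) with attribute `null_accuracy`.
#' @export
efbls_kmax_guard <- function(X, labels, k_max = 7, rounds = 20,
                             ceiling = 0.65, holdout = 0.25, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  for (k in seq.int(k_max, 1L)) {
    set.seed(seed)
    accs <- vapply(seq_len(rounds), function(r) {
      perm <- sample(labels)
      rep_round_accuracy(X, perm, method = "efbls", holdout = holdout,
                         k_max = k)
    }, numeric(1))
    if (mean(accs) < ceiling) {
      return(structure(k, null_accuracy = mean(accs)))
    }
  }
  structure(1L, null_accuracy = NA_real_)
}

#' Fit the lasso at a fixed penalty by coordinate descent
#'
#' Minimizes `(1/2) * sum((Y - Z %*% beta)^2) + lambda * sum(abs(beta))` by
#' cyclic coordinate descent with soft thresholding (no intercept: `Y` is
#' the zero-sum designed regressand and `Z` is centered).  Under this
#' convention the null solution `beta = 0` is optimal exactly when
#' `lambda >= max(abs(crossprod(Z, Y)))`.
#'
#' @param Z standardized regressor matrix.
#' @param Y regressand.
#' @param lambda penalty weight (>= 0).
#' @param beta0 warm start (default zeros).
#' @param tol convergence threshold on the largest coefficient change per
#'   sweep (default 1e-8).
#' @param max_sweeps sweep budget; non-convergence is an error naming
#'   `lambda`.
#' @return object of class `lasso_model`: list with `lambda`, `beta`
#'   (named), `nonzero`, `sweeps`.
#' @export
lasso_fit <- function(Z, Y, lambda, beta0 = NULL, tol = 1e-8,
                      max_sweeps = 100000L) {
  Z <- as.matrix(Z)
  if (lambda < 0) stop("lambda must be >= 0")
  G <- crossprod(Z)
  g <- drop(crossprod(Z, Y))
  lasso_fit_gram(G, g, lambda, colnames(Z), beta0, tol, max_sweeps)
}

lasso_fit_gram <- function(G, g, lambda, nms = NULL, beta0 = NULL,
                           tol = 1e-8, max_sweeps = 100000L) {
  p <- length(g)
  if (is.null(beta0)) beta0 <- numeric(p)
  res <- lasso_cd_gram(G, g, lambda, beta0, tol, as.integer(max_sweeps))
  if (!res$converged)
    stop("lasso coordinate descent did not converge at lambda = ", lambda)
  beta <- drop(res$beta)
  names(beta) <- nms
  structure(list(lambda = lambda, beta = beta,
                 nonzero = which(beta != 0), sweeps = res$sweeps),
            class = "lasso_model")
}

#' Cross-validated lasso
#'
#' Computes the solution path on a log-spaced grid from `lambda_max` (the
#' smallest penalty with an all-zero solution) down `decades` decades,
#' scores each penalty by K-fold cross-validated squared prediction error,
#' picks the largest penalty within one standard error of the minimum (the
#' one-SE rule), and refits on all rows.
#'
#' @param Z standardized regressor matrix.
#' @param Y regressand.
#' @param folds number of CV folds (default 10; `nrow(Z)` gives
#'   leave-one-out).
#' @param nlambda grid size (default 100).
#' @param decades grid depth below `lambda_max` (default 2, the usual
#'   path depth when features outnumber rows — deeper penalties give
#'   saturated, non-unique fits).
#' @param rule `"1se"` (default) or `"min"`.
#' @return `lasso_model` with extra fields `cv`: data.frame(lambda, cvm,
#'   cvsd, nonzero), `lambda_max`, `rule`, and `equation` (the printed
#'   sparse model).
#' @export
lasso_cv <- function(Z, Y, folds = 10, nlambda = 100, decades = 2,
                     rule = c("1se", "min")) {
  rule <- match.arg(rule)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (folds < 2) stop("need at least 2 folds")
  folds <- min(folds, n)
  lambda_max <- max(abs(crossprod(Z, Y)))
  if (lambda_max == 0) lambda_max <- 1
  grid <- 10^seq(log10(lambda_max), log10(lambda_max) - decades,
                 length.out = nlambda)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  cv_err <- matrix(NA_real_, folds, nlambda)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Ztr <- Z[tr, , drop = FALSE]; Ytr <- Y[tr]
    Zte <- Z[!tr, , drop = FALSE]; Yte <- Y[!tr]
    G <- crossprod(Ztr); g <- drop(crossprod(Ztr, Ytr))
    beta <- numeric(ncol(Z))
    dfmax <- max(2L, floor(0.75 * sum(tr)))
    for (li in seq_along(grid)) {
      # approaching saturation (active set close to the training row count)
      # the solution stops being unique and coordinate descent crawls;
      # freeze the path there, as path algorithms conventionally do — the
      # tighter sweep budget here only affects that degenerate deep end
      fit <- tryCatch(lasso_fit_gram(G, g, grid[li], beta0 = beta,
                                     max_sweeps = 2000L),
                      error = function(e) NULL)
      if (is.null(fit) || length(fit$nonzero) >= dfmax) {
        if (li <= length(grid))
          cv_err[f, li:length(grid)] <- if (li > 1L) cv_err[f, li - 1L] else
            mean((Yte - mean(Ytr))^2)
        break
      }
      beta <- unname(fit$beta)
      cv_err[f, li] <- mean((Yte - drop(Zte %*% beta))^2)
    }
  }
  cvm <- colMeans(cv_err)
  cvsd <- apply(cv_err, 2L, stats::sd) / sqrt(folds)
  i_min <- which.min(cvm)
  i_sel <- if (rule == "1se")
    min(which(cvm <= cvm[i_min] + cvsd[i_min])) else i_min
  # final fit on all data, warm-started along the path
  G <- crossprod(Z); g <- drop(crossprod(Z, Y))
  beta <- numeric(ncol(Z))
  nz_path <- rep(NA_integer_, length(grid))
  fits <- vector("list", length(grid))
  dfmax <- max(2L, floor(0.75 * n))
  for (li in seq_len(max(i_sel, i_min))) {
    fit <- tryCatch(lasso_fit_gram(G, g, grid[li], nms = colnames(Z),
                                   beta0 = beta, max_sweeps = 20000L),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta <- unname(fit$beta)
    nz_path[li] <- length(fit$nonzero)
    fits[[li]] <- fit
    if (length(fit$nonzero) >= dfmax) break
  }
  done <- which(!is.na(nz_path))
  if (!length(done)) stop("lasso path failed at the largest penalty")
  out <- fits[[min(i_sel, max(done))]]
  out$cv <- data.frame(lambda = grid, cvm = cvm, cvsd = cvsd,
                       nonzero = nz_path)
  out$lambda_max <- lambda_max
  out$rule <- rule
  out$equation <- model_equation(out$beta)
  out
}

#' Render a sparse linear model as an equation string
#'
#' @param beta named coefficient vector.
#' @param digits significant digits.
#' @return a string like `"Y = -0.01*C2_zuocun - 0.11*t4_zuochi"`.
#' @export
model_equation <- function(beta, digits = 3) {
  nz <- which(beta != 0)
  if (!length(nz)) return("Y = 0")
  terms <- vapply(nz, function(j) {
    cf <- signif(beta[j], digits)
    sprintf("%s %s*%s", if (cf < 0) "-" else "+", format(abs(cf)), names(beta)[j])
  }, character(1))
  eq <- paste(terms, collapse = " ")
  sub("^\\+ ", "", paste("Y =", eq))
}

#' @export
print.lasso_model <- function(x, ...) {
  cat("<lasso_model> lambda =", signif(x$lambda, 4),
      " nonzero =", length(x$nonzero), "\n")
  if (!is.null(x$equation)) cat(" ", x$equation, "\n")
  invisible(x)
}

#' Classify by thresholding predicted indices
#'
#' Subjects with predicted index above the threshold (default 0, the mean
#' of the designed regressand) are assigned to the first label level.  If
#' that orientation gets less than half the subjects right it is flipped
#' and the flip recorded.
#'
#' @param yhat numeric predicted indices.
#' @param labels two-level factor (first level = group 1).
#' @param threshold decision cut (default 0).
#' @param orientation `+1`/`-1` to force an orientation (e.g. the one
#'   learned on training data); `NULL` (default) auto-corrects.
#' @return object of class `classification_result`: list with `predicted`,
#'   `threshold`, `misclassification`, `accuracy`
#'   (`= 1 - misclassification` exactly), `flipped`.
#' @export
classify_by_index <- function(yhat, labels, threshold = 0, orientation = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly two groups")
  lv <- levels(labels)
  pred <- factor(ifelse(yhat > threshold, lv[1L], lv[2L]), levels = lv)
  acc <- mean(pred == labels)
  flipped <- FALSE
  if (is.null(orientation)) {
    if (acc < 0.5) {
      pred <- factor(lv[3L - as.integer(pred)], levels = lv)
      acc <- 1 - acc
      flipped <- TRUE
    }
  } else if (orientation < 0) {
    pred <- factor(lv[3L - as.integer(pred)], levels = lv)
    acc <- mean(pred == labels)
    flipped <- TRUE
  }
  structure(list(predicted = pred, threshold = threshold,
                 misclassification = 1 - acc, accuracy = acc,
                 flipped = flipped),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> accuracy ", round(100 * x$accuracy, 1),
      "% (misclassification ", round(x$misclassification, 3), ")",
      if (x$flipped) " [orientation flipped]", "\n", sep = "")
  invisible(x)
}

# best threshold over midpoints of adjacent sorted scores (brute force);
# returns threshold, orientation (+1: group1 above? no — group1 if score >
# threshold), and training misclassification
threshold_search <- function(scores, labels) {
  lv <- levels(labels)
  ord <- sort(unique(scores))
  cuts <- if (length(ord) > 1L)
    (ord[-1L] + ord[-length(ord)]) / 2 else ord
  cuts <- c(min(ord) - 1, cuts, max(ord) + 1)
  best <- list(mis = Inf, threshold = cuts[1L], orientation = +1)
  for (cut in cuts) {
    above1 <- mean((scores > cut) == (labels == lv[1L]))
    for (o in c(+1, -1)) {
      acc <- if (o > 0) above1 else 1 - above1
      if (1 - acc < best$mis)
        best <- list(mis = 1 - acc, threshold = cut, orientation = o)
    }
  }
  best
}

#' Two-group classification by principal-component thresholding
#'
#' PCA decomposes the standardized feature matrix into orthogonal
#' components; for a chosen component (or each of the first `n_components`
#' in `"search"` mode) the component scores are cut at the threshold
#' minimizing training misclassification, found by brute force over
#' midpoints of adjacent sorted scores.  Optionally a pair of components is
#' combined by Fisher's linear discriminant.
#'
#' @param Z standardized feature matrix.
#' @param labels two-level factor.
#' @param component integer component index, `"search"` (default) to pick
#'   the best of the first `n_components`, or an integer pair for the
#'   two-component Fisher mode.
#' @param n_components components examined in search mode (default 10).
#' @return list with `pca` (`rotation`, `scores`, `var_explained`),
#'   `per_component` (accuracy by component), `component` (the one used),
#'   `threshold`, `orientation` and `result` (a `classification_result`).
#' @export
pca_classify <- function(Z, labels, component = "search", n_components = 10) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly two groups")
  Z <- as.matrix(Z)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rank <- ncol(pc$rotation)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  pca <- list(rotation = pc$rotation, scores = pc$x,
              var_explained = var_explained)
  if (is.numeric(component) && length(component) == 2L) {
    if (max(component) > rank) stop("component index exceeds rank ", rank)
    sc <- pc$x[, component, drop = FALSE]
    ld <- MASS::lda(sc, grouping = labels)
    proj <- drop(sc %*% ld$scaling[, 1L])
    ts <- threshold_search(proj, labels)
    res <- classify_by_index(proj, labels, ts$threshold, ts$orientation)
    return(list(pca = pca, per_component = NULL, component = component,
                threshold = ts$threshold, orientation = ts$orientation,
                result = res, discriminant = ld$scaling[, 1L]))
  }
  comps <- if (identical(component, "search")) {
    if (n_components > rank) n_components <- rank
    seq_len(n_components)
  } else {
    if (component > rank) stop("component index ", component,
                               " exceeds rank ", rank)
    as.integer(component)
  }
  per <- lapply(comps, function(ci) {
    ts <- threshold_search(pc$x[, ci], labels)
    c(component = ci, accuracy = 1 - ts$mis, threshold = ts$threshold,
      orientation = ts$orientation)
  })
  per <- as.data.frame(do.call(rbind, per))
  best <- per[which.max(per$accuracy), ]
  ci <- as.integer(best$component)
  res <- classify_by_index(pc$x[, ci], labels, best$threshold,
                           best$orientation)
  list(pca = pca, per_component = per, component = ci,
       threshold = best$threshold, orientation = best$orientation,
       result = res)
}

#' Permutation p-value for group separation of predicted indices
#'
#' Two-sided permutation test of the difference in group means of the
#' predicted indices, by label shuffling, with add-one smoothing:
#' `p = (b + 1) / (n_perm + 1)` where `b` counts permutations at least as
#' extreme as observed.
#'
#' @param yhat predicted indices.
#' @param labels two-level factor.
#' @param n_perm number of permutations (default 10000; must be >= 1).
#' @return the p-value.
#' @export
separation_pvalue <- function(yhat, labels, n_perm = 10000) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly two groups")
  if (n_perm < 1) stop("n_perm must be at least 1")
  g1 <- labels == levels(labels)[1L]
  obs <- abs(mean(yhat[g1]) - mean(yhat[!g1]))
  n1 <- sum(g1)
  b <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(yhat), n1)
    stat <- abs(mean(yhat[idx]) - mean(yhat[-idx]))
    if (stat >= obs) b <- b + 1L
  }
  (b + 1) / (n_perm + 1)
}

# one stratified holdout round; returns held-out accuracy (used by the
# k_max permutation guard)
rep_round_accuracy <- function(X, labels, method, holdout, k_max = 7) {
  r <- run_round(X, labels, method, holdout, k_max = k_max,
                 lasso_folds = 10)
  r$accuracy
}

# stratified train/test split + fit + held-out evaluation for one round
run_round <- function(X, labels, method, holdout, k_max = 7,
                      lasso_folds = 10) {
  lv <- levels(labels)
  test_idx <- unlist(lapply(lv, function(g) {
    ids <- which(labels == g)
    sample(ids, max(1L, round(holdout * length(ids))))
  }))
  tr <- setdiff(seq_along(labels), test_idx)
  Xtr <- X[tr, , drop = FALSE]; ltr <- droplevels(labels[tr])
  Xte <- X[test_idx, , drop = FALSE]; lte <- labels[test_idx]
  st <- standardize_features(Xtr)
  Ztr <- st$Z
  Zte <- apply_standardization(Xte, st)
  n1 <- sum(ltr == lv[1L]); n2 <- sum(ltr == lv[2L])
  ord <- c(which(ltr == lv[1L]), which(ltr == lv[2L]))
  Y <- design_regressand(n1, n2)
  if (method == "efbls") {
    fit <- efbls_select(Ztr[ord, , drop = FALSE], Y, k_max = k_max)
    beta <- numeric(ncol(Ztr)); beta[fit$idx] <- fit$beta
    yhat_tr <- drop(Ztr %*% beta)
    train_res <- classify_by_index(yhat_tr, ltr)
    orient <- if (train_res$flipped) -1 else +1
    yhat_te <- drop(Zte %*% beta)
    res <- classify_by_index(yhat_te, lte, orientation = orient)
    list(features = fit$features, beta = fit$beta,
         accuracy = res$accuracy, yhat = yhat_te)
  } else if (method == "lasso") {
    fit <- lasso_cv(Ztr[ord, , drop = FALSE], Y, folds = lasso_folds)
    beta <- unname(fit$beta)
    yhat_tr <- drop(Ztr %*% beta)
    train_res <- classify_by_index(yhat_tr, ltr)
    orient <- if (train_res$flipped) -1 else +1
    yhat_te <- drop(Zte %*% beta)
    res <- classify_by_index(yhat_te, lte, orientation = orient)
    list(features = names(fit$beta)[fit$nonzero],
         beta = fit$beta[fit$nonzero],
         accuracy = res$accuracy, yhat = yhat_te)
  } else if (method == "pca") {
    cls <- pca_classify(Ztr, ltr, component = "search")
    sc_te <- drop(Zte %*% cls$pca$rotation[, cls$component])
    res <- classify_by_index(sc_te, lte, cls$threshold, cls$orientation)
    list(features = paste0("PC", cls$component), beta = NULL,
         accuracy = res$accuracy, yhat = sc_te)
  } else stop("unknown method: ", method)
}

#' Repeated-round selection-frequency report
#'
#' Runs `R` rounds of stratified random subsampling (train `1 - holdout`,
#' test `holdout`); each round standardizes on the training rows, fits the
#' chosen selector, and evaluates held-out accuracy.  The report gives, per
#' feature, `used_times` (rounds selecting it, out of `R`), `importance`
#' (mean absolute standardized coefficient over rounds where selected) and
#' the raw feature mean and SD over all subjects, plus the mean held-out
#' accuracy.
#'
#' @param X raw feature matrix (subjects x features) with column names.
#' @param labels two-level factor; every group needs at least 4 members so
#'   the split can be stratified.
#' @param method `"efbls"`, `"lasso"` or `"pca"`.
#' @param R rounds (default 20).
#' @param holdout held-out fraction (default 0.25).
#' @param seed RNG seed.
#' @param k_max forward-backward cap (efbls only).
#' @param lasso_folds CV folds inside each round (lasso only).
#' @return object of class `selection_report`: data.frame (feature,
#'   used_times, importance, mean, sd) sorted by used_times, with
#'   attributes `mean_accuracy`, `accuracies`, `R`, `method`.
#' @export
repeated_rounds_report <- function(X, labels, method = c("efbls", "lasso", "pca"),
                                   R = 20, holdout = 0.25, seed = 1L,
                                   k_max = 7, lasso_folds = 10) {
  method <- match.arg(method)
  if (R < 2) stop("need at least 2 rounds")
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly two groups")
  if (any(table(labels) < 4L))
    stop("each group needs at least 4 members to stratify the holdout")
  set.seed(seed)
  used <- integer(ncol(X)); names(used) <- colnames(X)
  imp_sum <- numeric(ncol(X)); names(imp_sum) <- colnames(X)
  accs <- numeric(R)
  for (r in seq_len(R)) {
    rr <- run_round(X, labels, method, holdout, k_max = k_max,
                    lasso_folds = lasso_folds)
    accs[r] <- rr$accuracy
    if (method != "pca" && length(rr$features)) {
      used[rr$features] <- used[rr$features] + 1L
      imp_sum[rr$features] <- imp_sum[rr$features] + abs(rr$beta)
    }
  }
  tab <- data.frame(feature = colnames(X),
                    used_times = unname(used),
                    importance = ifelse(used > 0, imp_sum / pmax(used, 1L), 0),
                    mean = colMeans(X),
                    sd = apply(X, 2L, stats::sd),
                    row.names = NULL)
  tab <- tab[order(-tab$used_times, -tab$importance), ]
  structure(tab, class = c("selection_report", "data.frame"),
            mean_accuracy = mean(accs), accuracies = accs,
            R = R, method = method)
}

#' @export
print.selection_report <- function(x, n = 10, ...) {
  cat("<selection_report> method=", attr(x, "method"),
      " rounds=", attr(x, "R"),
      " mean held-out accuracy=", round(attr(x, "mean_accuracy"), 3),
      "\n", sep = "")
  sel <- x[x$used_times > 0, , drop = FALSE]
  if (nrow(sel)) {
    print.data.frame(utils::head(sel, n), row.names = FALSE, digits = 4)
    if (nrow(sel) > n) cat("... ", nrow(sel) - n, " more selected features\n")
  } else cat("  (no feature ever selected)\n")
  invisible(x)
}
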