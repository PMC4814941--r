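#' Simulate a cohort and write it to disk
#'
#' Wraps [generate_cohort()]: writes one waveform CSV per subject, a
#' manifest CSV (`subject_id`, `group`, `file`, `fs`) and the ground truth
#' (true onsets, per-cycle lengths, generating templates) as JSON.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly; the manifest also records the
#'   cohort seed as a comment-free extra column is avoided — the seed is in
#'   `ground_truth.json`.
#' @export
simulate_cohort <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coh <- generate_cohort(spec)
  mani <- coh$manifest
  mani$file <- paste0(mani$subject_id, ".csv")
  mani$fs <- spec$fs
  for (i in seq_len(nrow(mani))) {
    sid <- mani$subject_id[i]
    write_recording(coh$recordings[[sid]], file.path(dir, mani$file[i]))
  }
  truth <- lapply(coh$truth, function(tr) {
    list(onsets = tr$onsets, L_i = tr$L_i, T_i = tr$T_i,
         templates = lapply(tr$templates, function(tp)
           list(a0 = tp$a0, a = tp$a, b = tp$b)))
  })
  jsonlite::write_json(list(seed = spec$seed, truth = truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(as.data.frame(mani), mpath, row.names = FALSE)
  invisible(mpath)
}

#' Extract features for a whole cohort
#'
#' Runs [extract_features()] on every subject of a manifest (on-disk
#' cohort) or of an in-memory [generate_cohort()] result.  Subjects whose
#' extraction fails are excluded and the failure reasons collected; zero
#' successful subjects is an error.
#'
#' @param cohort a `cohort_manifest` (from [read_manifest()]), a manifest
#'   path, or the list returned by [generate_cohort()].
#' @param fs fallback sampling rate for manifests without an `fs` column.
#' @param ... passed to [extract_features()].
#' @return data.frame with `subject_id`, `group` and the 193 feature
#'   columns; attribute `failures` is a named character vector of excluded
#'   subjects.
#' @export
extract_cohort_features <- function(cohort, fs = 200, ...) {
  recs <- list()
  if (is.character(cohort)) cohort <- read_manifest(cohort)
  if (inherits(cohort, "cohort_manifest")) {
    dir <- attr(cohort, "dir")
    for (i in seq_len(nrow(cohort))) {
      path <- cohort$file[i]
      if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(dir, path)
      fsi <- if ("fs" %in% names(cohort)) cohort$fs[i] else fs
      recs[[cohort$subject_id[i]]] <-
        tryCatch(read_recording(path, fs = fsi,
                                subject_id = cohort$subject_id[i],
                                group = cohort$group[i]),
                 error = function(e) e)
    }
  } else if (is.list(cohort) && !is.null(cohort$recordings)) {
    recs <- cohort$recordings
  } else stop("`cohort` must be a manifest, a manifest path, or a generated cohort")
  rows <- list(); failures <- character(0)
  for (sid in names(recs)) {
    rec <- recs[[sid]]
    fv <- if (inherits(rec, "error")) rec else
      tryCatch(extract_features(rec, ...), error = function(e) e)
    if (inherits(fv, "error")) {
      failures[sid] <- conditionMessage(fv)
      next
    }
    grp <- if (inherits(rec, "error")) NA_character_ else rec$group
    rows[[sid]] <- data.frame(subject_id = sid, group = grp,
                              t(as.numeric(fv)), stringsAsFactors = FALSE)
    names(rows[[sid]]) <- c("subject_id", "group", names(fv))
  }
  if (!length(rows))
    stop("feature extraction failed for every subject; first failure: ",
         if (length(failures)) failures[1L] else "none recorded")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Two-group classification report for a cohort
#'
#' Runs the requested methods — PCA component thresholding, designed-
#' regressand least squares with forward-backward selection, and
#' cross-validated LASSO — on one pairwise group comparison, each with a
#' full-data fit, a permutation p-value of the predicted-index separation,
#' and a repeated-round selection-frequency report.  Three-group cohorts
#' are analysed as pairwise comparisons, one call per pair.
#'
#' @param features feature data.frame from [extract_cohort_features()] or
#'   [read_feature_matrix()].
#' @param groups character pair naming the two groups to compare.
#' @param methods subset of `c("pca", "efbls", "lasso")`.
#' @param R repeated rounds (default 20).
#' @param holdout held-out fraction per round.
#' @param k_max forward-backward regressor cap (default 7).
#' @param seed RNG seed.
#' @param n_perm permutations for the separation p-value.
#' @return object of class `pulse_classification`: per-method list with the
#'   full-data fit, `accuracy` (full data), `p_value`, `equation` (sparse
#'   methods), and `report` (a `selection_report`).
#' @export
classify_cohort <- function(features, groups = c("healthy", "fld"),
                            methods = c("pca", "efbls", "lasso"),
                            R = 20, holdout = 0.25, k_max = 7, seed = 1L,
                            n_perm = 2000) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(groups) != 2L) stop("`groups` must name exactly two groups")
  unknown <- setdiff(groups, unique(features$group))
  if (length(unknown)) stop("unknown group name(s): ",
                            paste(unknown, collapse = ", "))
  sub <- features[features$group %in% groups, ]
  labels <- factor(sub$group, levels = groups)
  if (any(table(labels) < 4L)) stop("both groups need at least 4 subjects")
  X <- feature_matrix(sub)
  st <- standardize_features(X)
  n1 <- sum(labels == groups[1L]); n2 <- sum(labels == groups[2L])
  ord <- c(which(labels == groups[1L]), which(labels == groups[2L]))
  Y <- design_regressand(n1, n2)
  out <- list()
  for (m in methods) {
    set.seed(seed)
    if (m == "pca") {
      fit <- pca_classify(st$Z, labels)
      yhat <- fit$pca$scores[, fit$component]
      full_acc <- fit$result$accuracy
      eq <- NULL
      sel_features <- paste0("PC", fit$component)
    } else if (m == "efbls") {
      fit <- efbls_select(st$Z[ord, , drop = FALSE], Y, k_max = k_max)
      beta <- numeric(ncol(X)); beta[fit$idx] <- fit$beta
      yhat <- drop(st$Z %*% beta)
      full_acc <- classify_by_index(yhat, labels)$accuracy
      eq <- model_equation(stats::setNames(beta, colnames(X)))
      sel_features <- fit$features
    } else {
      fit <- lasso_cv(st$Z[ord, , drop = FALSE], Y)
      yhat <- drop(st$Z %*% unname(fit$beta))
      full_acc <- classify_by_index(yhat, labels)$accuracy
      eq <- fit$equation
      sel_features <- names(fit$beta)[fit$nonzero]
    }
    pval <- separation_pvalue(yhat, labels, n_perm = n_perm)
    report <- repeated_rounds_report(X, labels, method = m, R = R,
                                     holdout = holdout, seed = seed,
                                     k_max = k_max)
    out[[m]] <- list(fit = fit, selected = sel_features,
                     accuracy = full_acc, p_value = pval,
                     equation = eq, report = report,
                     mean_cv_accuracy = attr(report, "mean_accuracy"))
  }
  structure(list(groups = groups, n = c(n1, n2), methods = out,
                 R = R, holdout = holdout, k_max = k_max, seed = seed),
            class = "pulse_classification")
}

#' @export
print.pulse_classification <- function(x, ...) {
  cat("<pulse_classification> ", x$groups[1L], " (n=", x$n[1L], ") vs ",
      x$groups[2L], " (n=", x$n[2L], ")\n", sep = "")
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    cat(sprintf("  %-6s full-data accuracy %.0f%%, mean held-out %.0f%%, p = %.4g\n",
                m, 100 * r$accuracy, 100 * r$mean_cv_accuracy, r$p_value))
    if (!is.null(r$equation)) cat("         ", r$equation, "\n")
  }
  invisible(x)
}

#' Write a classification result to JSON
#'
#' @param cls a `pulse_classification`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(cls, path) {
  body <- list(groups = cls$groups, n = cls$n, seed = cls$seed,
               R = cls$R, holdout = cls$holdout, k_max = cls$k_max)
  body$methods <- lapply(cls$methods, function(r) {
    rep_df <- as.data.frame(r$report)
    rep_df <- rep_df[rep_df$used_times > 0, , drop = FALSE]
    list(selected = r$selected,
         accuracy = r$accuracy,
         mean_cv_accuracy = r$mean_cv_accuracy,
         p_value = r$p_value,
         equation = r$equation,
         report = rep_df)
  })
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
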