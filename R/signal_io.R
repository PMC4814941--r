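#' Construct a pulse recording
#'
#' A pulse recording holds up to six named channels of sampled radial-artery
#' waveform, the sampling rate, and subject metadata.  Amplitudes are in
#' arbitrary instrument units (raw ADC counts); no physical calibration is
#' attempted.
#'
#' @param channels named list of numeric vectors; names must be drawn from
#'   [pulse_channels()].
#' @param fs sampling rate in Hz; must exceed 96 Hz so that the 0.5-48 Hz
#'   analysis band is representable.
#' @param subject_id subject identifier string.
#' @param group group label, one of [pulse_groups()].
#' @return an object of class `pulse_recording` with fields `subject_id`,
#'   `group`, `fs`, `channels`, `duration_s` and attribute
#'   `missing_channels`.
#' @export
pulse_recording <- function(channels, fs, subject_id = "anon", group = "unknown") {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list of numeric vectors")
  bad <- setdiff(names(channels), pulse_channels())
  if (length(bad))
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         "; expected names among: ", paste(pulse_channels(), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (fs <= 2 * 48)
    stop("sampling rate fs = ", fs, " Hz too low: need fs > 96 Hz so the ",
         "0.5-48 Hz filter band is representable")
  group <- match.arg(group, pulse_groups())
  lens <- vapply(channels, length, integer(1))
  if (any(lens == 0L)) stop("zero-length channel(s): ",
                            paste(names(channels)[lens == 0L], collapse = ", "))
  for (nm in names(channels)) {
    if (!is.numeric(channels[[nm]]))
      stop("channel ", nm, " is not numeric")
    channels[[nm]] <- as.numeric(channels[[nm]])
  }
  if (length(unique(lens)) > 1L)
    stop("channels differ in length: ",
         paste(paste0(names(lens), "=", lens), collapse = ", "))
  rec <- structure(
    list(subject_id = as.character(subject_id), group = group, fs = fs,
         channels = channels, duration_s = lens[[1L]] / fs),
    class = "pulse_recording")
  attr(rec, "missing_channels") <- setdiff(pulse_channels(), names(channels))
  rec
}

#' @export
print.pulse_recording <- function(x, ...) {
  cat("<pulse_recording> subject", x$subject_id, "group", x$group, "\n")
  cat("  fs:", x$fs, "Hz  duration:", round(x$duration_s, 3), "s\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  miss <- attr(x, "missing_channels")
  if (length(miss)) cat("  missing:", paste(miss, collapse = ", "), "\n")
  invisible(x)
}

#' Read a pulse waveform CSV
#'
#' Waveform files are plain CSV with a header row naming the channels (a
#' subset of [pulse_channels()]) and one row per sample.  The sampling rate
#' is supplied out of band (manifest column or argument) because the file
#' format does not carry it.
#'
#' @param path path to the CSV file.
#' @param fs sampling rate in Hz (default 200).
#' @param subject_id,group subject metadata attached to the recording.
#' @return a [pulse_recording()].
#' @export
read_recording <- function(path, fs = 200, subject_id = "anon", group = "unknown") {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  bad <- setdiff(names(df), pulse_channels())
  if (length(bad))
    stop("waveform file ", path, " has unknown channel column(s): ",
         paste(bad, collapse = ", "))
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.character(col) || is.factor(col)) {
      suppressWarnings(num <- as.numeric(as.character(col)))
      if (anyNA(num) & !anyNA(col)) {
        row <- which(is.na(num))[1L]
        stop("non-numeric value in ", path, " at row ", row,
             ", column '", names(df)[j], "'")
      }
      df[[j]] <- num
    }
    if (anyNA(df[[j]])) {
      row <- which(is.na(df[[j]]))[1L]
      stop("missing/non-numeric value in ", path, " at row ", row,
           ", column '", names(df)[j], "'")
    }
  }
  pulse_recording(as.list(df), fs = fs, subject_id = subject_id, group = group)
}

#' Write a pulse recording to CSV
#'
#' @param rec a [pulse_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pulse_recording"))
  if (!length(rec$channels)) stop("recording has no channels to write")
  df <- as.data.frame(lapply(rec$channels, format_full), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 17 significant digits: doubles survive the text round trip bit-exactly
format_full <- function(x) sprintf("%.17g", x)

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `file` and
#' optionally `fs`.  Paths in `file` are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param path manifest CSV path.
#' @return a data.frame of class `cohort_manifest` with attribute `counts`
#'   (named: healthy, fld, cirrhosis) and `dir` (the manifest's directory).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "file")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicate subject_id in manifest: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$group), pulse_groups())
  if (length(bad))
    stop("unknown group label(s) in manifest: ", paste(bad, collapse = ", "))
  as_manifest(df, dir = dirname(path))
}

as_manifest <- function(df, dir = ".") {
  counts <- c(healthy = sum(df$group == "healthy"),
              fld = sum(df$group == "fld"),
              cirrhosis = sum(df$group == "cirrhosis"))
  structure(df, class = c("cohort_manifest", "data.frame"),
            counts = counts, dir = dir)
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("<cohort_manifest> ", nrow(x), " subjects (healthy ", cnt[["healthy"]],
      ", fld ", cnt[["fld"]], ", cirrhosis ", cnt[["cirrhosis"]], ")\n", sep = "")
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n")
  invisible(x)
}

#' Read/write a 193-column feature matrix
#'
#' Feature matrices are CSV files with columns `subject_id`, `group` and the
#' 193 named parameters of [feature_names()], in that fixed order.  Reading
#' a file whose feature columns are not exactly the 193-name vocabulary is a
#' format error.
#'
#' @param features data.frame with `subject_id`, `group` and the 193 feature
#'   columns.
#' @param path CSV path.
#' @return `read_feature_matrix()` returns the data.frame with feature
#'   columns reordered to the canonical order.
#' @export
write_feature_matrix <- function(features, path) {
  nm <- feature_names()
  miss <- setdiff(nm, names(features))
  if (length(miss))
    stop("feature matrix missing ", length(miss), " of the ", length(nm),
         " expected parameters (first missing: ", miss[1L], ")")
  df <- features[, c("subject_id", "group", nm)]
  for (cn in nm) df[[cn]] <- format_full(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature matrix missing column(s): ", paste(miss, collapse = ", "))
  feat_cols <- setdiff(names(df), need)
  nm <- feature_names()
  if (length(feat_cols) != length(nm) || length(setdiff(nm, feat_cols)))
    stop("feature matrix has ", length(feat_cols),
         " feature columns; expected exactly ", length(nm),
         " (32 parameters x 6 channels + 1 global period)")
  df[, c(need, nm)]
}

#' Extract the numeric feature matrix from a feature data.frame
#'
#' @param features data.frame as returned by [extract_cohort_features()] or
#'   [read_feature_matrix()].
#' @return numeric matrix (subjects x 193) with rownames = subject_id.
#' @export
feature_matrix <- function(features) {
  nm <- feature_names()
  X <- as.matrix(features[, nm])
  rownames(X) <- features$subject_id
  storage.mode(X) <- "double"
  X
}
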