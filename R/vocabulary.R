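#' Channel and feature vocabulary
#'
#' Pulse waveforms are recorded at three palpation positions (cun, guan, chi,
#' distal to proximal) on each wrist (zuo = left, you = right), giving six
#' channels.  Per channel the pipeline extracts 12 harmonic amplitudes
#' (C1-C12), 12 harmonic phases (F1-F12) and 8 time-domain parameters
#' (h1, t1, h3/h1, h4/h1, h5/h1, w, t4, t5); one global parameter, the mean
#' cycle period t, is shared across channels.  That gives
#' 32 x 6 + 1 = 193 named parameters per subject.
#'
#' @return `pulse_channels()` returns the six channel names in canonical
#'   order; `feature_names()` returns the 193 feature names in the fixed
#'   order used by every feature matrix written or read by this package.
#' @examples
#' pulse_channels()
#' length(feature_names())  # 193
#' @export
pulse_channels <- function() {
  c("zuocun", "zuoguan", "zuochi", "youcun", "youguan", "youchi")
}

#' @rdname pulse_channels
#' @export
feature_names <- function() {
  per_channel <- c(paste0("C", 1:12), paste0("F", 1:12),
                   "h1", "t1", "h3h1", "h4h1", "h5h1", "w", "t4", "t5")
  nm <- unlist(lapply(pulse_channels(), function(ch) paste0(per_channel, "_", ch)))
  c(nm, "t")
}

#' @rdname pulse_channels
#' @export
pulse_groups <- function() c("healthy", "fld", "cirrhosis", "unknown")

# per-channel parameter stems (32 per channel; internal)
channel_param_stems <- function() {
  c(paste0("C", 1:12), paste0("F", 1:12),
    "h1", "t1", "h3h1", "h4h1", "h5h1", "w", "t4", "t5")
}
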