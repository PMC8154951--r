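#' Valid-trial determination
#'
#' A test trial is valid when the infant's gaze was at the centre of the
#' screen just before the lateral images appeared: at least `min_frac` of the
#' valid samples in the `[-pre_onset_window_ms, 0)` window must fall in the
#' centre AOI. Trials with no valid pre-onset samples are invalid with reason
#' `no_data`.
#'
#' @param samples Trial samples with `rel_ms` (time relative to image onset),
#'   `x_px`, `y_px`, `valid`.
#' @param aois An [aoi_config()].
#' @param pre_onset_window_ms Length of the pre-onset check window
#'   (default 100 ms, one fixation-length of evidence).
#' @param min_frac Minimum centred fraction (default 0.5).
#' @return A list: `valid` (flag), `reason` (`"ok"`,
#'   `"not_centered_at_onset"` or `"no_data"`), `frac_centered`.
#' @export
validate_trial <- function(samples, aois, pre_onset_window_ms = 100,
                           min_frac = 0.5) {
  stopifnot(inherits(aois, "aoi_config"))
  tcol <- if ("rel_ms" %in% names(samples)) samples$rel_ms else samples$time_ms
  pre <- samples[tcol >= -pre_onset_window_ms & tcol < 0, , drop = FALSE]
  pre <- pre[as.logical(pre$valid), , drop = FALSE]
  if (nrow(pre) == 0L) {
    return(list(valid = FALSE, reason = "no_data", frac_centered = NA_real_))
  }
  frac <- mean(in_rect(pre$x_px, pre$y_px, aois$center))
  if (frac >= min_frac) {
    list(valid = TRUE, reason = "ok", frac_centered = frac)
  } else {
    list(valid = FALSE, reason = "not_centered_at_onset", frac_centered = frac)
  }
}

#' Infant-level inclusion decision
#'
#' An infant enters the analysis when they contribute at least
#' `min_valid_trials` valid test trials (default 5).
#'
#' @param validities Logical vector (or a list of [validate_trial()] results)
#'   over the infant's trials.
#' @param min_valid_trials Inclusion threshold (default 5).
#' @return A list: `included` (flag), `n_valid`, `n_trials`.
#' @export
include_infant <- function(validities, min_valid_trials = 5L) {
  if (is.list(validities) && !is.data.frame(validities)) {
    validities <- vapply(validities, function(v) isTRUE(v$valid), logical(1))
  }
  validities <- as.logical(validities)
  n_valid <- sum(validities, na.rm = TRUE)
  list(included = n_valid >= min_valid_trials, n_valid = n_valid,
       n_trials = length(validities))
}

#' Familiarization engagement summary
#'
#' Computes the percentage of the familiarization stream the infant spent
#' looking at the visual stimulus (TLT-pct), with the full stream duration as
#' denominator, and the split of on-face time between the eyes and mouth
#' sub-regions.
#'
#' @param samples Familiarization samples with `time_ms`, `x_px`, `y_px`,
#'   `valid`.
#' @param stream The `stream_spec` (defines the expected duration).
#' @param aois An [aoi_config()].
#' @param period_ms Sampling period (default 20).
#' @param denominator `"stream"` (default: the full stream duration) or
#'   `"tracked"` (valid samples only).
#' @return A list: `tlt_pct`, `eyes_pct`, `mouth_pct`, `n_on_face`,
#'   `n_expected`.
#' @export
familiarization_summary <- function(samples, stream, aois, period_ms = 20,
                                    denominator = c("stream", "tracked")) {
  stopifnot(inherits(stream, "stream_spec"), inherits(aois, "aoi_config"))
  denominator <- match.arg(denominator)
  if (stream$total_duration_ms <= 0) stop("zero-duration stream")
  n_expected <- floor(stream$total_duration_ms / period_ms)
  v <- samples[as.logical(samples$valid), , drop = FALSE]
  lab <- assign_aoi(v$x_px, v$y_px, aois, set = "familiarization")
  on_face <- lab %in% c("eyes", "mouth", "stimulus")
  denom <- if (denominator == "stream") n_expected else max(nrow(v), 1L)
  tlt_pct <- 100 * sum(on_face) / denom
  n_face <- sum(on_face)
  eyes_pct <- if (n_face > 0) 100 * sum(lab == "eyes") / n_face else NA_real_
  mouth_pct <- if (n_face > 0) 100 * sum(lab == "mouth") / n_face else NA_real_
  list(tlt_pct = tlt_pct, eyes_pct = eyes_pct, mouth_pct = mouth_pct,
       n_on_face = n_face, n_expected = n_expected)
}
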