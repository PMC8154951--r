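#' Per-trial looking-time metrics within the analysis window
#'
#' From the AOI-labelled fixations of one valid test trial, computes within
#' `[start_ms, end_ms]`:
#' \describe{
#'   \item{TLT}{total looking time per lateral image: summed fixation
#'     durations clipped to the window.}
#'   \item{LF}{longest single (clipped) fixation per lateral image.}
#'   \item{FG}{first gaze: 1 if the first lateral fixation beginning at or
#'     after `start_ms` is on the correct side, 0 if on the incorrect side,
#'     `NA` if there is none.}
#' }
#' The proportions `tlt_p = tlt_correct / (tlt_correct + tlt_incorrect)` and
#' `lf_p` are `NA` when their denominator is 0; the accuracies binarize the
#' proportions (1 above 0.5, 0 below, `NA` at exactly 0.5).
#'
#' @param fixations Fixation tibble from [idt_fixations()] with an `aoi`
#'   column (labels `left` / `right` among others).
#' @param correct_side `"left"` or `"right"`.
#' @param window An `analysis_window` (or a list with `start_ms`, `end_ms`).
#' @return A one-row tibble: `fg`, `tlt_correct_ms`, `tlt_incorrect_ms`,
#'   `tlt_p`, `tlt_acc`, `lf_correct_ms`, `lf_incorrect_ms`, `lf_p`, `lf_acc`.
#' @export
trial_metrics <- function(fixations, correct_side, window) {
  stopifnot(correct_side %in% c("left", "right"))
  start <- window$start_ms
  end <- window$end_ms
  incorrect_side <- if (correct_side == "left") "right" else "left"
  fx <- fixations[fixations$aoi %in% c("left", "right"), , drop = FALSE]
  clip <- pmax(0, pmin(fx$offset_ms, end) - pmax(fx$onset_ms, start))
  tlt <- function(side) sum(clip[fx$aoi == side])
  lf <- function(side) {
    d <- clip[fx$aoi == side & clip > 0]
    if (length(d)) max(d) else 0
  }
  tlt_c <- tlt(correct_side); tlt_i <- tlt(incorrect_side)
  lf_c <- lf(correct_side); lf_i <- lf(incorrect_side)

  prop <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  acc <- function(p) {
    if (is.na(p) || p == 0.5) NA_real_ else as.numeric(p > 0.5)
  }
  tlt_p <- prop(tlt_c, tlt_i)
  lf_p <- prop(lf_c, lf_i)

  first <- fx[fx$onset_ms >= start & fx$onset_ms < end, , drop = FALSE]
  fg <- if (nrow(first) == 0L) NA_real_ else {
    as.numeric(first$aoi[which.min(first$onset_ms)] == correct_side)
  }
  tibble::new_tibble(list(fg = fg,
                          tlt_correct_ms = tlt_c, tlt_incorrect_ms = tlt_i,
                          tlt_p = tlt_p, tlt_acc = acc(tlt_p),
                          lf_correct_ms = lf_c, lf_incorrect_ms = lf_i,
                          lf_p = lf_p, lf_acc = acc(lf_p)), nrow = 1L)
}

#' Per-infant aggregation of trial metrics
#'
#' Arithmetic means of each metric over the infant's valid trials, ignoring
#' `NA` trial values (ties and trials with no lateral looking); metrics that
#' are `NA` in every trial stay `NA` with a warning (the infant is then
#' excluded from group tests of that metric).
#'
#' @param metrics Tibble of [trial_metrics()] rows (one per valid trial).
#' @param infant_id Identifier.
#' @param age_months Optional age covariate.
#' @return A one-row tibble: `infant_id`, `age_months`, `n_valid_trials`, and
#'   `mean_fg`, `mean_tlt_correct_ms`, `mean_tlt_incorrect_ms`, `mean_tlt_p`,
#'   `mean_tlt_acc`, `mean_lf_p`, `mean_lf_acc`.
#' @export
infant_summary <- function(metrics, infant_id, age_months = NA_real_) {
  if (nrow(metrics) < 1L) stop("at least one trial is required")
  avg <- function(col) {
    v <- metrics[[col]]
    if (all(is.na(v))) {
      warning(sprintf("infant %s: '%s' undefined in every trial", infant_id, col))
      return(NA_real_)
    }
    mean(v, na.rm = TRUE)
  }
  tibble::tibble(
    infant_id = infant_id,
    age_months = age_months,
    n_valid_trials = nrow(metrics),
    mean_fg = avg("fg"),
    mean_tlt_correct_ms = avg("tlt_correct_ms"),
    mean_tlt_incorrect_ms = avg("tlt_incorrect_ms"),
    mean_tlt_p = avg("tlt_p"),
    mean_tlt_acc = avg("tlt_acc"),
    mean_lf_p = avg("lf_p"),
    mean_lf_acc = avg("lf_acc")
  )
}
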