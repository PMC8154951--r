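#' Per-infant lateralization matrix
#'
#' Averages the binary lateralization timecourses of each infant's valid
#' trials, giving one row per infant and one column per 20 ms time point: row
#' i, column t is the proportion of infant i's valid trials whose gaze was
#' over a lateralized image at time t.
#'
#' @param courses Numeric matrix, one row per valid trial, columns on the
#'   common time grid (e.g. stacked [lateralization_timecourse()] vectors).
#' @param infants Vector of infant identifiers, one per row of `courses`.
#' @param time_ms Optional time grid; taken from `colnames(courses)` or the
#'   `time_ms` attribute when absent.
#' @return A list of class `lateralization_matrix`: `mat` (infants x time),
#'   `n_trials` (named vector), `time_ms`.
#' @export
build_lateralization_matrix <- function(courses, infants, time_ms = NULL) {
  courses <- as.matrix(courses)
  stopifnot(nrow(courses) == length(infants))
  if (is.null(time_ms)) {
    time_ms <- attr(courses, "time_ms")
    if (is.null(time_ms) && !is.null(colnames(courses))) {
      time_ms <- as.numeric(colnames(courses))
    }
  }
  if (is.null(time_ms)) stop("a time grid is required")
  if (any(courses < 0 | courses > 1, na.rm = TRUE)) {
    stop("lateralization values must lie in [0, 1]")
  }
  keep <- !is.na(infants)
  if (!all(keep)) {
    warning("dropping trials with missing infant id")
    courses <- courses[keep, , drop = FALSE]
    infants <- infants[keep]
  }
  if (nrow(courses) == 0L) stop("no trials to aggregate")
  ids <- unique(infants)
  mat <- t(vapply(ids, function(id) {
    colMeans(courses[infants == id, , drop = FALSE])
  }, numeric(ncol(courses))))
  rownames(mat) <- ids
  n_trials <- vapply(ids, function(id) sum(infants == id), integer(1))
  structure(list(mat = mat, n_trials = n_trials, time_ms = time_ms),
            class = "lateralization_matrix")
}

#' Pointwise one-sample t-test of lateralization against a ceiling
#'
#' At each time point, the infants' mean lateralization proportions are
#' submitted to a right-tailed one-sample t-test against `mu0` (default 0.98):
#' a point is significantly lateralized when essentially the whole cohort is
#' at ceiling. Zero-variance columns (all infants identical) have no t
#' statistic; by convention they are significant iff their common mean exceeds
#' `mu0` (ceiling behaviour is exactly the phenomenon under test).
#'
#' @param lat A `lateralization_matrix`, or a plain infants x time matrix.
#' @param mu0 Null value (default 0.98).
#' @param alpha Pointwise significance level (default 0.01).
#' @param time_ms Time grid when `lat` is a plain matrix.
#' @return A tibble of class `pointwise_test`: `time_ms`, `mean`, `sd`, `t`,
#'   `p`, `significant`.
#' @export
pointwise_test <- function(lat, mu0 = 0.98, alpha = 0.01, time_ms = NULL) {
  if (inherits(lat, "lateralization_matrix")) {
    time_ms <- lat$time_ms
    mat <- lat$mat
  } else {
    mat <- as.matrix(lat)
    if (is.null(time_ms)) time_ms <- as.numeric(colnames(mat))
  }
  n <- nrow(mat)
  if (n < 2L) stop("at least 2 infants are required for the pointwise test")
  m <- colMeans(mat)
  s <- sqrt(colSums(sweep(mat, 2L, m)^2) / (n - 1L))
  tstat <- (m - mu0) / (s / sqrt(n))
  p <- stats::pt(tstat, df = n - 1L, lower.tail = FALSE)
  zv <- s == 0
  p[zv] <- ifelse(m[zv] > mu0, 0, 1)
  tstat[zv] <- ifelse(m[zv] > mu0, Inf, -Inf)
  out <- tibble::tibble(time_ms = time_ms, mean = m, sd = s, t = tstat, p = p,
                        significant = p < alpha)
  class(out) <- c("pointwise_test", class(out))
  attr(out, "mu0") <- mu0
  attr(out, "alpha") <- alpha
  attr(out, "n") <- n
  out
}

#' Locate the analysis window from the significance mask
#'
#' The analysis window runs from the earliest time point t >= 0 such that
#' every grid point in \[t, `end_ms`\] is significant (sustained
#' significance), to `end_ms`. A `transient_tolerance` of k > 0 grid points
#' allows isolated non-significant runs of at most k points inside the
#' window. If the mask is never sustainedly significant through `end_ms`, a
#' no-window result (`found = FALSE`) is returned with diagnostics.
#'
#' @param pw A `pointwise_test` tibble (or any data frame with `time_ms` and
#'   `significant`).
#' @param end_ms Window end (default 4700).
#' @param transient_tolerance Maximum ignorable run of non-significant points
#'   (default 0, strict).
#' @param min_width_ms Minimum usable window width (default 100: a window
#'   narrower than one fixation cannot support the fixation-based metrics and
#'   is reported as no-window).
#' @return A list of class `analysis_window`: `start_ms`, `end_ms`, `found`,
#'   `n_significant`, `pointwise` (the input mask).
#' @export
find_window <- function(pw, end_ms = 4700, transient_tolerance = 0L,
                        min_width_ms = 100) {
  stopifnot(all(c("time_ms", "significant") %in% names(pw)))
  sel <- pw$time_ms >= 0 & pw$time_ms <= end_ms
  times <- pw$time_ms[sel]
  sig <- pw$significant[sel]
  if (length(times) == 0L) stop("no time points at or after 0")
  start_ms <- NA_real_
  found <- FALSE
  if (any(sig)) {
    bad <- !sig
    # positions belonging to a non-significant run longer than the tolerance
    r <- rle(bad)
    blocking <- rep(r$values & r$lengths > transient_tolerance, r$lengths)
    # also: the window cannot end on tolerated non-significance
    last_block <- if (any(blocking)) max(which(blocking)) else 0L
    cand <- if (last_block < length(times)) (last_block + 1L) else NA_integer_
    if (!is.na(cand)) {
      # window must open on a significant point
      while (cand <= length(times) && !sig[cand]) cand <- cand + 1L
      if (cand <= length(times) && times[length(times)] == end_ms && sig[length(sig)]) {
        start_ms <- times[cand]
        found <- TRUE
      }
    }
  }
  if (found && end_ms - start_ms < min_width_ms) {
    start_ms <- NA_real_
    found <- FALSE
  }
  structure(list(start_ms = start_ms, end_ms = end_ms, found = found,
                 n_significant = sum(sig), pointwise = pw),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  if (x$found) {
    cat("<analysis_window> [", x$start_ms, ",", x$end_ms, "] ms\n")
  } else {
    cat("<analysis_window> no sustained window found (",
        x$n_significant, "significant points )\n")
  }
  invisible(x)
}

#' Plot the cohort lateralization curve and pointwise p values
#'
#' A two-panel summary of the data-driven window procedure: the mean (+/- SD)
#' lateralization proportion across infants over time, and the pointwise
#' right-tailed p values with the alpha line, with the window onset marked.
#' Requires ggplot2.
#'
#' @param lat A `lateralization_matrix`.
#' @param window An `analysis_window` from [find_window()].
#' @return A ggplot object.
#' @export
plot_lateralization <- function(lat, window = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  m <- colMeans(lat$mat)
  s <- apply(lat$mat, 2L, stats::sd)
  df <- data.frame(time_ms = lat$time_ms, mean = m,
                   lo = pmax(m - s, 0), hi = pmin(m + s, 1))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = time_ms, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from image onset (ms)",
                  y = "proportion of lateralized gaze") +
    ggplot2::theme_minimal()
  if (!is.null(window) && isTRUE(window$found)) {
    gg <- gg + ggplot2::geom_vline(xintercept = window$start_ms,
                                   linetype = "dashed")
  }
  gg
}
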