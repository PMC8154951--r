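#' Bridge isolated invalid samples by linear interpolation
#'
#' Tracker exports routinely contain isolated one-sample dropouts (blinks,
#' glints). A single invalid sample flanked by two valid samples on the 20 ms
#' grid is replaced by the linear interpolation of its neighbours; longer
#' invalid runs are left untouched (they break fixation windows).
#'
#' @param samples Data frame with `time_ms`, `x_px`, `y_px`, `valid`.
#' @param period_ms Sampling period (default 20).
#' @return The samples with bridged rows marked `valid = TRUE` and
#'   interpolated coordinates.
#' @export
bridge_invalid_samples <- function(samples, period_ms = 20) {
  n <- nrow(samples)
  if (n < 3L) return(samples)
  v <- as.logical(samples$valid)
  t <- samples$time_ms
  i <- 2:(n - 1L)
  single <- !v[i] & v[i - 1L] & v[i + 1L] &
    (t[i] - t[i - 1L] == period_ms) & (t[i + 1L] - t[i] == period_ms)
  idx <- i[single]
  if (length(idx)) {
    samples$x_px[idx] <- (samples$x_px[idx - 1L] + samples$x_px[idx + 1L]) / 2
    samples$y_px[idx] <- (samples$y_px[idx - 1L] + samples$y_px[idx + 1L]) / 2
    samples$valid[idx] <- TRUE
  }
  samples
}

# Greedy maximal I-DT on one gap-free run of valid samples.
# Returns a matrix of (start_idx, end_idx) rows.
idt_windows <- function(x, y, k, threshold) {
  n <- length(x)
  out_s <- integer(0)
  out_e <- integer(0)
  i <- 1L
  while (i + k - 1L <= n) {
    j <- i + k - 1L
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    if ((xmax - xmin) + (ymax - ymin) <= threshold) {
      while (j + 1L <= n) {
        nx <- x[j + 1L]; ny <- y[j + 1L]
        nxmin <- min(xmin, nx); nxmax <- max(xmax, nx)
        nymin <- min(ymin, ny); nymax <- max(ymax, ny)
        if ((nxmax - nxmin) + (nymax - nymin) > threshold) break
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
        j <- j + 1L
      }
      out_s <- c(out_s, i)
      out_e <- c(out_e, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cbind(out_s, out_e)
}

#' Dispersion-threshold (I-DT) fixation detection
#'
#' Parses time-ordered gaze samples of a single infant and phase into
#' fixations with the standard dispersion algorithm: a window of consecutive
#' valid samples is a fixation iff it lasts at least `min_duration_ms` and its
#' dispersion `(max x - min x) + (max y - min y)` stays at or below
#' `dispersion_px`; windows are extended greedily until the next sample would
#' violate the threshold, so emitted fixations are maximal, non-overlapping
#' and time-ordered. Samples outside fixations are saccades/noise. A window
#' never spans a gap of more than one sample: isolated invalid samples are
#' bridged by interpolation (see [bridge_invalid_samples()]; disable with
#' `bridge = FALSE`), longer invalid runs and timestamp gaps split the trace.
#'
#' A fixation's duration is `n_samples * period_ms` (each sample stands for
#' one 20 ms frame), so the minimum duration of 100 ms requires 5 samples.
#'
#' @param samples Data frame with `time_ms`, `x_px`, `y_px`, `valid` (and any
#'   other columns, ignored), sorted by time.
#' @param dispersion_px Dispersion threshold in pixels (default 30,
#'   approximately 0.9 degrees on the reference setup).
#' @param min_duration_ms Minimum fixation duration (default 100).
#' @param period_ms Sampling period (default 20, i.e. 50 Hz).
#' @param bridge Interpolate isolated invalid samples (default `TRUE`).
#' @param aois Optional [aoi_config()]; when given, fixation centroids are
#'   labelled with [assign_aoi()] (test-phase set).
#' @return A tibble with one row per fixation: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `x_px`, `y_px` (centroid), `n_samples`, and `aoi` when
#'   `aois` is supplied. Empty input or all-invalid input yields zero rows.
#' @examples
#' s <- data.frame(time_ms = seq(0, 180, 20), x_px = 500, y_px = 400, valid = TRUE)
#' idt_fixations(s)
#' @export
idt_fixations <- function(samples, dispersion_px = 30, min_duration_ms = 100,
                          period_ms = 20, bridge = TRUE, aois = NULL) {
  empty <- tibble::tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                          duration_ms = numeric(0), x_px = numeric(0),
                          y_px = numeric(0), n_samples = integer(0))
  if (is.null(samples) || nrow(samples) == 0L) {
    return(if (is.null(aois)) empty else tibble::tibble(empty, aoi = character(0)))
  }
  if (!"time_ms" %in% names(samples)) {
    if ("rel_ms" %in% names(samples)) samples$time_ms <- samples$rel_ms
    else stop("samples need a time_ms (or rel_ms) column")
  }
  stopifnot(all(diff(samples$time_ms) > 0))
  if (bridge) samples <- bridge_invalid_samples(samples, period_ms)
  v <- as.logical(samples$valid) & !is.na(samples$x_px) & !is.na(samples$y_px)
  k <- as.integer(ceiling(min_duration_ms / period_ms))

  # split into runs of contiguous valid samples
  new_run <- !v | c(TRUE, diff(samples$time_ms) != period_ms)
  run_id <- cumsum(new_run)
  run_id[!v] <- NA_integer_

  onset <- offset <- cx <- cy <- numeric(0)
  nsamp <- integer(0)
  tvec <- samples$time_ms
  xvec <- samples$x_px
  yvec <- samples$y_px
  for (rid in unique(run_id[!is.na(run_id)])) {
    idx <- which(!is.na(run_id) & run_id == rid)
    if (length(idx) < k) next
    w <- idt_windows(xvec[idx], yvec[idx], k, dispersion_px)
    if (nrow(w) == 0L) next
    for (r in seq_len(nrow(w))) {
      sel <- idx[w[r, 1L]:w[r, 2L]]
      onset <- c(onset, tvec[sel[1L]])
      offset <- c(offset, tvec[sel[length(sel)]] + period_ms)
      cx <- c(cx, mean(xvec[sel]))
      cy <- c(cy, mean(yvec[sel]))
      nsamp <- c(nsamp, length(sel))
    }
  }
  out <- if (length(onset)) {
    ord <- order(onset)
    tibble::new_tibble(list(onset_ms = onset[ord], offset_ms = offset[ord],
                            duration_ms = nsamp[ord] * period_ms,
                            x_px = cx[ord], y_px = cy[ord],
                            n_samples = nsamp[ord]),
                       nrow = length(onset))
  } else empty
  if (!is.null(aois)) out$aoi <- assign_aoi(out$x_px, out$y_px, aois)
  out
}

#' Binary lateralization timecourse of one test trial
#'
#' For every 20 ms time point from `t_start` to `t_end` (relative to the
#' lateral-image onset at t = 0), codes 1 when the gaze falls over either
#' lateralized image (left or right AOI) and 0 otherwise; invalid or missing
#' samples are coded 0 (after the same isolated-dropout bridging used before
#' fixation detection, unless `bridge = FALSE`).
#'
#' With `source = "fixations"` the trace is first parsed into fixations and a
#' time point is lateral when it is covered by a fixation centred on a lateral
#' AOI, or lies in the gap between two such fixations (gaze in transit between
#' the images).
#'
#' @param samples Trial samples with `rel_ms` (time relative to image onset;
#'   falls back to `time_ms`), `x_px`, `y_px`, `valid`.
#' @param aois An [aoi_config()].
#' @param t_start,t_end Grid limits in ms (defaults -500 and 4700).
#' @param period_ms Grid step (default 20).
#' @param bridge Bridge isolated invalid samples (default `TRUE`).
#' @param source `"samples"` (default) or `"fixations"`.
#' @return Numeric 0/1 vector over the grid, with the grid in attribute
#'   `time_ms`.
#' @export
lateralization_timecourse <- function(samples, aois, t_start = -500,
                                      t_end = 4700, period_ms = 20,
                                      bridge = TRUE,
                                      source = c("samples", "fixations")) {
  source <- match.arg(source)
  grid <- seq(t_start, t_end, by = period_ms)
  out <- numeric(length(grid))
  tcol <- if ("rel_ms" %in% names(samples)) samples$rel_ms else samples$time_ms
  if (source == "samples") {
    if (nrow(samples)) {
      s <- samples
      s$time_ms <- tcol
      if (bridge) s <- bridge_invalid_samples(s, period_ms)
      lat <- as.logical(s$valid) &
        (in_rect(s$x_px, s$y_px, aois$left) | in_rect(s$x_px, s$y_px, aois$right))
      m <- match(grid, s$time_ms)
      hit <- !is.na(m)
      out[hit] <- as.numeric(lat[m[hit]])
    }
  } else {
    s <- samples
    s$time_ms <- tcol
    fx <- idt_fixations(s, period_ms = period_ms, bridge = bridge, aois = aois)
    fx <- fx[fx$aoi %in% c("left", "right"), , drop = FALSE]
    if (nrow(fx)) {
      for (r in seq_len(nrow(fx))) {
        out[grid >= fx$onset_ms[r] & grid < fx$offset_ms[r]] <- 1
      }
      if (nrow(fx) > 1L) {
        for (r in seq_len(nrow(fx) - 1L)) {
          out[grid >= fx$offset_ms[r] & grid < fx$onset_ms[r + 1L]] <- 1
        }
      }
    }
  }
  attr(out, "time_ms") <- grid
  out
}
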