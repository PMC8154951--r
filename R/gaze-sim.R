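#' Synthetic infant gaze profile
#'
#' Ground-truth generative parameters of one simulated infant. Preference acts
#' at the level of look episodes, not samples: after leaving the centre, the
#' infant produces a sequence of lateral look episodes with lognormal
#' durations, each episode targeting the correct image with probability
#' `preference_theta` (0.5 = no preference); this reproduces the strongly
#' autocorrelated structure of real gaze. Episode boundaries re-orient with
#' probability `refixation_rate` (drawing a fresh side), visit the centre with
#' probability `p_center_return`, and otherwise re-fixate the same image.
#'
#' Defaults emulate the descriptive statistics of 8-month-old cohorts on a
#' 50 Hz remote tracker: roughly 9 +/- 3 valid trials out of 16
#' (`p_invalid_trial = 0.45`), familiarization engagement around 70%, looks of
#' a couple of seconds, ~700 ms median latency to lateralize after image
#' onset, 2% isolated sample loss, and mid-session fussiness attrition near
#' 17%.
#'
#' @param infant_id Identifier string.
#' @param age_months Age in months.
#' @param preference_theta Probability that a lateral look episode targets the
#'   correct image.
#' @param center_latency_meanlog,center_latency_sdlog Lognormal parameters of
#'   the latency (ms) to leave the centre after image onset.
#' @param fixation_dur_meanlog,fixation_dur_sdlog Lognormal parameters of look
#'   episode durations (ms).
#' @param refixation_rate Probability per episode boundary of re-orienting
#'   (drawing a new side Bernoulli(`preference_theta`)).
#' @param p_center_return Probability per episode boundary of a brief return
#'   to the centre before the next lateral look.
#' @param p_missing_sample Per-sample probability of an invalid (lost) sample.
#' @param p_invalid_trial Probability that the infant is not centred at image
#'   onset (the trial then fails the validity check downstream).
#' @param engagement_familiarization Fraction of the familiarization stream
#'   spent looking at the stimulus.
#' @param p_eyes_region Of on-face looking, fraction of episodes targeting the
#'   eyes region (the rest target the mouth).
#' @param fussiness_dropout Probability of mid-session dropout (the recording
#'   is truncated and the infant flagged for exclusion).
#' @param saccade_ms Transit duration between look targets.
#' @param centroid_jitter_sd Gaussian jitter (px) of episode centroids around
#'   the AOI centre.
#' @param sample_noise_sd Within-episode per-sample Gaussian noise (px).
#' @return An object of class `infant_profile`.
#' @export
infant_profile <- function(infant_id = "i01",
                           age_months = 8,
                           preference_theta = 0.5,
                           center_latency_meanlog = log(700),
                           center_latency_sdlog = 0.25,
                           fixation_dur_meanlog = log(1800),
                           fixation_dur_sdlog = 0.55,
                           refixation_rate = 0.5,
                           p_center_return = 0,
                           p_missing_sample = 0.02,
                           p_invalid_trial = 0.45,
                           engagement_familiarization = 0.70,
                           p_eyes_region = 0.90,
                           fussiness_dropout = 0.17,
                           saccade_ms = 40,
                           centroid_jitter_sd = 15,
                           sample_noise_sd = 3) {
  p <- list(infant_id = infant_id, age_months = age_months,
            preference_theta = preference_theta,
            center_latency_meanlog = center_latency_meanlog,
            center_latency_sdlog = center_latency_sdlog,
            fixation_dur_meanlog = fixation_dur_meanlog,
            fixation_dur_sdlog = fixation_dur_sdlog,
            refixation_rate = refixation_rate,
            p_center_return = p_center_return,
            p_missing_sample = p_missing_sample,
            p_invalid_trial = p_invalid_trial,
            engagement_familiarization = engagement_familiarization,
            p_eyes_region = p_eyes_region,
            fussiness_dropout = fussiness_dropout,
            saccade_ms = saccade_ms,
            centroid_jitter_sd = centroid_jitter_sd,
            sample_noise_sd = sample_noise_sd)
  probs <- c("preference_theta", "refixation_rate", "p_center_return",
             "p_missing_sample", "p_invalid_trial",
             "engagement_familiarization", "p_eyes_region", "fussiness_dropout")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(sprintf("%s must be in [0, 1]", nm))
  }
  if (p$saccade_ms < 0) stop("saccade_ms must be non-negative")
  structure(p, class = "infant_profile")
}

jittered_center <- function(rect, sd) rect_center(rect) + stats::rnorm(2L, 0, sd)

# Growable segment accumulator for the piecewise look plans (avoids the
# data.frame-per-segment overhead in the per-trial simulation loop).
new_seg_plan <- function(cap = 32L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$start <- env$end <- env$x <- env$y <- env$x0 <- env$y0 <- numeric(cap)
  env$transit <- logical(cap)
  env
}

seg_push <- function(env, start, end, xy, transit = FALSE, xy0 = c(NA_real_, NA_real_)) {
  n <- env$n + 1L
  if (n > length(env$start)) {
    for (f in c("start", "end", "x", "y", "x0", "y0", "transit")) {
      env[[f]] <- c(env[[f]], env[[f]])
    }
  }
  env$start[n] <- start; env$end[n] <- end
  env$x[n] <- xy[1]; env$y[n] <- xy[2]
  env$transit[n] <- transit
  env$x0[n] <- xy0[1]; env$y0[n] <- xy0[2]
  env$n <- n
}

seg_collect <- function(env) {
  n <- env$n
  list(start = env$start[seq_len(n)], end = env$end[seq_len(n)],
       x = env$x[seq_len(n)], y = env$y[seq_len(n)],
       transit = env$transit[seq_len(n)],
       x0 = env$x0[seq_len(n)], y0 = env$y0[seq_len(n)])
}

# Piecewise look plan -> 20 ms samples. segs: list(start, end, x, y,
# transit, x0, y0); transit rows interpolate (x0,y0) -> (x,y).
emit_samples <- function(grid, segs, profile, screen) {
  idx <- findInterval(grid, segs$start)
  idx[idx < 1L] <- 1L
  x <- segs$x[idx]
  y <- segs$y[idx]
  tr <- segs$transit[idx]
  if (any(tr)) {
    f <- (grid[tr] - segs$start[idx[tr]]) /
      pmax(segs$end[idx[tr]] - segs$start[idx[tr]], 1e-9)
    x[tr] <- segs$x0[idx[tr]] + f * (segs$x[idx[tr]] - segs$x0[idx[tr]])
    y[tr] <- segs$y0[idx[tr]] + f * (segs$y[idx[tr]] - segs$y0[idx[tr]])
  }
  n <- length(grid)
  x <- x + stats::rnorm(n, 0, profile$sample_noise_sd)
  y <- y + stats::rnorm(n, 0, profile$sample_noise_sd)
  x <- pmin(pmax(x, 0), screen[1] - 1e-6)
  y <- pmin(pmax(y, 0), screen[2] - 1e-6)
  valid <- stats::runif(n) >= profile$p_missing_sample
  offscreen <- is.na(x) | is.na(y)
  valid <- valid & !offscreen
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  list(x_px = x, y_px = y, valid = valid)
}

#' Simulate the gaze of one test trial
#'
#' Generates 50 Hz samples from `t_start` to `t_end` relative to the
#' lateral-image onset at t = 0. On a valid draw the gaze starts in the
#' centre, departs after a lognormal latency, and then alternates lateral look
#' episodes choosing the correct side per episode with probability
#' `preference_theta`; with probability `p_invalid_trial` the infant is
#' instead already looking at a (random) lateral image before onset, so the
#' trial fails the downstream centring check. Episode centroids are jittered
#' around the AOI centre and target-to-target transits take `saccade_ms`.
#'
#' Uses the current RNG state; seed the session (or use [simulate_cohort()])
#' for reproducibility.
#'
#' @param profile An [infant_profile()].
#' @param trial One row of a `trial_schedule`'s `trials` tibble (needs
#'   `correct_side`).
#' @param aois An [aoi_config()].
#' @param t_start,t_end Sample grid limits (defaults -500 and 4700 ms).
#' @param period_ms Sampling period (default 20).
#' @return A tibble with `rel_ms`, `x_px`, `y_px`, `valid`.
#' @export
simulate_trial <- function(profile, trial, aois, t_start = -500,
                           t_end = 4700, period_ms = 20) {
  stopifnot(inherits(profile, "infant_profile"), inherits(aois, "aoi_config"))
  correct <- trial$correct_side
  incorrect <- if (correct == "left") "right" else "left"
  grid <- seq(t_start, t_end, by = period_ms)
  draw_dur <- function() stats::rlnorm(1L, profile$fixation_dur_meanlog,
                                       profile$fixation_dur_sdlog)
  invalid_trial <- stats::runif(1L) < profile$p_invalid_trial

  plan <- new_seg_plan()
  push <- function(start, end, xy, transit = FALSE, xy0 = c(NA_real_, NA_real_)) {
    seg_push(plan, start, end, xy, transit, xy0)
  }

  if (!invalid_trial) {
    latency <- stats::rlnorm(1L, profile$center_latency_meanlog,
                             profile$center_latency_sdlog)
    c0 <- jittered_center(aois$center, profile$centroid_jitter_sd)
    push(t_start, latency, c0)
    cur <- latency
    side <- if (stats::runif(1L) < profile$preference_theta) correct else incorrect
    prev_xy <- c0
  } else {
    cur <- t_start
    side <- if (stats::runif(1L) < 0.5) correct else incorrect
    prev_xy <- NULL
  }

  while (cur <= t_end) {
    xy <- jittered_center(aois[[side]], profile$centroid_jitter_sd)
    if (!is.null(prev_xy) && profile$saccade_ms > 0) {
      push(cur, cur + profile$saccade_ms, xy, transit = TRUE, xy0 = prev_xy)
      cur <- cur + profile$saccade_ms
    }
    dur <- draw_dur()
    push(cur, cur + dur, xy)
    cur <- cur + dur
    prev_xy <- xy
    if (stats::runif(1L) < profile$p_center_return) {
      cxy <- jittered_center(aois$center, profile$centroid_jitter_sd)
      if (profile$saccade_ms > 0) {
        push(cur, cur + profile$saccade_ms, cxy, transit = TRUE, xy0 = prev_xy)
        cur <- cur + profile$saccade_ms
      }
      cdur <- 0.3 * draw_dur()
      push(cur, cur + cdur, cxy)
      cur <- cur + cdur
      prev_xy <- cxy
      side <- if (stats::runif(1L) < profile$preference_theta) correct else incorrect
    } else if (stats::runif(1L) < profile$refixation_rate) {
      side <- if (stats::runif(1L) < profile$preference_theta) correct else incorrect
    }
  }
  out <- emit_samples(grid, seg_collect(plan), profile, aois$screen)
  tibble::new_tibble(list(rel_ms = grid, x_px = out$x_px, y_px = out$y_px,
                          valid = out$valid), nrow = length(grid))
}

#' Simulate familiarization-phase gaze over a stream
#'
#' Alternates on-stimulus look episodes (targeting the eyes region with
#' probability `p_eyes_region`, otherwise the mouth) with off-stimulus
#' episodes whose durations are scaled so the on-stimulus fraction tracks
#' `engagement_familiarization` tightly. Off-stimulus episodes are either
#' background looks (valid samples outside the stimulus rectangle) or
#' tracking loss (invalid samples), with equal probability.
#'
#' @param profile An [infant_profile()].
#' @param stream A `stream_spec` from [schedule_stream()].
#' @param aois An [aoi_config()].
#' @param period_ms Sampling period (default 20).
#' @return A tibble with `time_ms` (from 0), `x_px`, `y_px`, `valid`.
#' @export
simulate_familiarization <- function(profile, stream, aois, period_ms = 20) {
  stopifnot(inherits(profile, "infant_profile"), inherits(stream, "stream_spec"))
  total <- stream$total_duration_ms
  if (total <= 0) stop("zero-duration stream")
  grid <- seq(0, by = period_ms, length.out = floor(total / period_ms))
  e <- profile$engagement_familiarization
  draw_dur <- function() stats::rlnorm(1L, profile$fixation_dur_meanlog,
                                       profile$fixation_dur_sdlog)
  bg_point <- function() {
    # a point on screen but outside the stimulus rectangle
    if (stats::runif(1L) < 0.5) c(stats::runif(1L, 0, aois$stimulus[1] - 1),
                                  stats::runif(1L, 0, aois$screen[2] - 1))
    else c(stats::runif(1L, 0, aois$screen[1] - 1),
           stats::runif(1L, 0, aois$stimulus[2] - 1))
  }
  plan <- new_seg_plan()
  push <- function(start, end, xy, lost = FALSE) {
    seg_push(plan, start, end, if (lost) c(NA_real_, NA_real_) else xy)
  }
  cur <- 0
  while (cur <= total) {
    if (e > 0) {
      on_dur <- draw_dur()
      region <- if (stats::runif(1L) < profile$p_eyes_region) "eyes" else "mouth"
      push(cur, cur + on_dur, jittered_center(aois[[region]],
                                              profile$centroid_jitter_sd))
      cur <- cur + on_dur
      if (e < 1) {
        off_dur <- on_dur * (1 - e) / e
        lost <- stats::runif(1L) < 0.5
        push(cur, cur + off_dur, if (lost) c(NA, NA) else bg_point(), lost = lost)
        cur <- cur + off_dur
      }
    } else {
      push(cur, total + period_ms, c(NA, NA), lost = TRUE)
      break
    }
  }
  out <- emit_samples(grid, seg_collect(plan), profile, aois$screen)
  tibble::new_tibble(list(time_ms = grid, x_px = out$x_px, y_px = out$y_px,
                          valid = out$valid), nrow = length(grid))
}

#' Simulate a cohort of infants
#'
#' Generates complete synthetic recordings (familiarization and/or test
#' phases) plus a ground-truth table of each infant's drawn parameters, for
#' parameter-recovery and calibration studies. Reproducible given `seed`.
#' Infants drawn as fussy are truncated at a random point of the test phase
#' and flagged in the truth table (downstream analysis excludes them via the
#' flag, mimicking manual fussiness exclusion).
#'
#' Test-trial sample times are stored as absolute time within the phase:
#' trial k occupies `[(k-1) * span, k * span)` ms where
#' `span = t_end - t_start + period_ms`; the image onset of trial k is at
#' `(k-1) * span - t_start`. The `rel_ms` column carries onset-relative time.
#'
#' @param n_infants Number of infants (>= 1).
#' @param schedule A `trial_schedule` from [build_test_trials()].
#' @param stream Optional `stream_spec` (required when `"familiarization"` is
#'   in `phases`).
#' @param aois An [aoi_config()].
#' @param profile Template [infant_profile()] for all infants.
#' @param theta Optional vector (length 1 or `n_infants`) of per-infant
#'   preference parameters overriding the profile's.
#' @param age_mean,age_sd Normal distribution of ages (months).
#' @param phases Character subset of `c("test", "familiarization")`.
#' @param seed Optional integer seed.
#' @param t_start,t_end,period_ms Trial sample grid (defaults -500, 4700, 20).
#' @return A list with `samples` (one tibble: `infant_id`, `phase`,
#'   `trial_id`, `time_ms`, `rel_ms`, `x_px`, `y_px`, `valid`) and `truth`
#'   (tibble of per-infant ground-truth parameters and the `fussy` flag).
#' @export
simulate_cohort <- function(n_infants, schedule, stream = NULL,
                            aois = aoi_config(), profile = infant_profile(),
                            theta = NULL, age_mean = 7.96, age_sd = 0.25,
                            phases = c("test", "familiarization"),
                            seed = NULL, t_start = -500, t_end = 4700,
                            period_ms = 20) {
  stopifnot(n_infants >= 1L, inherits(schedule, "trial_schedule"))
  phases <- match.arg(phases, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if ("familiarization" %in% phases && is.null(stream)) {
    stop("a stream_spec is required to simulate the familiarization phase")
  }
  if (is.null(theta)) theta <- profile$preference_theta
  theta <- rep_len(theta, n_infants)
  span <- t_end - t_start + period_ms

  ids <- sprintf("i%02d", seq_len(n_infants))
  acc <- list()  # per-part lists of parallel column vectors
  add_part <- function(id, phase, trial_id, time_ms, rel_ms, out) {
    n <- length(time_ms)
    acc[[length(acc) + 1L]] <<- list(
      infant_id = rep(id, n), phase = rep(phase, n),
      trial_id = rep(trial_id, n), time_ms = time_ms, rel_ms = rel_ms,
      x_px = out$x_px, y_px = out$y_px, valid = out$valid)
  }
  ages <- numeric(n_infants)
  fussy_flags <- logical(n_infants)
  for (i in seq_len(n_infants)) {
    p <- profile
    p$infant_id <- ids[i]
    p$preference_theta <- theta[i]
    ages[i] <- stats::rnorm(1L, age_mean, age_sd)
    fussy_flags[i] <- stats::runif(1L) < p$fussiness_dropout
    if ("familiarization" %in% phases) {
      fam <- simulate_familiarization(p, stream, aois, period_ms)
      add_part(ids[i], "familiarization", NA_integer_, fam$time_ms,
               rep(NA_real_, nrow(fam)), fam)
    }
    if ("test" %in% phases) {
      n_trials <- nrow(schedule$trials)
      keep <- if (fussy_flags[i]) sample.int(n_trials, 1L) - 1L else n_trials
      for (k in seq_len(keep)) {
        tr <- simulate_trial(p, schedule$trials[k, ], aois,
                             t_start, t_end, period_ms)
        add_part(ids[i], "test", k, (k - 1L) * span + (tr$rel_ms - t_start),
                 tr$rel_ms, tr)
      }
    }
  }
  cols <- lapply(stats::setNames(nm = c("infant_id", "phase", "trial_id",
                                        "time_ms", "rel_ms", "x_px", "y_px",
                                        "valid")),
                 function(f) do.call(c, lapply(acc, `[[`, f)))
  samples <- tibble::new_tibble(cols, nrow = length(cols$time_ms))
  truth <- tibble::tibble(
    infant_id = ids, age_months = ages, preference_theta = theta,
    engagement = profile$engagement_familiarization,
    p_eyes_region = profile$p_eyes_region,
    p_invalid_trial = profile$p_invalid_trial,
    fussy = fussy_flags)
  list(samples = samples, truth = truth)
}

#' Write gaze samples in the canonical CSV dialect
#'
#' Columns `infant_id, phase, trial_id, time_ms, x_px, y_px, valid` (valid as
#' 0/1), comma-separated.
#'
#' @param samples A samples tibble (e.g. from [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(samples, path) {
  out <- samples[, c("infant_id", "phase", "trial_id", "time_ms",
                     "x_px", "y_px", "valid")]
  out$valid <- as.integer(out$valid)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read gaze samples (comma- or tab-separated)
#'
#' Accepts the canonical dialect written by [write_gaze_csv()] with either
#' separator, and reconstructs the onset-relative `rel_ms` column for test
#' trials from the fixed trial span.
#'
#' @param path Input file path.
#' @param t_start,t_end,period_ms The trial grid the file was generated with.
#' @return A samples tibble.
#' @export
read_gaze_csv <- function(path, t_start = -500, t_end = 4700, period_ms = 20) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  df$valid <- df$valid != 0
  span <- t_end - t_start + period_ms
  df$rel_ms <- ifelse(df$phase == "test",
                      df$time_ms - (df$trial_id - 1L) * span + t_start,
                      NA_real_)
  tibble::as_tibble(df[, c("infant_id", "phase", "trial_id", "time_ms",
                           "rel_ms", "x_px", "y_px", "valid")])
}
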