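#' Analyse one experiment's gaze recordings
#'
#' Runs the full test-phase analysis on a cohort's samples: per-trial validity
#' (centred just before image onset), infant inclusion (>= `min_valid_trials`
#' valid trials), the data-driven analysis window (per-infant lateralization
#' averages, pointwise right-tailed t-test against `mu0`, sustained
#' significance through `end_ms`), I-DT fixation parsing and AOI labelling of
#' every valid trial, the per-trial looking metrics within the window,
#' per-infant summaries, and the group-level tests (paired TLT
#' correct/incorrect; one-sample t against 0.5 for TLT-p, TLT-acc, LF-p,
#' LF-acc and FG; first-gaze chi-square; Shapiro-Wilk diagnostics).
#'
#' When the strict pointwise criterion never yields a sustained window (it
#' requires essentially ceiling lateralization in every valid trial),
#' `window_fallback = "full"` (default) computes the metrics over the full
#' 0 to `end_ms` interval and flags `window$found = FALSE`.
#'
#' @param samples Samples tibble (see [simulate_cohort()] / [read_gaze_csv()]).
#' @param schedule The session's `trial_schedule`.
#' @param aois An [aoi_config()].
#' @param meta Optional tibble with `infant_id`, `age_months`, and optionally
#'   a logical `fussy` column (fussy infants are excluded up front).
#' @param min_valid_trials Inclusion threshold (default 5).
#' @param pre_onset_window_ms,center_frac Validity-check parameters.
#' @param mu0,alpha Pointwise-test parameters (defaults 0.98, 0.01).
#' @param end_ms Analysis end (default 4700).
#' @param window_fallback `"full"` or `"none"` (error when no window).
#' @param timecourse_source `"samples"` (default) or `"fixations"`, see
#'   [lateralization_timecourse()].
#' @return A list of class `experiment_analysis`: `qc` (per-infant validity
#'   counts and inclusion), `window`, `lat_matrix`, `trial_metrics` (per valid
#'   trial, with trial factors), `infants` (per-infant summaries), `stats`
#'   (group tests), `familiarization` (per-infant TLT-pct and eyes/mouth
#'   split, when familiarization samples and `stream` are supplied).
#' @param stream Optional `stream_spec` for familiarization summaries.
#' @export
analyze_experiment <- function(samples, schedule, aois = aoi_config(),
                               meta = NULL, stream = NULL,
                               min_valid_trials = 5L,
                               pre_onset_window_ms = 100, center_frac = 0.5,
                               mu0 = 0.98, alpha = 0.01, end_ms = 4700,
                               window_fallback = c("full", "none"),
                               timecourse_source = c("samples", "fixations")) {
  window_fallback <- match.arg(window_fallback)
  timecourse_source <- match.arg(timecourse_source)
  stopifnot(inherits(schedule, "trial_schedule"))

  fussy_ids <- character(0)
  if (!is.null(meta) && "fussy" %in% names(meta)) {
    fussy_ids <- meta$infant_id[which(meta$fussy)]
  }
  test <- samples[samples$phase == "test" &
                    !(samples$infant_id %in% fussy_ids), , drop = FALSE]
  if (nrow(test) == 0L) stop("no test-phase samples")
  test <- as.data.frame(test)   # plain-frame subsetting in the hot loops
  by_inf <- split(test, test$infant_id)

  qc_rows <- list()
  courses <- list()
  course_inf <- character(0)
  metr_rows <- list()
  inf_rows <- list()
  trials_tbl <- schedule$trials
  splits <- list()      # per infant: list(by_trial, valid_ids)

  for (id in names(by_inf)) {
    inf <- by_inf[[id]]
    by_trial <- split(inf, inf$trial_id)
    val <- vapply(by_trial, function(tr) {
      validate_trial(tr, aois, pre_onset_window_ms, center_frac)$valid
    }, logical(1))
    inc <- include_infant(val, min_valid_trials)
    qc_rows[[id]] <- tibble::tibble(infant_id = id, n_trials = length(val),
                                    n_valid = inc$n_valid,
                                    included = inc$included)
    if (!inc$included) next
    valid_ids <- as.integer(names(by_trial))[val]
    splits[[id]] <- list(by_trial = by_trial, valid_ids = valid_ids)
    for (tid in valid_ids) {
      tr <- by_trial[[as.character(tid)]]
      courses[[length(courses) + 1L]] <-
        lateralization_timecourse(tr, aois, t_end = end_ms,
                                  source = timecourse_source)
      course_inf <- c(course_inf, id)
    }
  }
  included_ids <- names(by_inf)[vapply(qc_rows[names(by_inf)],
                                       function(q) q$included, logical(1))]
  if (length(included_ids) < 2L) {
    stop("fewer than 2 included infants; cannot run the window analysis")
  }

  grid <- attr(courses[[1L]], "time_ms")
  lat <- build_lateralization_matrix(do.call(rbind, courses), course_inf,
                                     time_ms = grid)
  pw <- pointwise_test(lat, mu0 = mu0, alpha = alpha)
  window <- find_window(pw, end_ms = end_ms)
  if (!window$found) {
    if (window_fallback == "none") stop("no sustained analysis window found")
    window$start_ms <- 0
  }

  age_of <- function(id) {
    if (!is.null(meta) && "age_months" %in% names(meta)) {
      a <- meta$age_months[meta$infant_id == id]
      if (length(a)) return(a[1L])
    }
    NA_real_
  }

  for (id in included_ids) {
    sp <- splits[[id]]
    rows <- lapply(sp$valid_ids, function(tid) {
      tr <- sp$by_trial[[as.character(tid)]]
      tr <- tr[order(tr$rel_ms), , drop = FALSE]
      tr$time_ms <- tr$rel_ms
      fx <- idt_fixations(tr, aois = aois)
      info <- trials_tbl[trials_tbl$trial_id == tid, , drop = FALSE]
      m <- trial_metrics(fx, info$correct_side[1L], window)
      c(list(infant_id = id, trial_id = tid, word = info$word[1L],
             correct_image = info$correct_image[1L], woman = info$woman[1L],
             correct_side = info$correct_side[1L]),
        as.list(m))
    })
    tm <- tibble::new_tibble(
      lapply(stats::setNames(nm = names(rows[[1L]])), function(f) {
        unlist(lapply(rows, `[[`, f), use.names = FALSE)
      }), nrow = length(rows))
    metr_rows[[id]] <- tm
    inf_rows[[id]] <- suppressWarnings(
      infant_summary(tm, id, age_of(id))
    )
  }
  trial_metrics_tbl <- do.call(rbind, metr_rows)
  infants <- do.call(rbind, inf_rows)

  fam <- NULL
  fam_samples <- samples[samples$phase == "familiarization" &
                           samples$infant_id %in% included_ids, , drop = FALSE]
  if (!is.null(stream) && nrow(fam_samples) > 0L) {
    fam <- do.call(rbind, lapply(split(fam_samples, fam_samples$infant_id),
      function(fs) {
        s <- familiarization_summary(fs, stream, aois)
        tibble::tibble(infant_id = fs$infant_id[1L], tlt_pct = s$tlt_pct,
                       eyes_pct = s$eyes_pct, mouth_pct = s$mouth_pct)
      }))
    infants <- merge(infants, fam, by = "infant_id", all.x = TRUE)
    infants <- tibble::as_tibble(infants)
  }

  stats_out <- experiment_stats(infants)

  structure(list(qc = do.call(rbind, qc_rows), window = window,
                 lat_matrix = lat, trial_metrics = trial_metrics_tbl,
                 infants = infants, stats = stats_out,
                 familiarization = fam),
            class = "experiment_analysis")
}

# Group-level tests on the per-infant summaries of one experiment.
experiment_stats <- function(infants) {
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  one <- function(col) safe(one_sample_test(infants[[col]], mu0 = 0.5))
  fg_counts <- c(correct = sum(infants$mean_fg > 0.5, na.rm = TRUE),
                 incorrect = sum(infants$mean_fg < 0.5, na.rm = TRUE))
  list(
    paired_tlt = safe(paired_test(infants$mean_tlt_correct_ms,
                                  infants$mean_tlt_incorrect_ms)),
    tlt_p = one("mean_tlt_p"),
    tlt_acc = one("mean_tlt_acc"),
    lf_p = one("mean_lf_p"),
    lf_acc = one("mean_lf_acc"),
    fg = one("mean_fg"),
    fg_chi2 = if (all(fg_counts > 0)) {
      # small cohorts trip the chi-square approximation warning; the test is
      # reported as a descriptive companion to the t-test either way
      safe(suppressWarnings(chi_square_test(fg_counts)))
    } else NULL,
    normality = lapply(stats::setNames(nm = c("mean_tlt_p", "mean_tlt_acc",
                                              "mean_lf_p", "mean_lf_acc")),
                       function(col) safe(normality_check(infants[[col]]))),
    n = nrow(infants)
  )
}

#' @export
print.experiment_analysis <- function(x, ...) {
  cat("<experiment_analysis>", nrow(x$infants), "included infants,",
      sum(x$qc$n_valid[x$qc$included]), "valid trials\n")
  if (x$window$found) {
    cat("  analysis window:", x$window$start_ms, "-", x$window$end_ms, "ms\n")
  } else {
    cat("  no sustained window; full 0 -", x$window$end_ms, "ms used\n")
  }
  s <- x$stats$tlt_p
  if (!is.null(s)) {
    cat(sprintf("  TLT-p vs 0.5: mean %.3f, t(%d) = %.3f, p = %.4f, d = %.3f\n",
                s$mean, s$df, s$t, s$p, s$d))
  }
  invisible(x)
}

#' Simulate and analyse one full synthetic experiment
#'
#' Convenience wrapper: builds (or takes) a design, simulates a cohort with a
#' given ground-truth preference, and runs [analyze_experiment()].
#'
#' @param n_infants Number of infants.
#' @param theta Ground-truth preference for the correct image.
#' @param harmony,cued_role Design of the cued words (see [make_words()]).
#' @param seed Integer seed (drives design, schedule and cohort).
#' @param profile Template [infant_profile()].
#' @param phases Phases to simulate (default test only).
#' @param ... Passed to [analyze_experiment()].
#' @return The `experiment_analysis`, with the simulation `truth` attached.
#' @export
simulate_experiment <- function(n_infants = 23, theta = 0.5,
                                harmony = "vowel", cued_role = "action",
                                seed = NULL, profile = infant_profile(),
                                phases = "test", ...) {
  if (!is.null(seed)) set.seed(seed)
  words <- make_words(harmony, cued_role)
  config <- design_config(words = words)
  schedule <- build_test_trials(config)
  aois <- aoi_config()
  stream <- NULL
  if ("familiarization" %in% phases) {
    stream <- schedule_stream(build_familiarization_sequence(config), config)
  }
  sim <- simulate_cohort(n_infants, schedule, stream = stream, aois = aois,
                         profile = profile, theta = theta, phases = phases)
  res <- analyze_experiment(sim$samples, schedule, aois, meta = sim$truth,
                            stream = stream, ...)
  attr(res, "truth") <- sim$truth
  res
}

#' Cross-experiment analysis
#'
#' Pools the per-infant summaries of several experiments (labelled by the
#' type of phonemic cue and the type of evaluated word) and runs, per metric,
#' the two-way between-subjects ANOVA with partial eta squared, the ANCOVA
#' with age, and the Pearson correlations with age.
#'
#' @param infants Combined infant-summary tibble with `cue` and `word_type`
#'   columns (and `age_months` for the ANCOVA/correlations).
#' @param metrics Metric columns to analyse.
#' @return A list with `anova` (named list of tibbles), `ancova`,
#'   `correlations_age`.
#' @export
cross_experiment_analysis <- function(infants,
                                      metrics = c("mean_tlt_p", "mean_tlt_acc",
                                                  "mean_lf_p", "mean_lf_acc")) {
  anovas <- lapply(stats::setNames(nm = metrics), function(m) {
    two_way_anova(infants, m)
  })
  ancovas <- NULL
  cors <- NULL
  if ("age_months" %in% names(infants) && any(!is.na(infants$age_months))) {
    ancovas <- lapply(stats::setNames(nm = metrics), function(m) {
      ancova_test(infants, m)
    })
    cors <- metric_correlations(infants, "age_months", metrics)
  }
  list(anova = anovas, ancova = ancovas, correlations_age = cors)
}
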