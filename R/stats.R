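#' One-sample t-test with Cohen's d
#'
#' Two-sided one-sample t-test of `values` against `mu0` (default 0.5, the
#' chance level for the looking-proportion metrics), with
#' `d = (mean - mu0) / sd`, which equals `t / sqrt(n)`.
#'
#' @param values Numeric vector, `NA`s dropped, n >= 2 with positive variance.
#' @param mu0 Null value (default 0.5).
#' @return A list: `t`, `df`, `p`, `d`, `mean`, `sd`, `n`.
#' @export
one_sample_test <- function(values, mu0 = 0.5) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) stop("need at least 2 values")
  if (stats::sd(x) == 0) stop("zero variance: one-sample t-test undefined")
  ht <- stats::t.test(x, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d = (mean(x) - mu0) / stats::sd(x),
       mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Cohen's d from a printed one-sample t statistic
#'
#' The identity `d = t / sqrt(n)` for a one-sample t-test.
#'
#' @param t t statistic.
#' @param n Sample size.
#' @return Cohen's d.
#' @examples
#' cohens_d_from_t(2.389, 23)
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test (e.g. total looking time to the correct versus the
#' incorrect image). `d_method = "diff_sd"` (default) divides the mean
#' difference by the SD of the differences; `"avg_sd"` divides it by the mean
#' of the two group SDs.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @param d_method Effect-size convention.
#' @return A list: `t`, `df`, `p`, `d`, `mean_x`, `mean_y`, `n`.
#' @export
paired_test <- function(x, y, d_method = c("diff_sd", "avg_sd")) {
  d_method <- match.arg(d_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 pairs")
  diffs <- x - y
  if (stats::sd(diffs) == 0) stop("zero variance of differences: paired t-test undefined")
  ht <- stats::t.test(x, y, paired = TRUE)
  d <- if (d_method == "diff_sd") mean(diffs) / stats::sd(diffs)
       else mean(diffs) / mean(c(stats::sd(x), stats::sd(y)))
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       d = d, mean_x = mean(x), mean_y = mean(y), n = length(x))
}

anova_table <- function(fit, effects) {
  tab <- tryCatch(car::Anova(fit, type = 2), error = function(e) {
    if (!grepl("residual sum of squares is 0", conditionMessage(e))) stop(e)
    NULL
  })
  if (is.null(tab)) {
    # degenerate fit (zero residual variance): fall back to sequential SS;
    # terms with zero SS carry no effect (F = 0), saturated terms F = Inf
    seq_tab <- suppressWarnings(stats::anova(fit))
    err_df <- seq_tab["Residuals", "Df"]
    rows <- setdiff(rownames(seq_tab), "Residuals")
    ss <- seq_tab[rows, "Sum Sq"]
    tol <- 1e-10 * max(ss, 1)
    return(tibble::tibble(effect = rows, ss = ss, df = seq_tab[rows, "Df"],
                          F = ifelse(ss <= tol, 0, Inf),
                          p = ifelse(ss <= tol, 1, 0),
                          partial_eta_sq = ifelse(ss <= tol, 0, 1),
                          error_df = err_df, error_ss = 0))
  }
  err_ss <- tab["Residuals", "Sum Sq"]
  err_df <- tab["Residuals", "Df"]
  rows <- setdiff(rownames(tab), "Residuals")
  ss <- tab[rows, "Sum Sq"]
  df <- tab[rows, "Df"]
  f <- tab[rows, "F value"]
  p <- tab[rows, "Pr(>F)"]
  # all-identical responses: 0/0 F ratios are reported as 0 (no effect)
  degenerate <- ss == 0
  f[degenerate] <- 0
  p[degenerate] <- 1
  pes <- ifelse(ss + err_ss > 0, ss / (ss + err_ss), 0)
  tibble::tibble(effect = rows, ss = ss, df = df, F = f, p = p,
                 partial_eta_sq = pes, error_df = err_df, error_ss = err_ss)
}

#' Two-way between-subjects ANOVA with partial eta squared
#'
#' Fits `dv ~ f1 * f2` on infant-level summaries pooled across experiments
#' (factors: type of phonemic cue and type of evaluated word) and reports
#' Type-II sums of squares (the convention for unbalanced cross-experiment
#' group sizes; `ss_type = 3` is available), F, p and partial eta squared
#' `SS_effect / (SS_effect + SS_error)` per effect.
#'
#' @param data Data frame of infant summaries.
#' @param dv Name of the dependent variable column.
#' @param f1,f2 Names of the two between-subject factor columns.
#' @param ss_type 2 (default) or 3.
#' @return A tibble with one row per effect (`f1`, `f2`, interaction):
#'   `effect`, `ss`, `df`, `F`, `p`, `partial_eta_sq`, `error_df`.
#' @export
two_way_anova <- function(data, dv, f1 = "cue", f2 = "word_type", ss_type = 2) {
  data <- as.data.frame(data)
  data[[f1]] <- factor(data[[f1]])
  data[[f2]] <- factor(data[[f2]])
  data <- data[!is.na(data[[dv]]), , drop = FALSE]
  cells <- table(data[[f1]], data[[f2]])
  if (any(cells == 0)) stop("empty design cell")
  fml <- stats::reformulate(sprintf("%s * %s", f1, f2), response = dv)
  if (ss_type == 3) {
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
    fit <- stats::lm(fml, data = data)
    tab <- car::Anova(fit, type = 3)
    tab <- tab[setdiff(rownames(tab), "(Intercept)"), , drop = FALSE]
    err_ss <- tab["Residuals", "Sum Sq"]; err_df <- tab["Residuals", "Df"]
    rows <- setdiff(rownames(tab), "Residuals")
    out <- tibble::tibble(effect = rows, ss = tab[rows, "Sum Sq"],
                          df = tab[rows, "Df"], F = tab[rows, "F value"],
                          p = tab[rows, "Pr(>F)"],
                          partial_eta_sq = tab[rows, "Sum Sq"] /
                            (tab[rows, "Sum Sq"] + err_ss),
                          error_df = err_df, error_ss = err_ss)
    degenerate <- out$ss == 0
    out$F[degenerate] <- 0
    out$p[degenerate] <- 1
    return(out)
  }
  fit <- stats::lm(fml, data = data)
  anova_table(fit, c(f1, f2))
}

#' ANCOVA: factor effects adjusted for a covariate
#'
#' Linear-model ANCOVA `dv ~ covariate + f1 * f2` with Type-II sums of
#' squares: the factor effects are those of [two_way_anova()] adjusted for
#' the covariate (typically age in months). A constant covariate falls back
#' to the plain ANOVA with a warning.
#'
#' @inheritParams two_way_anova
#' @param covariate Name of the numeric covariate column.
#' @return A tibble as in [two_way_anova()], with an extra row for the
#'   covariate.
#' @export
ancova_test <- function(data, dv, covariate = "age_months",
                        f1 = "cue", f2 = "word_type") {
  data <- as.data.frame(data)
  data <- data[!is.na(data[[dv]]) & !is.na(data[[covariate]]), , drop = FALSE]
  if (length(unique(data[[covariate]])) < 2L) {
    warning("constant covariate: falling back to ANOVA")
    return(two_way_anova(data, dv, f1, f2))
  }
  data[[f1]] <- factor(data[[f1]])
  data[[f2]] <- factor(data[[f2]])
  cells <- table(data[[f1]], data[[f2]])
  if (any(cells == 0)) stop("empty design cell")
  fml <- stats::reformulate(sprintf("%s + %s * %s", covariate, f1, f2),
                            response = dv)
  fit <- stats::lm(fml, data = data)
  anova_table(fit, c(covariate, f1, f2))
}

#' Pearson correlations of infant metrics with a covariate
#'
#' Standard Pearson r with two-sided p for each metric column against `x`
#' (age, familiarization engagement, or number of valid trials). Zero
#' variance in either variable yields `NA` with a warning.
#'
#' @param data Data frame of infant summaries.
#' @param x Name of the covariate column.
#' @param metrics Character vector of metric column names.
#' @return A tibble: `metric`, `r`, `p`, `n`.
#' @export
metric_correlations <- function(data, x,
                                metrics = c("mean_tlt_p", "mean_tlt_acc",
                                            "mean_lf_p", "mean_lf_acc",
                                            "mean_fg")) {
  data <- as.data.frame(data)
  rows <- lapply(metrics, function(m) {
    keep <- !is.na(data[[x]]) & !is.na(data[[m]])
    xv <- data[[x]][keep]; yv <- data[[m]][keep]
    if (length(xv) < 3L || stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      warning(sprintf("correlation of %s with %s undefined", m, x))
      return(tibble::tibble(metric = m, r = NA_real_, p = NA_real_,
                            n = length(xv)))
    }
    ct <- stats::cor.test(xv, yv)
    tibble::tibble(metric = m, r = unname(ct$estimate), p = ct$p.value,
                   n = length(xv))
  })
  do.call(rbind, rows)
}

#' Multiple-comparison adjustment
#'
#' Holm step-down by default (Bonferroni and others via `method`); adjusted
#' p values are monotone and never smaller than the raw ones.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param method Passed to [stats::p.adjust()] (default `"holm"`).
#' @return Adjusted p values.
#' @export
multiple_comparison_adjust <- function(p, method = "holm") {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = method)
}

#' Shapiro-Wilk normality check
#'
#' Diagnostic only: recorded in reports, never used to gate the t-tests.
#'
#' @param values Numeric vector (n >= 3).
#' @return A list: `statistic`, `p`, `degenerate` (TRUE when the test is
#'   undefined, e.g. constant input).
#' @export
normality_check <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3L) stop("need at least 3 values")
  if (stats::sd(x) == 0) {
    warning("constant input: normality test undefined")
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::shapiro.test(x)
  list(statistic = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Pearson chi-square test on binary counts
#'
#' Goodness of fit of a 1 x 2 count vector against given proportions
#' (default 50:50, e.g. first-gaze counts), or independence in a 2 x 2
#' table. No continuity correction by default.
#'
#' @param counts Length-2 vector or 2 x 2 matrix of counts.
#' @param p Null proportions for the goodness-of-fit case (default 0.5/0.5).
#' @param correct Continuity correction (default `FALSE`).
#' @return A list: `chi2`, `df`, `p`.
#' @export
chi_square_test <- function(counts, p = c(0.5, 0.5), correct = FALSE) {
  if (is.matrix(counts)) {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(expected <= 0)) stop("zero expected count")
    ht <- stats::chisq.test(counts, correct = correct)
  } else {
    stopifnot(length(counts) == 2L)
    if (any(sum(counts) * p <= 0)) stop("zero expected count")
    ht <- stats::chisq.test(counts, p = p, correct = correct)
  }
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Per-item preference checks
#'
#' Guards against item-driven preferences: for each counterbalanced grouping
#' (tested word, woman, gesture, word-image pair), compares a looking metric
#' between the two item levels within infants (paired t-test on per-infant
#' item means) and Holm-adjusts across groupings. Groupings without two
#' levels are skipped with a warning.
#'
#' @param trials Data frame with one row per valid trial: `infant_id`, the
#'   metric column, and one column per grouping.
#' @param metric Metric column name (default `"tlt_p"`).
#' @param groupings Character vector of grouping column names present in
#'   `trials`.
#' @return A tibble: `grouping`, `level_1`, `level_2`, `t`, `df`, `p`,
#'   `p_adj`, `n_infants`.
#' @export
item_preference_check <- function(trials, metric = "tlt_p",
                                  groupings = c("word", "woman")) {
  trials <- as.data.frame(trials)
  rows <- list()
  for (g in groupings) {
    lev <- sort(unique(stats::na.omit(trials[[g]])))
    if (length(lev) < 2L) {
      warning(sprintf("grouping '%s' has fewer than 2 levels; skipped", g))
      next
    }
    if (length(lev) > 2L) {
      warning(sprintf("grouping '%s' has more than 2 levels; skipped", g))
      next
    }
    per <- stats::aggregate(trials[[metric]],
                            by = list(infant = trials$infant_id,
                                      level = trials[[g]]),
                            FUN = mean, na.rm = TRUE)
    wide <- stats::reshape(per, idvar = "infant", timevar = "level",
                           direction = "wide")
    a <- wide[[paste0("x.", lev[1])]]
    b <- wide[[paste0("x.", lev[2])]]
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 2L || stats::sd(a[keep] - b[keep]) == 0) {
      warning(sprintf("grouping '%s': not enough paired data; skipped", g))
      next
    }
    pt <- paired_test(a[keep], b[keep])
    rows[[g]] <- tibble::tibble(grouping = g, level_1 = as.character(lev[1]),
                                level_2 = as.character(lev[2]),
                                t = pt$t, df = pt$df, p = pt$p,
                                n_infants = pt$n)
  }
  if (!length(rows)) {
    return(tibble::tibble(grouping = character(0), level_1 = character(0),
                          level_2 = character(0), t = numeric(0),
                          df = numeric(0), p = numeric(0),
                          p_adj = numeric(0), n_infants = integer(0)))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- multiple_comparison_adjust(out$p)
  out[, c("grouping", "level_1", "level_2", "t", "df", "p", "p_adj",
          "n_infants")]
}
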