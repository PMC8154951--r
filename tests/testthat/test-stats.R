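test_that("one-sample t and Cohen's d match the closed-form oracle", {
  x <- c(0.6, 0.55, 0.65, 0.6)
  res <- one_sample_test(x, mu0 = 0.5)
  o <- oracle_t(x, 0.5)
  expect_equal(res$t, o$t, tolerance = 1e-12)
  expect_equal(res$t, 4.899, tolerance = 1e-3)
  expect_equal(res$df, 3)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  expect_equal(res$d, res$t / sqrt(4), tolerance = 1e-12)
  expect_error(one_sample_test(rep(0.5, 10)), "zero variance")
  expect_error(one_sample_test(0.6), "at least 2")
})

test_that("d = t/sqrt(n) reproduces printed effect-size pairs to two decimals", {
  expect_equal(round(cohens_d_from_t(2.389, 23), 2), 0.50)
  expect_equal(round(cohens_d_from_t(3.607, 21), 2), 0.79)
  expect_equal(round(cohens_d_from_t(2.694, 23), 2), 0.56)
  expect_equal(round(cohens_d_from_t(2.336, 23), 2), 0.49)
})

test_that("paired t matches the oracle, negates under swap, and rejects degeneracy", {
  x <- c(2, 3, 4); y <- c(1, 1, 2)
  res <- paired_test(x, y)
  o <- oracle_t(x - y, 0)
  expect_equal(res$t, 5, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  swapped <- paired_test(y, x)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_error(paired_test(x, x), "zero variance")
  expect_error(paired_test(x, y[1:2]), "equal length")
  # both d conventions
  expect_equal(res$d, mean(x - y) / sd(x - y), tolerance = 1e-12)
  d2 <- paired_test(x, y, d_method = "avg_sd")$d
  expect_equal(d2, mean(x - y) / mean(c(sd(x), sd(y))), tolerance = 1e-12)
})

test_that("the two-way ANOVA reproduces the unbalanced-design error df", {
  set.seed(51)
  sizes <- c(23, 21, 20, 23)
  grid <- expand.grid(cue = c("vowel", "consonant"),
                      word_type = c("action", "object"))
  df <- do.call(rbind, lapply(1:4, function(g) {
    data.frame(cue = grid$cue[g], word_type = grid$word_type[g],
               mean_tlt_p = rnorm(sizes[g], 0.55, 0.1))
  }))
  res <- two_way_anova(df, "mean_tlt_p")
  expect_equal(unique(res$error_df), 83)      # 87 - 4 cells
  expect_equal(res$df, c(1, 1, 1))
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
})

test_that("ANOVA detects a pure main effect and stays silent on null interactions", {
  set.seed(52)
  n <- 40
  df <- expand.grid(cue = rep(c("vowel", "consonant"), each = n / 2),
                    word_type = c("action", "object"))
  df$dv <- 0.5 + 0.1 * (df$cue == "vowel") + rnorm(nrow(df), 0, 0.02)
  res <- two_way_anova(df, "dv")
  expect_lt(res$p[res$effect == "cue"], 1e-6)
  expect_gt(res$p[grepl(":", res$effect)], 0.001)
  expect_gt(res$partial_eta_sq[res$effect == "cue"], 0.5)
  # identical values -> all F reported as 0
  df$dv <- 0.5
  res0 <- two_way_anova(df, "dv")
  expect_true(all(res0$F == 0))
  # empty cell errors
  expect_error(two_way_anova(df[df$cue == "vowel" | df$word_type == "action", ],
                             "dv"), "empty")
})

test_that("Type-II ANOVA matches car::Anova on an unbalanced fixture", {
  set.seed(53)
  df <- data.frame(cue = sample(c("a", "b"), 50, TRUE),
                   word_type = sample(c("x", "y"), 50, TRUE),
                   dv = rnorm(50))
  res <- two_way_anova(df, "dv")
  fit <- lm(dv ~ cue * word_type,
            data = transform(df, cue = factor(cue), word_type = factor(word_type)))
  ref <- car::Anova(fit, type = 2)
  expect_equal(res$F, ref[1:3, "F value"], tolerance = 1e-10)
  expect_equal(res$p, ref[1:3, "Pr(>F)"], tolerance = 1e-10)
})

test_that("ANCOVA adjusts for the covariate sensibly", {
  set.seed(54)
  n <- 60
  df <- data.frame(cue = rep(c("vowel", "consonant"), each = n / 2),
                   word_type = rep(c("action", "object"), n / 2),
                   age_months = rnorm(n, 8, 0.3))
  # covariate uncorrelated with dv: ANCOVA ~ ANOVA
  df$dv <- 0.5 + 0.08 * (df$cue == "vowel") + rnorm(n, 0, 0.05)
  a1 <- two_way_anova(df, "dv")
  a2 <- ancova_test(df, "dv")
  f1 <- a1$F[a1$effect == "cue"]
  f2 <- a2$F[a2$effect == "cue"]
  expect_lt(abs(f1 - f2) / f1, 0.25)
  # dv identical to the covariate: factor effects vanish after adjustment
  df$dv <- df$age_months
  a3 <- ancova_test(df, "dv")
  expect_lt(max(a3$F[a3$effect != "age_months"]), 1e-10)
  # constant covariate falls back to ANOVA
  df$age_months <- 8
  df$dv <- 0.5 + 0.08 * (df$cue == "vowel") + rnorm(n, 0, 0.05)
  expect_warning(a4 <- ancova_test(df, "dv"), "constant covariate")
  expect_false("age_months" %in% a4$effect)
})

test_that("orthogonal covariates leave the balanced-design effect SS unchanged", {
  set.seed(55)
  n <- 32
  df <- expand.grid(cue = c("a", "b"), word_type = c("x", "y"))[rep(1:4, n / 4), ]
  df$dv <- rnorm(n)
  cue_num <- as.numeric(df$cue == "a") - 0.5
  cov_raw <- rnorm(n)
  X <- model.matrix(~ factor(cue) * factor(word_type), transform(df, cue = df$cue))
  df$age_months <- residuals(lm(cov_raw ~ X - 1))   # orthogonal to the design
  a <- two_way_anova(df, "dv")
  b <- ancova_test(df, "dv")
  for (eff in a$effect) {
    expect_equal(b$ss[b$effect == eff], a$ss[a$effect == eff], tolerance = 1e-8)
  }
})

test_that("correlations recover exact and null relationships", {
  df <- data.frame(age_months = 1:10, mean_tlt_p = 2 * (1:10) + 3)
  res <- metric_correlations(df, "age_months", "mean_tlt_p")
  expect_equal(res$r, 1, tolerance = 1e-12)
  # null calibration: shuffled pairs reject at about the nominal rate
  set.seed(56)
  n_rej <- 0
  for (i in 1:200) {
    d2 <- data.frame(age_months = rnorm(30), mean_tlt_p = rnorm(30))
    r <- metric_correlations(d2, "age_months", "mean_tlt_p")
    n_rej <- n_rej + (r$p < 0.05)
  }
  expect_gt(n_rej, 2)
  expect_lt(n_rej, 24)  # 99% band around 10 of 200
  # zero variance warns and returns NA
  d3 <- data.frame(age_months = rep(8, 5), mean_tlt_p = rnorm(5))
  expect_warning(r3 <- metric_correlations(d3, "age_months", "mean_tlt_p"),
                 "undefined")
  expect_true(is.na(r3$r))
})

test_that("a constructed cohort with true rho recovers it within the 95% CI", {
  set.seed(57)
  rho <- 0.336
  n <- 43
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  df <- data.frame(age_months = x, mean_tlt_p = y)
  res <- metric_correlations(df, "age_months", "mean_tlt_p")
  ci <- cor.test(x, y)$conf.int
  expect_gte(res$r, ci[1])
  expect_lte(res$r, ci[2])
  expect_equal(res$n, 43)
})

test_that("Holm adjustment matches the hand calculation and its invariants", {
  expect_equal(multiple_comparison_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(multiple_comparison_adjust(0.03), 0.03)
  expect_equal(multiple_comparison_adjust(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.02, 0.04, 0.3)
  adj <- multiple_comparison_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(multiple_comparison_adjust(c(0.5, 1.5)))
})

test_that("normality diagnostics behave across distributions", {
  set.seed(58)
  # normal draws: rejection near the nominal rate over replicates
  rej <- mean(replicate(100, normality_check(rnorm(50))$p < 0.05))
  expect_lt(rej, 0.15)
  # two-point mass: decisively non-normal
  expect_lt(normality_check(sample(c(0, 1), 50, TRUE))$p, 0.01)
  expect_warning(res <- normality_check(rep(1, 10)), "constant")
  expect_true(res$degenerate)
  expect_error(normality_check(c(1, 2)), "at least 3")
})

test_that("chi-square handles goodness-of-fit, hand values and degenerate tables", {
  even <- chi_square_test(c(12, 12))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  skew <- chi_square_test(c(20, 4))
  expect_equal(skew$chi2, (20 - 12)^2 / 12 + (4 - 12)^2 / 12, tolerance = 1e-12)
  expect_equal(skew$df, 1)
  expect_error(chi_square_test(c(5, 3), p = c(1, 0)), "zero expected")
  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(chi_square_test(tab)$df, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "zero expected")
})

test_that("item-preference checks flag planted item effects and pass neutral ones", {
  set.seed(59)
  mk_trials <- function(bias_word = 0) {
    do.call(rbind, lapply(sprintf("i%02d", 1:20), function(id) {
      n <- 8
      word <- sample(rep(c("w1", "w2"), n / 2))
      woman <- sample(rep(c("A", "B"), n / 2))
      tlt_p <- pmin(pmax(rnorm(n, 0.5 + bias_word * (word == "w1"), 0.15), 0), 1)
      data.frame(infant_id = id, word = word, woman = woman, tlt_p = tlt_p)
    }))
  }
  neutral <- item_preference_check(mk_trials(0))
  expect_equal(nrow(neutral), 2)
  expect_true(all(neutral$p_adj > 0.05))
  biased <- item_preference_check(mk_trials(0.3))
  expect_lt(biased$p_adj[biased$grouping == "word"], 0.01)
  # single-level grouping is skipped with a warning
  tr <- mk_trials(0)
  tr$word <- "w1"
  expect_warning(res <- item_preference_check(tr, groupings = c("word", "woman")),
                 "fewer than 2")
  expect_equal(res$grouping, "woman")
})
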