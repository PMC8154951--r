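# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use brute-force / closed-form routes distinct from the
# package implementation.

default_words <- function() make_words("vowel", "action", seed = 7)

default_design <- function() design_config(words = default_words())

default_schedule <- function(seed = 5) build_test_trials(default_design(), seed = seed)

# Exhaustive-window I-DT oracle: at each start index of a gap-free valid run,
# find the largest window whose dispersion (recomputed from scratch with
# range()) stays within the threshold; accept if it reaches the minimum
# length, else advance by one sample.
oracle_idt <- function(samples, dispersion_px = 30, min_duration_ms = 100,
                       period_ms = 20) {
  v <- as.logical(samples$valid) & !is.na(samples$x_px) & !is.na(samples$y_px)
  k <- ceiling(min_duration_ms / period_ms)
  run <- cumsum(!v | c(TRUE, diff(samples$time_ms) != period_ms))
  out <- NULL
  for (rid in unique(run[v])) {
    idx <- which(v & run == rid)
    i <- 1L
    n <- length(idx)
    disp <- function(a, b) {
      sel <- idx[a:b]
      diff(range(samples$x_px[sel])) + diff(range(samples$y_px[sel]))
    }
    while (i + k - 1L <= n) {
      j <- i + k - 1L
      if (disp(i, j) <= dispersion_px) {
        while (j + 1L <= n && disp(i, j + 1L) <= dispersion_px) j <- j + 1L
        sel <- idx[i:j]
        out <- rbind(out, data.frame(
          onset_ms = samples$time_ms[sel[1]],
          offset_ms = samples$time_ms[sel[length(sel)]] + period_ms,
          n_samples = length(sel),
          x_px = mean(samples$x_px[sel]),
          y_px = mean(samples$y_px[sel])))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out
}

# Random-walk gaze trace for I-DT equivalence checks.
random_walk_trace <- function(n = 600, step_sd = 5, jump_p = 0.03) {
  x <- numeric(n); y <- numeric(n)
  x[1] <- 512; y[1] <- 384
  for (i in 2:n) {
    if (runif(1) < jump_p) {
      x[i] <- runif(1, 50, 950); y[i] <- runif(1, 50, 700)
    } else {
      x[i] <- x[i - 1] + rnorm(1, 0, step_sd)
      y[i] <- y[i - 1] + rnorm(1, 0, step_sd)
    }
  }
  data.frame(time_ms = seq(0, by = 20, length.out = n),
             x_px = pmin(pmax(x, 0), 1023), y_px = pmin(pmax(y, 0), 767),
             valid = TRUE)
}

# Closed-form one-sample t (right tail optional).
oracle_t <- function(x, mu0, right = FALSE) {
  n <- length(x)
  t <- (mean(x) - mu0) / (sd(x) / sqrt(n))
  p <- if (right) pt(t, n - 1, lower.tail = FALSE) else 2 * pt(-abs(t), n - 1)
  list(t = t, df = n - 1, p = p)
}

# Circular word-transition counts of an event sequence.
circular_transitions <- function(words) {
  table(factor(words), factor(c(words[-1], words[1])))
}
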