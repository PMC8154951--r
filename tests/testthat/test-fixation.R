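make_trace <- function(xs, ys, t0 = 0, valid = TRUE) {
  data.frame(time_ms = seq(t0, by = 20, length.out = length(xs)),
             x_px = xs, y_px = ys, valid = valid)
}

test_that("a zero-dispersion trace yields one fixation with exact centroid and duration", {
  s <- make_trace(rep(500, 10), rep(400, 10))
  fx <- idt_fixations(s)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$x_px, 500)
  expect_equal(fx$y_px, 400)
  expect_equal(fx$duration_ms, 200)
  expect_equal(fx$n_samples, 10)
  expect_equal(fx$onset_ms, 0)
  expect_equal(fx$offset_ms, 200)
})

test_that("a large positional jump forces a split into two fixations", {
  s <- make_trace(c(rep(500, 5), rep(900, 5)), rep(400, 10))
  fx <- idt_fixations(s)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$duration_ms, c(100, 100))
  expect_equal(fx$x_px, c(500, 900))
})

test_that("sub-threshold traces shorter than the minimum duration yield nothing", {
  s <- make_trace(rep(500, 4), rep(400, 4))
  expect_equal(nrow(idt_fixations(s)), 0)
  expect_equal(nrow(idt_fixations(s[0, ])), 0)
  s$valid <- FALSE
  expect_equal(nrow(idt_fixations(s)), 0)
})

test_that("package I-DT equals the exhaustive-window oracle on random-walk traces", {
  set.seed(101)
  for (rep in 1:25) {
    s <- random_walk_trace(300)
    fx <- idt_fixations(s, bridge = FALSE)
    or <- oracle_idt(s)
    if (is.null(or)) {
      expect_equal(nrow(fx), 0)
    } else {
      expect_equal(nrow(fx), nrow(or))
      expect_equal(fx$onset_ms, or$onset_ms)
      expect_equal(fx$offset_ms, or$offset_ms)
      expect_equal(fx$x_px, or$x_px)
      expect_equal(fx$n_samples, or$n_samples)
    }
  }
})

test_that("I-DT is invariant to translation and every fixation meets the minimum length", {
  set.seed(7)
  s <- random_walk_trace(400)
  fx <- idt_fixations(s, bridge = FALSE)
  s2 <- s
  s2$x_px <- s2$x_px - 200
  s2$y_px <- s2$y_px + 50
  fx2 <- idt_fixations(s2, bridge = FALSE)
  expect_equal(fx2$onset_ms, fx$onset_ms)
  expect_equal(fx2$x_px, fx$x_px - 200)
  expect_true(all(fx$n_samples >= ceiling(100 / 20)))
  # maximality: extending any fixation by its next sample violates the bound
  for (r in seq_len(nrow(fx))) {
    i0 <- match(fx$onset_ms[r], s$time_ms)
    i1 <- i0 + fx$n_samples[r] - 1L
    if (i1 + 1 <= nrow(s)) {
      sel <- i0:(i1 + 1)
      disp <- diff(range(s$x_px[sel])) + diff(range(s$y_px[sel]))
      expect_gt(disp, 30)
    }
  }
})

test_that("single invalid samples are bridged; longer gaps split windows", {
  xs <- rep(500, 11); ys <- rep(400, 11)
  s <- make_trace(xs, ys)
  s$valid[6] <- FALSE
  s$x_px[6] <- NA
  fx <- idt_fixations(s)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$n_samples, 11)
  # bridging off: the gap splits the run into two 5-sample fixations
  fx0 <- idt_fixations(s, bridge = FALSE)
  expect_equal(nrow(fx0), 2)
  # a two-sample gap always splits
  s2 <- make_trace(rep(500, 12), rep(400, 12))
  s2$valid[6:7] <- FALSE
  fx2 <- idt_fixations(s2)
  expect_equal(nrow(fx2), 2)
})

test_that("AOI assignment follows the half-open rectangle convention", {
  aois <- aoi_config()
  expect_equal(assign_aoi(190, 384, aois), "left")
  expect_equal(assign_aoi(800, 384, aois), "right")
  expect_equal(assign_aoi(512, 384, aois), "center")
  expect_equal(assign_aoi(512, 100, aois), "center")
  # boundary x = 380 belongs to center, not left (half-open)
  expect_equal(assign_aoi(380, 384, aois), "center")
  expect_equal(assign_aoi(379.999, 384, aois), "left")
  expect_equal(assign_aoi(100, 50, aois), "outside")
  expect_equal(assign_aoi(NA, 50, aois), "outside")
  expect_equal(assign_aoi(c(190, 800), c(384, 384), aois), c("left", "right"))
})

test_that("overlapping primary AOIs are rejected at configuration time", {
  expect_error(aoi_config(left = c(0, 209, 500, 559)), "overlap")
  expect_error(aoi_config(left = c(-5, 209, 380, 559)), "screen")
  expect_error(aoi_config(left = c(100, 209, 50, 559)), "x0 < x1")
})

test_that("AOI label frequencies of uniform points match rectangle areas", {
  set.seed(11)
  aois <- aoi_config()
  n <- 4000
  x <- runif(n, 0, 1024); y <- runif(n, 0, 768)
  lab <- assign_aoi(x, y, aois)
  areas <- c(left = 380 * 350, right = 380 * 350, center = 264 * 768)
  for (nm in names(areas)) {
    p <- areas[[nm]] / (1024 * 768)
    expect_lt(abs(mean(lab == nm) - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("the lateralization timecourse codes lateral gaze 1 and everything else 0", {
  aois <- aoi_config()
  grid <- seq(-500, 4700, 20)
  # all-centre trial
  s <- data.frame(rel_ms = grid, x_px = 512, y_px = 384, valid = TRUE)
  v <- lateralization_timecourse(s, aois)
  expect_equal(sum(v), 0)
  expect_length(v, length(grid))
  # step onto the left image at 1000 ms
  s2 <- s
  s2$x_px[grid >= 1000] <- 190
  v2 <- lateralization_timecourse(s2, aois)
  expect_equal(unname(v2[grid < 1000]), rep(0, sum(grid < 1000)))
  expect_equal(unname(v2[grid >= 1000]), rep(1, sum(grid >= 1000)))
  # invalid samples are 0 even at lateral coordinates (no bridging here: run)
  s3 <- s2
  s3$valid[grid >= 3000] <- FALSE
  v3 <- lateralization_timecourse(s3, aois, bridge = FALSE)
  expect_equal(sum(v3[grid >= 3000]), 0)
  # missing time points are 0
  v4 <- lateralization_timecourse(s2[grid <= 2000, ], aois)
  expect_equal(sum(v4[grid > 2000]), 0)
})

test_that("the timecourse matches the simulator's known occupancy schedule", {
  aois <- aoi_config()
  set.seed(3)
  sch <- default_schedule()
  p <- infant_profile(p_invalid_trial = 0, p_missing_sample = 0,
                      refixation_rate = 0, preference_theta = 1,
                      center_latency_meanlog = log(1000),
                      center_latency_sdlog = 0)
  tr <- simulate_trial(p, sch$trials[1, ], aois)
  v <- lateralization_timecourse(tr, aois)
  grid <- attr(v, "time_ms")
  # before onset the gaze is centred; after latency + transit it is lateral
  expect_equal(sum(v[grid < 1000]), 0)
  expect_equal(unname(v[grid >= 1040]), rep(1, sum(grid >= 1040)))
})
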