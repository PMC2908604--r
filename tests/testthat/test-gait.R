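make_events <- function(td, lo, limb = "left_fore") {
  gait_events(data.frame(limb = limb,
                         event = c(rep("touch_down", length(td)),
                                   rep("lift_off", length(lo))),
                         frame = c(td, lo)))
}

test_that("stride segmentation counts cycles and zeroes translations", {
  set.seed(401)
  n <- 91
  vals <- cbind(4 + cumsum(stats::rnorm(n, 0, 0.05)),
                stats::rnorm(n), stats::rnorm(n),
                matrix(stats::rnorm(3 * n, 0, 10), n))
  ser <- one_segment_series(vals, "scapula")
  ev <- make_events(td = c(0, 40, 88), lo = c(25, 65))
  cyc <- segment_strides(ser, ev)
  expect_length(cyc, 2)  # 3 touch downs -> 2 strides
  for (cy in cyc) {
    m <- ps_segment_matrices(cy$series)$scapula
    expect_equal(unname(m[1, c("tx", "ty", "tz")]), c(0, 0, 0))
    # rotations untouched at touch down
    expect_equal(unname(m[1, "rx"]), vals[cy$td_frame + 1, 4])
  }
  # lift off before its touch down -> inconsistent ordering is rejected
  expect_error(gait_events(data.frame(limb = "l",
    event = c("lift_off", "touch_down"), frame = c(5, 10))), "alternate")
})

test_that("inclusion filters keep closed-band interior and log rejections", {
  mk <- function(speed, sym) structure(list(speed_ms = speed, symmetry = sym),
                                       class = "stride_cycle")
  res <- filter_strides(list(mk(0.25, 0.5), mk(0.25, 0.35), mk(0.31, 0.5),
                             mk(0.2, 0.4), mk(0.3, 0.6)))
  expect_length(res$kept, 3)  # interior point and both band edges kept
  expect_equal(res$rejections$reason, c("symmetry", "speed"))
  expect_equal(res$rejections$stride, c(2L, 3L))
})

test_that("time normalization is exact on constants, ramps and endpoints", {
  n <- 121
  ramp <- seq(0, 12, length.out = n)
  vals <- cbind(ramp, 0, 0, 5, 0, 0)
  ser <- one_segment_series(vals, "seg")
  ev <- make_events(td = c(0, 120), lo = 60)
  cy <- segment_strides(ser, ev)[[1]]
  tn <- time_normalize(cy)
  expect_equal(dim(tn), c(100L, 6L))
  expect_equal(unname(tn[, "seg.rx"]), rep(5, 100))   # constant -> constant
  contact <- tn[1:50, "seg.tx"]
  expect_equal(unname(contact), seq(0, ramp[61], length.out = 50))
  expect_equal(unname(tn[1, "seg.tx"]), 0)            # touch-down value
  expect_equal(unname(tn[50, "seg.tx"]), ramp[61])    # lift-off value
  expect_equal(unname(tn[100, "seg.tx"]), ramp[121])  # cycle end
})

test_that("time normalization recovers an analytic sinusoid", {
  fps <- 300
  f <- function(t) 10 * sin(2 * pi * t / 0.9)
  t <- seq(0, 0.9, by = 1 / fps)
  vals <- cbind(0, 0, 0, f(t), 0, 0)
  ser <- one_segment_series(vals, "seg", fps = fps)
  lo <- 150L
  ev <- make_events(td = c(0, length(t) - 1L), lo = lo)
  cy <- segment_strides(ser, ev)[[1]]
  tn <- time_normalize(cy)
  t_contact <- seq(0, lo / fps, length.out = 50)
  t_swing <- seq(lo / fps, 0.9, length.out = 51)[-1]
  expect_lt(max(abs(tn[, "seg.rx"] - f(c(t_contact, t_swing)))), 1e-3)
})

test_that("normalization is idempotent on an already-normalized cycle", {
  set.seed(402)
  # the 50+50 grid itself: 49 contact intervals, then 50 swing intervals
  # whose samples sit at frames 50..99
  n <- 100
  vals <- cbind(cumsum(stats::rnorm(n, 0, .1)), 0, 0,
                cumsum(stats::rnorm(n, 0, 1)), 0, 0)
  vals[1, c(1, 2, 3)] <- 0
  ser <- one_segment_series(vals, "seg")
  ev <- make_events(td = c(0, 99), lo = 49)
  cy <- segment_strides(ser, ev)[[1]]
  tn <- time_normalize(cy)
  expect_equal(unname(tn[, "seg.rx"]), vals[, 4], tolerance = 1e-10)
})

test_that("pooling is permutation-invariant and degenerate-safe", {
  set.seed(403)
  traces <- replicate(5, {
    m <- matrix(stats::rnorm(300), 100, 3,
                dimnames = list(NULL, c("a.tx", "a.ty", "a.rz")))
    attr(m, "contact_samples") <- 50L
    m
  }, simplify = FALSE)
  p1 <- pool_strides(traces)
  p2 <- pool_strides(rev(traces))
  expect_equal(p1$mean, p2$mean)
  expect_equal(p1$sd, p2$sd)
  # identical trials: zero s.d. everywhere
  p3 <- pool_strides(traces[c(1, 1, 1)])
  expect_equal(max(abs(p3$sd)), 0)
  expect_error(pool_strides(traces[1]), "at least 2")
})

test_that("endpoint summaries implement the printed amplitude arithmetic", {
  # two-trial toy: endpoint means drive contact amplitude, full-cycle
  # excursion drives maximal amplitude
  base <- matrix(0, 100, 1, dimnames = list(NULL, "scapula.rz"))
  tr1 <- base; tr1[, 1] <- seq(73.7, 37.3, length.out = 100)
  tr2 <- base; tr2[, 1] <- seq(69.7, 41.3, length.out = 100)
  tr1[1, 1] <- 73.7; tr2[1, 1] <- 69.7
  # force the sample-50 values to the printed lift-off means
  tr1[50, 1] <- 41.3; tr2[50, 1] <- 37.3
  for (m in list(tr1, tr2)) attr(m, "contact_samples") <- 50L
  attr(tr1, "contact_samples") <- attr(tr2, "contact_samples") <- 50L
  es <- endpoint_summary(pool_strides(list(tr1, tr2)))
  expect_equal(es$td_mean, 71.7)
  expect_equal(es$lo_mean, 39.3)
  expect_equal(es$contact_amplitude, abs(39.3 - 71.7))
  expect_gte(es$max_amplitude, es$contact_amplitude)
})

test_that("individual comparison reproduces a hand-computed t-test", {
  got <- compare_individuals(c(1, 2, 3), c(2, 3, 4))
  # pooled s^2 = 1, t = -1 / sqrt(2/3)
  expect_equal(got$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * stats::pt(-1 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(compare_individuals(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_error(compare_individuals(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_individuals(1, c(1, 2)), "n >= 2")
})

test_that("the t-test holds its nominal type-I error at the study sizes", {
  set.seed(404)
  # the two study animals: n = 18 and n = 14, equal means, printed s.d.
  rej <- mean(replicate(2000, {
    compare_individuals(stats::rnorm(18, 57.4, 4.8),
                        stats::rnorm(14, 57.4, 4.9))$p < 0.05
  }))
  expect_gt(rej, 0.035); expect_lt(rej, 0.065)
})

test_that("repeatability summaries recover injected digitization noise", {
  reps <- as.data.frame(matrix(2, 10, 6,
    dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))))
  rs <- repeatability_summary(reps)
  expect_equal(rs$sd, rep(0, 6))
  expect_equal(rs$mean, rep(2, 6))
  set.seed(405)
  reps$tx <- -0.43 + stats::rnorm(10, 0, 0.13)
  rs <- repeatability_summary(reps)
  # chi-square bounds on a sample s.d. at n = 10, alpha = 0.01
  lo <- 0.13 * sqrt(stats::qchisq(0.005, 9) / 9)
  hi <- 0.13 * sqrt(stats::qchisq(0.995, 9) / 9)
  expect_gt(rs$sd_raw[1], lo); expect_lt(rs$sd_raw[1], hi)
  expect_equal(rs$mean[1], round(mean(reps$tx), 1))  # reported to 0.1
  expect_error(repeatability_summary(reps[, -1]), "missing DOF")
  expect_error(repeatability_summary(reps[1, ]), "n >= 2")
})
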