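test_that("three-point curvature matches the circumradius oracle", {
  expect_equal(three_point_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  # circle of radius 2 about the origin
  expect_equal(abs(three_point_curvature(c(-2, 0), c(0, 2), c(2, 0))), 0.5)

  set.seed(42)
  for (i in 1:1000) {
    A <- runif(2, -10, 10); B <- runif(2, -10, 10); C <- runif(2, -10, 10)
    area2 <- abs((A[1] - B[1]) * (C[2] - B[2]) -
                   (A[2] - B[2]) * (C[1] - B[1]))
    if (area2 < 1e-6) next
    k_pkg <- abs(three_point_curvature(A, B, C))
    k_orc <- circumradius_curvature(A, B, C)
    expect_lt(abs(k_pkg - k_orc) / k_orc, 1e-9)
  }
  expect_error(three_point_curvature(c(0, 0), c(0, 0), c(1, 1)),
               "coincident")
})

test_that("curvature is rigid-motion invariant and scales as 1/s", {
  set.seed(7)
  for (i in 1:50) {
    A <- runif(2); B <- runif(2) + c(2, 0); C <- runif(2) + c(4, 1)
    th <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- runif(2, -5, 5)
    rot <- function(p) as.vector(Rm %*% p + shift)
    expect_equal(abs(three_point_curvature(rot(A), rot(B), rot(C))),
                 abs(three_point_curvature(A, B, C)), tolerance = 1e-9)
    s <- runif(1, 0.5, 4)
    expect_equal(three_point_curvature(s * A, s * B, s * C),
                 three_point_curvature(A, B, C) / s, tolerance = 1e-9)
  }
})

test_that("bending angle follows the signed three-point geometry", {
  mk <- function(p1, p2, p3) midline_track(
    0, lapply(list(bodypart1 = p1, bodypart2 = p2, bodypart3 = p3),
              function(p) data.frame(x = p[1], y = p[2], likelihood = 1)),
    fps = 1)
  # collinear -> 0
  expect_equal(bending_angle(mk(c(0, 0), c(1, 0), c(2, 0)))$angle_deg, 0)
  # right-angle bend, magnitude 90, sign by the left-positive convention
  a <- bending_angle(mk(c(0, 0), c(1, 0), c(1, 1)))$angle_deg
  expect_equal(abs(a), 90)
  # mirror flip about the body axis negates the angle
  b <- bending_angle(mk(c(0, 0), c(1, 0), c(1, -1)))$angle_deg
  expect_equal(b, -a)
  # angle is scale-invariant
  d <- bending_angle(mk(c(0, 0), c(3, 0), c(3, 3)))$angle_deg
  expect_equal(d, a)
  # low-likelihood frames are flagged invalid
  trk <- mk(c(0, 0), c(1, 0), c(1, 1))
  trk$parts$bodypart2$likelihood <- 0.5
  res <- bending_angle(trk)
  expect_false(res$valid)
  expect_true(is.na(res$angle_deg))
})

test_that("bout segmentation separates flicks from swimming", {
  fps <- 200
  tt <- seq(0, 10, by = 1 / fps)
  # one left-sided pulse
  x <- numeric(length(tt))
  x[tt >= 2 & tt <= 2.4] <- 30 * sin(pi * (tt[tt >= 2 & tt <= 2.4] - 2) / 0.4)
  bouts <- segment_bouts(data.frame(time_s = tt, angle_deg = x))
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$type, "lETF")

  # 5 s sinusoid at 9.7 Hz -> one swim bout of ~5 s
  x <- numeric(length(tt))
  sel <- tt >= 3 & tt <= 8
  x[sel] <- 25 * sin(2 * pi * 9.7 * (tt[sel] - 3))
  bouts <- segment_bouts(data.frame(time_s = tt, angle_deg = x))
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$type, "swim")
  expect_lt(abs(bouts$duration - 5), 0.3)

  # flat signal -> nothing
  none <- segment_bouts(data.frame(time_s = tt,
                                   angle_deg = numeric(length(tt))))
  expect_equal(nrow(none), 0)
})

test_that("bout boundaries are recovered from simulated tracks", {
  plan <- data.frame(type = c("rETF", "swim"), start = c(1, 4),
                     duration = c(0.4, 3), frequency = c(NA, 7.2))
  trk <- simulate_tail(plan, fps = 200, rng_seed = 8)
  bouts <- segment_bouts(bending_angle(trk))
  expect_equal(nrow(bouts), 2)
  expect_equal(bouts$type, c("rETF", "swim"))
  two_frames <- 2 / 200
  expect_lt(abs(bouts$t_start[1] - 1), 0.1 + two_frames)
  expect_lt(abs(bouts$t_end[2] - 7), 0.25 + two_frames)
  expect_lt(abs(bouts$beat_frequency[2] - 7.2), 0.5)
})

test_that("beat frequency comes from hysteresis zero crossings", {
  fps <- 200
  tt <- seq(0, 2, by = 1 / fps)
  x <- 20 * sin(2 * pi * 10 * tt)
  ang <- data.frame(time_s = tt, angle_deg = x)
  bf <- beat_frequency(list(t_start = 0, t_end = 2), ang)
  expect_lt(abs(bf$frequency_hz - 10), 0.25)

  # noisy slow swimming at the early-stage 4.3 Hz rate
  set.seed(31)
  x <- 20 * sin(2 * pi * 4.3 * tt) + rnorm(length(tt), 0, 2)
  bf <- beat_frequency(list(t_start = 0, t_end = 2),
                       data.frame(time_s = tt, angle_deg = x))
  expect_lt(abs(bf$frequency_hz - 4.3), 0.5)

  # half a cycle has too few reversals
  x <- 20 * sin(pi * tt / 2)
  expect_error(beat_frequency(list(t_start = 0, t_end = 2),
                              data.frame(time_s = tt, angle_deg = x)),
               "reversals")
})

test_that("bouts are assigned to overlapping bursts per channel", {
  mk <- function(on, off, ch) burst_train(ch, data.frame(
    onset_s = on, peak_s = (on + off) / 2, offset_s = off,
    duration_s = off - on, peak_dff = 1, is_long = FALSE,
    truncated = FALSE))
  trains <- list(L = mk(10, 20, "L"), R = mk(50, 60, "R"))
  bouts <- data.frame(type = c("lETF", "swim", "rETF"),
                      t_start = c(12, 54, 80), t_end = c(13, 56, 81),
                      duration = 1, beat_frequency = NA, peak_abs_bend = 20)
  cc <- cooccurrence(bouts, trains, max_lag = 2)
  expect_equal(as.character(cc$assignments$category),
               c("L_only", "R_only", "neither"))

  # synchronized bursts containing a bout -> "both"
  trains2 <- list(L = mk(10, 20, "L"), R = mk(11, 21, "R"))
  cc2 <- cooccurrence(bouts[1, ], trains2, max_lag = 2)
  expect_equal(as.character(cc2$assignments$category), "both")

  # no bursts at all -> everything "neither"
  empty <- burst_train("L", data.frame(
    onset_s = numeric(0), peak_s = numeric(0), offset_s = numeric(0),
    duration_s = numeric(0), peak_dff = numeric(0), is_long = logical(0),
    truncated = logical(0)))
  empty_r <- empty; empty_r$channel <- "R"
  cc3 <- cooccurrence(bouts, list(L = empty, R = empty_r))
  expect_true(all(cc3$assignments$category == "neither"))
})
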