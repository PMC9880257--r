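test_that("phase defaults encode the documented interval/coupling regimes", {
  expect_equal(phase_defaults("VI")$mean_interval, 85)
  expect_equal(phase_defaults("V")$mean_interval, 55)
  expect_equal(phase_defaults("III")$mean_interval, 40)
  expect_equal(phase_defaults("III")$coupling_prob, 0)
  expect_equal(phase_defaults("V")$coupling_prob, 1)
  expect_equal(phase_defaults("V")$sync_jitter_sd, 0.5)
  expect_gt(phase_defaults("VI")$long_burst_prob, 0)
  expect_error(phase_defaults("VIII"), "unknown phase")
})

test_that("phase_params enforces its invariants", {
  expect_error(phase_params("X", mean_interval = -1, interval_cv = 0.1,
                            coupling_prob = 0), "mean_interval")
  expect_error(phase_params("X", mean_interval = 40, interval_cv = 0.1,
                            coupling_prob = 1.5), "coupling_prob")
  expect_error(phase_params("X", mean_interval = 40, interval_cv = 0.1,
                            coupling_prob = 0, long_burst_prob = 0.1,
                            long_burst_duration_range = c(10, 20)),
               "30 s threshold")
})

test_that("fully coupled zero-jitter trains have identical L/R times", {
  p <- phase_params("V", mean_interval = 55, interval_cv = 0.1,
                    coupling_prob = 1, sync_jitter_sd = 0)
  tr <- sample_event_trains(p, span = 2000, rng_seed = 5)
  expect_equal(tr$L$event_times, tr$R$event_times)
})

test_that("uncoupled interval distribution matches the requested mean", {
  p <- phase_params("III", mean_interval = 40, interval_cv = 0.12,
                    coupling_prob = 0)
  tr <- sample_event_trains(p, span = 4000, rng_seed = 11)
  iv <- diff(tr$R$event_times)
  se <- sd(iv) / sqrt(length(iv))
  expect_lt(abs(mean(iv) - 40), 3 * se)
  # left channel runs at the same marginal rate
  expect_lt(abs(length(tr$L$event_times) - length(tr$R$event_times)),
            0.3 * length(tr$R$event_times))
})

test_that("long bursts appear only with positive long_burst_prob", {
  p0 <- phase_params("X", 40, 0.1, 0, long_burst_prob = 0)
  tr0 <- sample_event_trains(p0, span = 3000, rng_seed = 3)
  expect_true(all(tr0$R$event_durations <= 30))
  p1 <- phase_params("X", 85, 0.1, 0, long_burst_prob = 0.5)
  tr1 <- sample_event_trains(p1, span = 3000, rng_seed = 3)
  expect_gt(sum(tr1$R$event_durations > 30), 0)
})

test_that("sampling is deterministic under a fixed seed", {
  a <- sample_event_trains(phase_defaults("IV"), 1000, rng_seed = 42)
  b <- sample_event_trains(phase_defaults("IV"), 1000, rng_seed = 42)
  expect_identical(a, b)
  expect_error(sample_event_trains(phase_defaults("IV"), -5, 1), "span")
})

test_that("noise-free rendering of no events is a flat baseline", {
  tr <- list(L = event_train("L", numeric(0), numeric(0)),
             R = event_train("R", numeric(0), numeric(0)))
  fl <- render_trace(tr, quiet_kernel(baseline = 100), span = 20, rng_seed = 1)
  expect_true(all(fl$channels$L == 100))
  expect_true(all(fl$channels$R == 100))
})

test_that("post-peak decay of a rendered burst follows k_off", {
  k <- quiet_kernel(k_off = 1.1, baseline = 100)
  fl <- render_single_channel(5, 4, span = 40, kernel = k)
  dff <- (fl$channels$L - 100) / 100
  pk <- which.max(dff)
  # fit log-linear decay well past the rise transient
  idx <- which(fl$times >= fl$times[pk] + 2.5 & fl$times <= fl$times[pk] + 5)
  fit <- lm(log(dff[idx]) ~ fl$times[idx])
  expect_lt(abs(-coef(fit)[2] - 1.1) / 1.1, 0.01)
})

test_that("two events 40 s apart render two maxima 40 s apart", {
  fl <- render_single_channel(c(10, 50), c(4, 4), span = 100)
  x <- fl$channels$L
  loc <- which(diff(sign(diff(x))) == -2) + 1
  loc <- loc[x[loc] > 100 * 1.5]
  expect_length(loc, 2)
  expect_lt(abs(diff(fl$times[loc]) - 40), 0.2 + 1e-9)
})

test_that("rendering is additive in the event set at zero noise", {
  kA <- quiet_kernel(baseline = 1)
  a <- render_single_channel(10, 5, span = 120, kernel = kA)
  b <- render_single_channel(c(60, 90), c(4, 35), span = 120, kernel = kA)
  ab <- render_single_channel(c(10, 60, 90), c(5, 4, 35), span = 120,
                              kernel = kA)
  expect_equal((ab$channels$L - 1),
               (a$channels$L - 1) + (b$channels$L - 1), tolerance = 1e-12)
})

test_that("tail simulation produces the planned bout structure", {
  plan <- data.frame(type = "rETF", start = 1, duration = 0.5,
                     frequency = NA)
  trk <- simulate_tail(plan, fps = 200, rng_seed = 2, noise_px = 0)
  ang <- bending_angle(trk)
  moving <- ang$angle_deg[abs(ang$angle_deg) > 1]
  expect_true(all(moving < 0))  # right flicks bend rightward (negative)

  empty <- simulate_tail(plan[0, ], fps = 200, rng_seed = 1, noise_px = 0)
  ang0 <- bending_angle(empty)
  expect_true(all(abs(ang0$angle_deg) < 1e-9))

  overlap <- data.frame(type = c("swim", "rETF"), start = c(0, 2),
                        duration = c(5, 1), frequency = c(5, NA))
  expect_error(simulate_tail(overlap, fps = 200), "overlap")
  expect_error(simulate_tail(plan, fps = 50), "fps")
})

test_that("simulated swim frequency is recovered by the kinematics chain", {
  plan <- data.frame(type = "swim", start = 1, duration = 5,
                     frequency = 9.7)
  trk <- simulate_tail(plan, fps = 200, rng_seed = 4)
  ang <- bending_angle(trk)
  bouts <- segment_bouts(ang)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$type, "swim")
  expect_lt(abs(bouts$beat_frequency - 9.7), 0.5)
})

test_that("cohort laterality follows the binomial model", {
  expect_true(all(simulate_cohort(5, 1, rng_seed = 1)$first_onset == "R"))
  expect_true(all(simulate_cohort(5, 0, rng_seed = 1)$first_onset == "L"))
  co <- simulate_cohort(17000, 13 / 17, rng_seed = 9)
  p <- 13 / 17
  se <- sqrt(p * (1 - p) / 17000)
  expect_lt(abs(mean(co$first_onset == "R") - p), 3 * se)
  expect_error(simulate_cohort(0), "n_embryos")
})

test_that("ground truth events are recovered exactly from noiseless traces", {
  k <- quiet_kernel()
  # the noiseless short-burst kernel peaks at a known offset after onset
  s_star <- k$rise_tau * log(1 + 1 / (k$k_off * k$rise_tau))
  for (ph in c("III", "V", "VI")) {
    p <- phase_defaults(ph)
    span <- 15 * p$mean_interval
    tr <- sample_event_trains(p, span, rng_seed = 31)
    fl <- render_trace(tr, k, span = span, rng_seed = 32)
    det <- detect_pipeline(fl)
    for (ch in c("L", "R")) {
      truth <- tr[[ch]]$event_times
      dur <- tr[[ch]]$event_durations
      keep <- truth > 10 & truth < span - 50
      got <- det[[ch]]$events$peak_s
      got <- got[got > 10 & got < span - 50]
      expect_equal(length(got), sum(keep), info = paste("phase", ph, ch))
      offs <- vapply(which(keep), function(i) {
        min(abs(got - (truth[i] + s_star)))
      }, 1)
      # short transients localize to one frame around the kernel maximum;
      # long plateaus peak a few seconds into the burst
      tol <- ifelse(dur[keep] > 30, 5, 0.2 + 1e-9)
      expect_true(all(offs <= tol), info = paste("phase", ph, ch))
    }
  }
})
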