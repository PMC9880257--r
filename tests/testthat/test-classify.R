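test_that("synchrony matching is greedy, exclusive and tolerance-bound", {
  m <- match_synchronous_bursts(c(0, 40, 80), c(0, 40, 80), tol = 2)
  expect_equal(m$sync_fraction, 1)

  m <- match_synchronous_bursts(c(20, 60), c(0, 40, 80), tol = 2)
  expect_equal(m$sync_fraction, 0)

  m <- match_synchronous_bursts(c(1, 60), c(0, 40, 80), tol = 2)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$t_R, 0)
  expect_equal(m$sync_fraction, 1 / 3)
  expect_error(match_synchronous_bursts(1, 2, tol = 0), "tol")
})

test_that("window features tile correctly and report zero CV when regular", {
  pk <- seq(0, by = 40, length.out = 31)
  mk <- function(pk, ch = "R") burst_train(ch, data.frame(
    onset_s = pk - 1, peak_s = pk, offset_s = pk + 1, duration_s = 2,
    peak_dff = 1, is_long = FALSE, truncated = FALSE))
  f <- window_features(mk(pk + 1, "L"), mk(pk), window_cycles = 10,
                       step_cycles = 10)
  expect_true(all(abs(f$cv_R) < 1e-12))
  expect_equal(f$t_start[-1], f$t_end[-nrow(f)])  # non-overlapping tiling
  # each window holds 11 R peaks and the 10 L partners that fall inside it
  expect_equal(f$sync_fraction, rep(10 / 11, nrow(f)))

  few <- mk(c(0, 40))
  out <- window_features(mk(c(1, 41), "L"), few)
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "flagged"), "too few")
})

test_that("stationary regular generator output has low window CV", {
  hits <- unlist(lapply(1:40, function(s) {
    tr <- sample_event_trains(phase_defaults("III"), span = 1500,
                              rng_seed = s)
    f <- window_features(as_burst_train(tr$L), as_burst_train(tr$R))
    f$cv_R <= 0.25
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("the classification rule table maps features to phases", {
  f <- function(sync, cv, ratio = 1) {
    list(sync_fraction = sync, cv_R = cv, interval_ratio_vs_ref = ratio)
  }
  expect_equal(classify_window(f(1.0, 0.1, 1.0)), "V")
  # the reported 55 -> 85 s lengthening gives ratio ~1.55
  expect_equal(classify_window(f(1.0, 0.1, 1.55)), "VI")
  expect_equal(classify_window(f(0.02, 0.7)), "I")
  expect_equal(classify_window(f(1.0, 0.7)), "VII")
  expect_equal(classify_window(f(0.5, 0.1)), "IV")
  expect_equal(classify_window(f(0.1, 0.1)), "III")
  expect_equal(classify_window(f(0.1, 0.4)), "II")
  expect_equal(classify_window(f(NA, 0.4)), "unclassified")
})

test_that("labels are threshold-monotone in the sync fraction", {
  set.seed(5)
  late <- c("IV", "V", "VI", "VII")
  for (i in 1:200) {
    cv <- runif(1, 0, 0.8)
    ratio <- runif(1, 0.8, 2)
    s1 <- runif(1)
    s2 <- runif(1, s1, 1)
    l1 <- classify_window(list(sync_fraction = s1, cv_R = cv,
                               interval_ratio_vs_ref = ratio))
    l2 <- classify_window(list(sync_fraction = s2, cv_R = cv,
                               interval_ratio_vs_ref = ratio))
    expect_false(l1 %in% late && !(l2 %in% late))
  }
})

test_that("segment smoothing removes blips and can enforce monotone order", {
  feats <- data.frame(t_start = seq(0, 80, by = 20),
                      t_end = seq(20, 100, by = 20),
                      mean_interval_R = 40, cv_R = 0.1, sync_fraction = 1,
                      long_burst_count = 0)
  segs <- smooth_segments(feats, c("V", "V", "IV", "V", "V"))
  expect_equal(segs$label, "V")
  expect_equal(segs$n_windows, 5)
  expect_equal(segs$t_start, 0)
  expect_equal(segs$t_end, 100)

  # idempotent on already-monotone labels
  lab <- c("III", "III", "IV", "IV", "V")
  segs <- smooth_segments(feats, lab)
  expect_equal(segs$label, c("III", "IV", "V"))
  expect_equal(sum(segs$n_windows), 5)
  expect_equal(segs$t_end[-nrow(segs)], segs$t_start[-1])

  # monotone projection maps the backward transition forward
  segs <- smooth_segments(feats, c("IV", "IV", "V", "V", "IV"),
                          monotone = TRUE)
  expect_equal(segs$label[nrow(segs)], "V")
})

test_that("each generated phase is recovered as the modal window label", {
  phases <- c("I", "II", "III", "IV", "V", "VI", "VII")
  for (ph in phases) {
    p <- phase_defaults(ph)
    labs <- unlist(lapply(1:15, function(s) {
      tr <- sample_event_trains(p, span = 25 * p$mean_interval + 100,
                                rng_seed = s)
      f <- window_features(as_burst_train(tr$L), as_burst_train(tr$R),
                           ref_interval = if (ph %in% c("VI", "VII")) 55
                                          else NULL)
      classify_windows(f)
    }))
    modal <- names(sort(table(labs), decreasing = TRUE))[1]
    expect_equal(modal, ph, info = paste("phase", ph))
  }
})

test_that("a staged recording is recovered in order with high accuracy", {
  cc <- concat_phase_trains(seed = 2, cycles = 50)
  f <- window_features(cc$L, cc$R)
  labs <- classify_windows(f)
  tru <- truth_labels(f, cc$truth)
  expect_gte(mean(labs == tru), 0.8)
  segs <- smooth_segments(f, labs, monotone = TRUE)
  # all seven phases appear, in developmental order
  expect_true(all(c("I", "II", "III", "IV", "V", "VI", "VII") %in%
                    segs$label))
  ord <- match(segs$label, c("I", "II", "III", "IV", "V", "VI", "VII"))
  expect_true(all(diff(ord) >= 0))
  # segments tile the analyzed span without overlap
  expect_equal(segs$t_start[-1], segs$t_end[-nrow(segs)])
})

test_that("onset laterality picks the earlier channel and flags ties", {
  mk <- function(pk, ch) burst_train(ch, data.frame(
    onset_s = pk, peak_s = pk, offset_s = pk + 1,
    duration_s = rep(1, length(pk)), peak_dff = rep(1, length(pk)),
    is_long = rep(FALSE, length(pk)), truncated = rep(FALSE, length(pk))))
  expect_equal(onset_laterality(mk(10, "L"), mk(5, "R")), "R")
  expect_equal(onset_laterality(mk(10, "L"), mk(numeric(0), "R")), "L")
  expect_equal(onset_laterality(mk(5.1, "L"), mk(5, "R")), "indeterminate")
  expect_error(onset_laterality(mk(numeric(0), "L"), mk(numeric(0), "R")),
               "no bursts")
})
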