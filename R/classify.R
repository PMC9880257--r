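PHASE_LEVELS <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Classification thresholds for the seven-phase taxonomy
#'
#' The source taxonomy is qualitative ("constant intervals", "rarely
#' synchronizes", "sporadic"); these numeric cut-points are explicit
#' package definitions chosen to separate the reported interval regimes
#' (40 / 55 / 85 s) and coupling regimes with margin.
#'
#' @param cv_regular interval CV at or below which a rhythm counts as
#'   regular (default 0.25).
#' @param cv_sporadic interval CV above which a rhythm counts as sporadic
#'   (default 0.5).
#' @param s_lo,s_hi sync-fraction cut-points separating unsynchronized,
#'   intermittently synchronized, and fully synchronized windows
#'   (defaults 0.2, 0.8).
#' @param r_long interval ratio (current / synchronized-regime reference)
#'   at or above which a fully synchronized regular window counts as the
#'   lengthened-interval phase VI (default 1.3; the reported 55 to 85 s
#'   lengthening gives a ratio of about 1.55).
#' @return named list of thresholds.
#' @export
phase_thresholds <- function(cv_regular = 0.25, cv_sporadic = 0.5,
                             s_lo = 0.2, s_hi = 0.8, r_long = 1.3) {
  stopifnot(cv_regular < cv_sporadic, s_lo < s_hi, r_long > 1)
  list(cv_regular = cv_regular, cv_sporadic = cv_sporadic,
       s_lo = s_lo, s_hi = s_hi, r_long = r_long)
}

#' Match synchronous bursts between the two channels
#'
#' Greedy nearest-neighbor matching of burst peak times: candidate pairs
#' with `|dt| <= tol` are accepted in order of increasing `|dt|`, each
#' burst matched at most once. The sync fraction is the number of matches
#' over the number of right-channel bursts.
#'
#' @param train_L,train_R [burst_train] objects or numeric peak-time
#'   vectors.
#' @param tol matching tolerance in seconds (> 0).
#' @return list with `pairs` (data frame `t_L`, `t_R`, `delta_t`) and
#'   `sync_fraction`.
#' @export
match_synchronous_bursts <- function(train_L, train_R, tol) {
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  tl <- peak_times(train_L)
  tr <- peak_times(train_R)
  empty <- data.frame(t_L = numeric(0), t_R = numeric(0),
                      delta_t = numeric(0))
  if (!length(tl) || !length(tr)) {
    return(list(pairs = empty,
                sync_fraction = if (length(tr)) 0 else NA_real_))
  }
  cand <- expand.grid(i = seq_along(tl), j = seq_along(tr))
  cand$dt <- tl[cand$i] - tr[cand$j]
  cand <- cand[abs(cand$dt) <= tol, , drop = FALSE]
  cand <- cand[order(abs(cand$dt), cand$j), , drop = FALSE]
  used_l <- logical(length(tl))
  used_r <- logical(length(tr))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_l[i] && !used_r[j]) {
      used_l[i] <- used_r[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  list(pairs = data.frame(t_L = tl[pairs$i], t_R = tr[pairs$j],
                          delta_t = pairs$dt),
       sync_fraction = sum(keep) / length(tr))
}

#' Sliding-window feature extraction over the two burst trains
#'
#' Windows span `window_cycles` consecutive right-channel cycles and
#' advance by `step_cycles` cycles. Per window: mean interval and CV per
#' channel, sync fraction (tolerance `max(2 s, 5%` of the window's median
#' right interval)), long-burst count, and the ratio of the window's mean
#' right interval to a reference synchronized-regime interval. The
#' reference defaults to the median right interval of the first window
#' whose sync fraction reaches `s_hi`; recordings that begin after the
#' synchronized regime was established should pass it explicitly.
#'
#' @param train_L,train_R [burst_train] objects.
#' @param window_cycles window length in right-channel cycles (>= 5).
#' @param step_cycles step between window starts, in cycles.
#' @param ref_interval reference synchronized-regime interval, seconds;
#'   `NULL` derives it from the data as described above.
#' @param thresholds a [phase_thresholds()] list (only `s_hi` is used
#'   here).
#' @return data frame of window features (one row per window; zero rows,
#'   with a `flagged` attribute, when there are too few bursts).
#' @export
window_features <- function(train_L, train_R, window_cycles = 10,
                            step_cycles = 2, ref_interval = NULL,
                            thresholds = phase_thresholds()) {
  if (window_cycles < 5) stop("'window_cycles' must be >= 5", call. = FALSE)
  tr <- peak_times(train_R)
  tl <- peak_times(train_L)
  m <- length(tr)
  cols <- c("t_start", "t_end", "mean_interval_L", "mean_interval_R",
            "cv_L", "cv_R", "sync_fraction", "long_burst_count",
            "interval_ratio_vs_ref")
  if (m < window_cycles + 1) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    attr(out, "flagged") <- "too few right-channel bursts for one window"
    return(out)
  }
  starts <- seq(1L, m - window_cycles, by = step_cycles)
  long_peaks <- c(
    if (inherits(train_L, "burst_train"))
      train_L$events$peak_s[train_L$events$is_long],
    if (inherits(train_R, "burst_train"))
      train_R$events$peak_s[train_R$events$is_long])

  rows <- lapply(starts, function(k) {
    t0 <- tr[k]; t1 <- tr[k + window_cycles]
    iv_r <- diff(tr[k:(k + window_cycles)])
    l_in <- tl[tl >= t0 & tl <= t1]
    iv_l <- if (length(l_in) > 1) diff(l_in) else numeric(0)
    tol <- max(2, 0.05 * median(iv_r))
    sync <- match_synchronous_bursts(l_in, tr[k:(k + window_cycles)],
                                     tol)$sync_fraction
    data.frame(
      t_start = t0, t_end = t1,
      mean_interval_L = if (length(iv_l)) mean(iv_l) else NA_real_,
      mean_interval_R = mean(iv_r),
      cv_L = if (length(iv_l) > 1) sd(iv_l) / mean(iv_l) else NA_real_,
      cv_R = if (length(iv_r) > 1) sd(iv_r) / mean(iv_r) else NA_real_,
      sync_fraction = sync,
      long_burst_count = sum(long_peaks >= t0 & long_peaks <= t1),
      interval_ratio_vs_ref = NA_real_
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(ref_interval)) {
    # first sustained fully-synchronized stretch (>= 3 consecutive windows)
    # anchors the reference interval; a lone chance-synchronized window
    # must not. Fall back to the first synchronized window if none.
    sync_ok <- out$sync_fraction >= thresholds$s_hi
    r <- rle(sync_ok)
    run_start <- cumsum(c(1L, r$lengths))[which(r$values & r$lengths >= 3)[1]]
    if (is.na(run_start)) run_start <- which(sync_ok)[1]
    if (!is.na(run_start)) {
      idx <- starts[run_start:min(run_start + 2, length(starts))]
      ref_interval <- median(unlist(lapply(idx, function(k) {
        diff(tr[k:(k + window_cycles)])
      })))
    }
  }
  if (!is.null(ref_interval)) {
    out$interval_ratio_vs_ref <- out$mean_interval_R / ref_interval
  }
  attr(out, "ref_interval") <- ref_interval
  out
}

#' Classify one feature window into a developmental phase
#'
#' Ordered decision list over the window features (first match wins):
#' VII — fully synchronized and sporadic; VI — fully synchronized,
#' regular, lengthened interval; V — fully synchronized and regular;
#' IV — regular with intermittent synchrony; III — regular and
#' unsynchronized; II — intermediate dispersion; I — sporadic. The
#' regularity feature is the right-channel interval CV (the anchoring
#' rhythm). Windows with undefined features return `"unclassified"`.
#'
#' @param f a one-row data frame (or list) of [window_features()] output.
#' @param thresholds a [phase_thresholds()] list.
#' @return a phase label, `"I".."VII"` or `"unclassified"`.
#' @export
classify_window <- function(f, thresholds = phase_thresholds()) {
  cv <- f$cv_R
  sync <- f$sync_fraction
  ratio <- f$interval_ratio_vs_ref
  if (is.null(cv) || is.na(cv) || is.na(sync)) return("unclassified")
  th <- thresholds
  if (sync >= th$s_hi && cv > th$cv_sporadic) return("VII")
  if (sync >= th$s_hi && cv <= th$cv_regular &&
      !is.na(ratio) && ratio >= th$r_long) return("VI")
  if (sync >= th$s_hi && cv <= th$cv_regular) return("V")
  if (cv <= th$cv_regular && sync > th$s_lo && sync < th$s_hi) return("IV")
  if (cv <= th$cv_regular && sync <= th$s_lo) return("III")
  if (cv > th$cv_regular && cv <= th$cv_sporadic) return("II")
  "I"
}

#' Classify every window of a feature table
#'
#' @param features data frame from [window_features()].
#' @param thresholds a [phase_thresholds()] list.
#' @return character vector of labels, one per window.
#' @export
classify_windows <- function(features, thresholds = phase_thresholds()) {
  if (!nrow(features)) return(character(0))
  vapply(seq_len(nrow(features)),
         function(i) classify_window(features[i, ], thresholds),
         character(1))
}

label_mode <- function(labels, center) {
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  if (center %in% winners) center else winners[1]
}

#' Smooth window labels and merge them into phase segments
#'
#' Applies a width-3 mode filter (ties keep the center label), optionally
#' projects the sequence onto the monotone developmental order (any
#' backward transition, other than into `"unclassified"`, is mapped to the
#' previous label), and merges adjacent equal labels into segments that
#' tile the analyzed span. Segment boundaries between consecutive windows
#' are placed at the start of the later window.
#'
#' @param features data frame from [window_features()].
#' @param labels character vector from [classify_windows()].
#' @param monotone logical; apply the monotone projection (default
#'   `FALSE`).
#' @return data frame of segments: `label`, `t_start`, `t_end`,
#'   `n_windows`, `mean_interval_s`, `cv`, `sync_fraction`,
#'   `long_burst_count`.
#' @export
smooth_segments <- function(features, labels, monotone = FALSE) {
  n <- length(labels)
  stopifnot(nrow(features) == n)
  if (n == 0) {
    return(data.frame(label = character(0), t_start = numeric(0),
                      t_end = numeric(0), n_windows = integer(0),
                      mean_interval_s = numeric(0), cv = numeric(0),
                      sync_fraction = numeric(0),
                      long_burst_count = integer(0)))
  }
  sm <- vapply(seq_len(n), function(i) {
    label_mode(labels[max(1, i - 1):min(n, i + 1)], labels[i])
  }, character(1))
  if (monotone && n > 1) {
    for (i in 2:n) {
      if (sm[i] == "unclassified" || sm[i - 1] == "unclassified") next
      if (match(sm[i], PHASE_LEVELS) < match(sm[i - 1], PHASE_LEVELS)) {
        sm[i] <- sm[i - 1]
      }
    }
  }
  run_id <- cumsum(c(1L, as.integer(sm[-1] != sm[-n])))
  segs <- lapply(split(seq_len(n), run_id), function(idx) {
    i0 <- idx[1]; i1 <- idx[length(idx)]
    data.frame(
      label = sm[i0],
      t_start = features$t_start[i0],
      t_end = if (i1 < n) features$t_start[i1 + 1] else features$t_end[i1],
      n_windows = length(idx),
      mean_interval_s = mean(features$mean_interval_R[idx], na.rm = TRUE),
      cv = mean(features$cv_R[idx], na.rm = TRUE),
      sync_fraction = mean(features$sync_fraction[idx], na.rm = TRUE),
      long_burst_count = sum(features$long_burst_count[idx])
    )
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' First-onset laterality of a recording
#'
#' Which channel produced the earliest burst peak. Peaks landing within
#' one frame of each other are indeterminate.
#'
#' @param train_L,train_R [burst_train] objects.
#' @param frame_interval frame interval in seconds used for the tie
#'   window (default 0.2).
#' @return `"L"`, `"R"` or `"indeterminate"`.
#' @export
onset_laterality <- function(train_L, train_R, frame_interval = 0.2) {
  tl <- peak_times(train_L)
  tr <- peak_times(train_R)
  if (!length(tl) && !length(tr)) {
    stop("no bursts in either channel", call. = FALSE)
  }
  if (!length(tl)) return("R")
  if (!length(tr)) return("L")
  if (abs(tl[1] - tr[1]) <= frame_interval) return("indeterminate")
  if (tr[1] < tl[1]) "R" else "L"
}
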