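#' Detected burst train for one channel
#'
#' Container for time-ordered burst events and their derived peak-to-peak
#' intervals. `duration_s = offset_s - onset_s`; `is_long` flags durations
#' above 30 s; `truncated` flags events whose onset or offset ran into a
#' recording boundary (kept, but excluded from duration statistics).
#'
#' @param channel `"L"` or `"R"`.
#' @param events data frame with columns `onset_s`, `peak_s`, `offset_s`,
#'   `duration_s`, `peak_dff`, `is_long`, `truncated`, sorted by `peak_s`.
#' @return object of class `"burst_train"` with derived `intervals`.
#' @export
burst_train <- function(channel, events) {
  channel <- match.arg(channel, c("L", "R"))
  needed <- c("onset_s", "peak_s", "offset_s", "duration_s", "peak_dff",
              "is_long", "truncated")
  miss <- setdiff(needed, names(events))
  if (length(miss)) {
    stop("events lacking column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) > 1 && is.unsorted(events$peak_s, strictly = TRUE)) {
    events <- events[order(events$peak_s), , drop = FALSE]
  }
  with(events, {
    if (any(onset_s > peak_s | peak_s > offset_s)) {
      stop("burst events must satisfy onset <= peak <= offset", call. = FALSE)
    }
  })
  rownames(events) <- NULL
  structure(list(channel = channel,
                 events = events,
                 intervals = if (nrow(events) > 1) diff(events$peak_s)
                             else numeric(0)),
            class = "burst_train")
}

#' @export
print.burst_train <- function(x, ...) {
  cat("<burst_train> channel", x$channel, "-", nrow(x$events), "events")
  if (length(x$intervals)) {
    cat(sprintf(", mean interval %.1f s", mean(x$intervals)))
  }
  cat("\n")
  invisible(x)
}

# strided rolling quantile with linear interpolation between evaluation
# points; partial windows at the edges
rolling_quantile <- function(x, width, q, stride = NULL) {
  n <- length(x)
  if (width >= n) return(rep(quantile(x, q, names = FALSE), n))
  if (is.null(stride)) stride <- max(1L, width %/% 20L)
  h <- width %/% 2L
  centers <- unique(c(seq(1L, n, by = stride), n))
  vals <- vapply(centers, function(i) {
    quantile(x[max(1L, i - h):min(n, i + h)], q, names = FALSE)
  }, numeric(1))
  if (length(centers) == n) return(vals)
  approx(centers, vals, xout = seq_len(n))$y
}

#' Normalize a fluorescence trace to dF/F0
#'
#' Computes \eqn{\Delta F/F_0 = (F - F_0)/F_0} per channel. The default
#' baseline estimator is a rolling 20th-percentile filter, which tracks
#' slow drift while staying below the sparse bursts; alternatives are a
#' single global percentile or a user-supplied constant.
#'
#' @param trace a raw [fluorescence_trace()].
#' @param baseline_method `"rolling_quantile"` (default),
#'   `"global_quantile"`, or `"constant"` (requires `f0`).
#' @param window baseline window length in seconds (rolling method);
#'   should exceed the longest inter-burst interval. Default 120 s.
#' @param q baseline quantile (default 0.2).
#' @param f0 constant baseline value(s) for `baseline_method = "constant"`;
#'   a single number or one per channel.
#' @return a normalized [fluorescence_trace()].
#' @export
compute_dff <- function(trace,
                        baseline_method = c("rolling_quantile",
                                            "global_quantile", "constant"),
                        window = 120, q = 0.2, f0 = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  baseline_method <- match.arg(baseline_method)
  if (trace$normalized) {
    warning("trace is already normalized; returning as-is")
    return(trace)
  }
  width <- max(3L, as.integer(round(window / trace$frame_interval)))
  out <- trace
  for (i in seq_along(trace$channels)) {
    x <- trace$channels[[i]]
    f0_i <- switch(baseline_method,
      rolling_quantile = rolling_quantile(x, width, q),
      global_quantile = rep(quantile(x, q, names = FALSE), length(x)),
      constant = {
        if (is.null(f0)) stop("'f0' required for constant baseline",
                              call. = FALSE)
        rep(if (length(f0) > 1) f0[[i]] else f0, length(x))
      })
    if (any(f0_i <= 0)) {
      stop("baseline F0 is non-positive in channel '",
           names(trace$channels)[i], "'", call. = FALSE)
    }
    out$channels[[i]] <- (x - f0_i) / f0_i
  }
  out$normalized <- TRUE
  out
}

#' Savitzky-Golay denoised derivative of a normalized trace
#'
#' First difference scaled to dF/F0 per second, then smoothed with a
#' Savitzky-Golay filter. On polynomial inputs of degree at most
#' `sg_order` the filter is exact away from the edges, so a linear ramp
#' yields its slope.
#'
#' @param trace a normalized [fluorescence_trace()].
#' @param sg_window filter window in frames (odd, > `sg_order`);
#'   default 7 frames (1.4 s at the 0.2 s frame interval).
#' @param sg_order polynomial order, default 3.
#' @return object of class `"trace_derivative"`: same time grid, one
#'   derivative series per channel (dF/F0 per second).
#' @export
denoised_derivative <- function(trace, sg_window = 7, sg_order = 3) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!trace$normalized) {
    stop("derivative expects a normalized (dF/F0) trace; run compute_dff()",
         call. = FALSE)
  }
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L || sg_window <= sg_order) {
    stop("'sg_window' must be odd and greater than 'sg_order'", call. = FALSE)
  }
  if (sg_window > length(trace$times)) {
    stop("'sg_window' longer than the series", call. = FALSE)
  }
  chans <- lapply(trace$channels, function(x) {
    d <- c(0, diff(x)) / trace$frame_interval
    signal::sgolayfilt(d, p = sg_order, n = sg_window)
  })
  structure(list(times = trace$times, channels = chans,
                 frame_interval = trace$frame_interval,
                 sg_window = sg_window, sg_order = sg_order),
            class = "trace_derivative")
}

# local maxima (strict left, non-strict right) of a numeric vector
local_maxima <- function(d) {
  n <- length(d)
  if (n < 3) return(integer(0))
  which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
}

# topographic prominence of a local maximum: height above the higher of
# the two minima separating it from taller terrain (or the series end)
peak_prominence <- function(d, i) {
  n <- length(d)
  left_min <- d[i]
  j <- i
  while (j > 1 && d[j - 1] <= d[i]) {
    j <- j - 1
    left_min <- min(left_min, d[j])
  }
  right_min <- d[i]
  j <- i
  while (j < n && d[j + 1] <= d[i]) {
    j <- j + 1
    right_min <- min(right_min, d[j])
  }
  d[i] - max(left_min, right_min)
}

# onset/offset indices for a derivative peak at index i, following the
# duration rule: onset where the derivative first rises above 0 before the
# peak; offset where it returns up to 0 after the negative lobe that
# follows the fluorescence maximum. A hysteresis band +/- eps guards
# against noise-split boundaries. Candidate negative lobes must reach
# -lobe_thr, and a lobe only terminates the event if the smoothed trace
# xs has actually fallen back towards the onset baseline at the return
# point -- a sub-threshold dip on a sustained plateau does not end the
# burst. The search stops at the next burst's rise or the trace end.
event_bounds <- function(d, xs, i, eps, lobe_thr, rise_thr) {
  n <- length(d)
  j <- i
  while (j > 1 && d[j - 1] > eps) j <- j - 1
  onset_idx <- j
  trunc_left <- (j == 1 && d[1] > eps)
  base <- xs[onset_idx]

  j <- i
  while (j < n && d[j] > eps) j <- j + 1          # leave the rise lobe
  offset_idx <- n
  trunc_right <- TRUE
  repeat {
    while (j < n && d[j] > -lobe_thr && d[j] < rise_thr) j <- j + 1
    if (j >= n || d[j] >= rise_thr) {             # trace end or next burst
      offset_idx <- j
      trunc_right <- j >= n
      break
    }
    while (j < n) {                               # return to 0, debounced
      nxt <- min(j + 1L, n)
      if (d[j] >= -eps && d[nxt] >= -eps) break
      j <- j + 1
    }
    peak_so_far <- max(xs[onset_idx:j])
    if (j >= n || xs[j] - base < 0.33 * (peak_so_far - base)) {
      offset_idx <- j
      trunc_right <- (j >= n && d[n] < -eps)
      break
    }
  }
  list(onset = onset_idx, offset = offset_idx,
       truncated = trunc_left || trunc_right)
}

#' Detect calcium bursts from a denoised derivative
#'
#' Candidate peaks are local maxima of the denoised differentiated trace
#' whose height and topographic prominence both exceed `prominence_k`
#' times a robust (MAD-based) noise scale. Each accepted peak is expanded
#' to a burst event: onset where the derivative rises from 0 before the
#' peak, offset where it climbs back to 0 after the negative lobe that
#' follows the fluorescence maximum. Events whose peaks fall closer than
#' `min_separation` are merged, keeping the larger peak, the earlier onset
#' and the later offset. `peak_s` is the time of the fluorescence maximum
#' between onset and offset.
#'
#' @param deriv a `"trace_derivative"` from [denoised_derivative()].
#' @param trace the matching normalized [fluorescence_trace()].
#' @param prominence_k detection threshold in units of the robust noise
#'   scale (default 4).
#' @param min_separation minimum peak separation in seconds (default 2).
#' @param channels channels to process (default: all in the trace).
#' @return named list of [burst_train] objects.
#' @export
detect_bursts <- function(deriv, trace, prominence_k = 4,
                          min_separation = 2, channels = NULL) {
  stopifnot(inherits(deriv, "trace_derivative"),
            inherits(trace, "fluorescence_trace"))
  if (length(deriv$times) != length(trace$times)) {
    stop("derivative and trace lengths differ", call. = FALSE)
  }
  if (is.null(channels)) channels <- names(trace$channels)
  out <- lapply(channels, function(ch) {
    detect_bursts_channel(deriv$channels[[ch]], trace$channels[[ch]],
                          trace$times, ch, prominence_k, min_separation,
                          deriv$sg_window, deriv$sg_order)
  })
  names(out) <- channels
  out
}

detect_bursts_channel <- function(d, x, times, channel, prominence_k,
                                  min_separation, sg_window = 7,
                                  sg_order = 3) {
  if (max(abs(d)) == 0) {
    return(burst_train(channel, data.frame(
      onset_s = numeric(0), peak_s = numeric(0), offset_s = numeric(0),
      duration_s = numeric(0), peak_dff = numeric(0), is_long = logical(0),
      truncated = logical(0))))
  }
  sigma <- mad(d)
  if (sigma == 0) sigma <- sd(d)
  # hysteresis floor keeps the offset search from chasing the exponential
  # tail to numerical zero on noiseless traces
  eps <- max(0.1 * sigma, 1e-3 * max(abs(d)))
  thr <- prominence_k * sigma

  cand <- local_maxima(d)
  cand <- cand[d[cand] >= thr]
  cand <- cand[vapply(cand, function(i) peak_prominence(d, i) >= thr,
                      logical(1))]

  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0),
                      peak_dff = numeric(0), is_long = logical(0),
                      truncated = logical(0))
  if (!length(cand)) return(burst_train(channel, empty))

  # peak localization on the SG-smoothed trace: the fluorescence maximum
  # between onset and offset, taken as the first entry into the peak band
  # (within 2 robust noise scales of the window maximum) so that a
  # noise-flattened maximum still yields a stable, reproducible time
  xs <- signal::sgolayfilt(x, p = sg_order, n = sg_window)
  delta <- 2 * mad(x - xs)

  evs <- lapply(cand, function(i) {
    b <- event_bounds(d, xs, i, eps, lobe_thr = thr / 2, rise_thr = thr)
    idx <- b$onset:b$offset
    pk <- idx[which(xs[idx] >= max(xs[idx]) - delta)[1]]
    data.frame(onset_s = times[b$onset], peak_s = times[pk],
               offset_s = times[b$offset],
               duration_s = times[b$offset] - times[b$onset],
               peak_dff = xs[pk],
               is_long = (times[b$offset] - times[b$onset]) >
                 LONG_BURST_THRESHOLD_S,
               truncated = b$truncated)
  })
  evs <- do.call(rbind, evs)
  evs <- evs[order(evs$peak_s), , drop = FALSE]

  # merge peaks closer than min_separation, keeping the larger
  keep <- rep(TRUE, nrow(evs))
  i <- 1L
  while (i < nrow(evs)) {
    nxt <- i + 1L
    while (nxt <= nrow(evs) && !keep[nxt]) nxt <- nxt + 1L
    if (nxt > nrow(evs)) break
    if (keep[i] && evs$peak_s[nxt] - evs$peak_s[i] < min_separation) {
      win <- if (evs$peak_dff[i] >= evs$peak_dff[nxt]) i else nxt
      los <- if (win == i) nxt else i
      evs$onset_s[win] <- min(evs$onset_s[i], evs$onset_s[nxt])
      evs$offset_s[win] <- max(evs$offset_s[i], evs$offset_s[nxt])
      evs$duration_s[win] <- evs$offset_s[win] - evs$onset_s[win]
      evs$is_long[win] <- evs$duration_s[win] > LONG_BURST_THRESHOLD_S
      evs$truncated[win] <- evs$truncated[i] || evs$truncated[nxt]
      keep[los] <- FALSE
      if (win != i) i <- win
    } else {
      i <- nxt
    }
  }
  evs <- evs[keep, , drop = FALSE]
  # duplicates can arise when two derivative peaks map into one burst
  evs <- evs[!duplicated(evs$peak_s), , drop = FALSE]
  burst_train(channel, evs)
}

#' Inter-burst intervals and their summary statistics
#'
#' Intervals are consecutive peak-to-peak differences. With fewer than two
#' events the interval list is empty and the summary statistics are `NA`
#' with `defined = FALSE`.
#'
#' @param train a [burst_train].
#' @return list with `intervals` (seconds), `mean`, `cv`, `n`, `defined`.
#' @export
compute_intervals <- function(train) {
  stopifnot(inherits(train, "burst_train"))
  iv <- train$intervals
  if (length(iv) < 1) {
    return(list(intervals = numeric(0), mean = NA_real_, cv = NA_real_,
                n = 0L, defined = FALSE))
  }
  m <- mean(iv)
  list(intervals = iv, mean = m,
       cv = if (length(iv) > 1) sd(iv) / m else 0,
       n = length(iv), defined = TRUE)
}

#' Convert a ground-truth event train to a burst train
#'
#' Maps generator events onto the detected-burst container, anchoring
#' each event at its onset (`peak_s = onset_s`), the stable timing anchor
#' the detector also targets.
#'
#' @param train an [event_train()].
#' @param peak_dff nominal peak amplitude recorded for each event.
#' @return a [burst_train].
#' @export
as_burst_train <- function(train, peak_dff = 1) {
  stopifnot(inherits(train, "event_train"))
  n <- length(train$event_times)
  burst_train(train$channel, data.frame(
    onset_s = train$event_times,
    peak_s = train$event_times,
    offset_s = train$event_times + train$event_durations,
    duration_s = train$event_durations,
    peak_dff = rep(peak_dff, n),
    is_long = train$event_durations > LONG_BURST_THRESHOLD_S,
    truncated = rep(FALSE, n)
  ))
}
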