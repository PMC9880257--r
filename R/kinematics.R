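#' Signed three-point midline curvature
#'
#' Menger curvature of the triangle through the three midline points:
#' magnitude `4 * Area / (|AB| |BC| |CA|)`, the reciprocal circumradius,
#' with the sign taken from the z-component of the cross product of the
#' vectors from the mid point B to A and to C (left bends positive under
#' the package convention). Collinear points give 0. Units are 1/length
#' in the coordinate units.
#'
#' @param A,B,C planar coordinates: length-2 numeric vectors, or n x 2
#'   matrices for a vectorized call. B is the mid-tail point.
#' @return signed curvature (numeric scalar or vector).
#' @examples
#' three_point_curvature(c(-2, 0), c(0, 2), c(2, 0))  # 0.5 (radius-2 circle)
#' @export
three_point_curvature <- function(A, B, C) {
  to_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 2)
  A <- to_mat(A); B <- to_mat(B); C <- to_mat(C)
  if (!all(is.finite(A), is.finite(B), is.finite(C))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  ab <- sqrt(rowSums((A - B)^2))
  bc <- sqrt(rowSums((B - C)^2))
  ca <- sqrt(rowSums((C - A)^2))
  if (any(ab == 0 | bc == 0 | ca == 0)) {
    stop("coincident points have no defined curvature", call. = FALSE)
  }
  cross_z <- (A[, 1] - B[, 1]) * (C[, 2] - B[, 2]) -
             (A[, 2] - B[, 2]) * (C[, 1] - B[, 1])
  2 * cross_z / (ab * bc * ca)
}

#' Signed tail-bending angle from a midline track
#'
#' Per frame, 180 degrees minus the interior angle at the mid-tail point
#' between the segments towards the ocellus and towards the tail tip,
#' signed like [three_point_curvature()] (left bend positive); a straight
#' tail gives 0. Frames with any body-part likelihood below the threshold,
#' or with coincident points, are flagged invalid (`NA` angle).
#'
#' @param track a [midline_track()].
#' @param likelihood_threshold minimum per-part likelihood for a frame to
#'   be used (default 0.9, the usual pose-tracking convention).
#' @return data frame with `time_s`, `angle_deg`, `valid`.
#' @export
bending_angle <- function(track, likelihood_threshold = 0.9) {
  stopifnot(inherits(track, "midline_track"))
  p1 <- track$parts$bodypart1
  p2 <- track$parts$bodypart2
  p3 <- track$parts$bodypart3
  ok <- p1$likelihood >= likelihood_threshold &
        p2$likelihood >= likelihood_threshold &
        p3$likelihood >= likelihood_threshold

  ba_x <- p1$x - p2$x; ba_y <- p1$y - p2$y
  bc_x <- p3$x - p2$x; bc_y <- p3$y - p2$y
  nba <- sqrt(ba_x^2 + ba_y^2)
  nbc <- sqrt(bc_x^2 + bc_y^2)
  ok <- ok & nba > 0 & nbc > 0
  cosang <- pmin(1, pmax(-1, (ba_x * bc_x + ba_y * bc_y) / (nba * nbc)))
  interior <- acos(cosang) * 180 / pi
  cross_z <- ba_x * bc_y - ba_y * bc_x
  ang <- (180 - interior) * ifelse(cross_z >= 0, 1, -1)
  ang[!ok] <- NA_real_
  data.frame(time_s = track$times, angle_deg = ang, valid = ok)
}

#' Bout-segmentation thresholds
#'
#' @param mad_k movement threshold in multiples of the robust (MAD) scale
#'   of the signal (default 3).
#' @param abs_min_deg absolute floor of the movement threshold, in the
#'   signal's units (default 3; prevents a zero threshold on noiseless
#'   tracks).
#' @param min_duration minimum epoch duration in seconds (default 0.05).
#' @param merge_gap sub-threshold gaps shorter than this (seconds) are
#'   bridged, so an alternating bout is not split at its zero crossings
#'   (default 0.2).
#' @param min_reversals minimum sign reversals for a swim bout (default 3).
#' @param min_alt_freq minimum alternation frequency, Hz, for a swim bout
#'   (default 3).
#' @return named list.
#' @export
bout_thresholds <- function(mad_k = 3, abs_min_deg = 3, min_duration = 0.05,
                            merge_gap = 0.2, min_reversals = 3,
                            min_alt_freq = 3) {
  list(mad_k = mad_k, abs_min_deg = abs_min_deg,
       min_duration = min_duration, merge_gap = merge_gap,
       min_reversals = min_reversals, min_alt_freq = min_alt_freq)
}

# indices of hysteresis sign switches: state flips only when the signal
# exceeds +/- h on the opposite side
sign_switches <- function(x, h) {
  state <- 0L
  idx <- integer(0)
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    s <- if (x[i] > h) 1L else if (x[i] < -h) -1L else 0L
    if (s != 0L && s != state) {
      if (state != 0L) idx <- c(idx, i)
      state <- s
    }
  }
  idx
}

#' Segment a bending series into movement bouts
#'
#' Movement epochs are runs where `|signal|` exceeds the movement
#' threshold (`max(mad_k * MAD, abs_min_deg)`) for at least
#' `min_duration`, after bridging sub-threshold gaps shorter than
#' `merge_gap`. An epoch containing at least `min_reversals` hysteresis
#' sign reversals at an alternation rate of at least `min_alt_freq` is a
#' swim bout (its beat frequency comes from [beat_frequency()]); other
#' epochs are early tail flicks, sided by the sign of their extreme
#' deflection (left/positive = `lETF`).
#'
#' @param angle data frame from [bending_angle()] (or any data frame with
#'   `time_s` and a signal column named `angle_deg` or `curvature`).
#' @param thresholds a [bout_thresholds()] list.
#' @return data frame of bouts: `type`, `t_start`, `t_end`, `duration`,
#'   `beat_frequency` (`NA` for flicks), `peak_abs_bend`.
#' @export
segment_bouts <- function(angle, thresholds = bout_thresholds()) {
  sig_col <- intersect(c("angle_deg", "curvature"), names(angle))[1]
  if (is.na(sig_col)) stop("no signal column found", call. = FALSE)
  x <- angle[[sig_col]]
  tt <- angle$time_s
  dt <- median(diff(tt))
  th <- thresholds
  x0 <- ifelse(is.na(x), 0, x)
  # noise scale of the quiescent baseline: two-pass so that movement
  # epochs themselves do not inflate the threshold
  quiet <- x0[abs(x0) < th$abs_min_deg]
  sigma_q <- if (length(quiet) > 10) mad(quiet) else 0
  thr <- max(th$mad_k * sigma_q, th$abs_min_deg)

  active <- abs(x0) >= thr
  if (!any(active)) {
    return(data.frame(type = character(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      beat_frequency = numeric(0),
                      peak_abs_bend = numeric(0)))
  }
  # bridge short sub-threshold gaps (zero crossings of an alternation)
  gap_frames <- max(1L, as.integer(round(th$merge_gap / dt)))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) &&
        r$lengths[k] <= gap_frames) {
      active[starts[k]:ends[k]] <- TRUE
    }
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & (r$lengths - 1L) * dt >= th$min_duration)

  bouts <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    xw <- x0[idx]
    sw <- sign_switches(xw, thr / 2)
    duration <- tt[ends[k]] - tt[starts[k]]
    n_rev <- length(sw)
    alt_freq <- if (n_rev >= 2) {
      (n_rev - 1) / (2 * (tt[idx[sw[n_rev]]] - tt[idx[sw[1]]]))
    } else 0
    is_swim <- n_rev >= th$min_reversals && alt_freq >= th$min_alt_freq
    type <- if (is_swim) "swim" else if (xw[which.max(abs(xw))] > 0) "lETF"
            else "rETF"
    data.frame(type = type,
               t_start = tt[starts[k]], t_end = tt[ends[k]],
               duration = duration,
               beat_frequency = if (is_swim) alt_freq else NA_real_,
               peak_abs_bend = max(abs(xw)))
  })
  out <- do.call(rbind, bouts)
  rownames(out) <- NULL
  out
}

#' Beat frequency of a swim bout
#'
#' Counts hysteresis zero crossings of the signal inside the bout and
#' converts them to full alternation cycles: with switches at times
#' `t_1..t_k`, the frequency is `(k - 1) / (2 * (t_k - t_1))` Hz (each
#' full cycle crosses zero twice). Requires at least 3 reversals.
#'
#' @param bout one row of [segment_bouts()] output (any list with
#'   `t_start`, `t_end`).
#' @param angle the signal data frame the bout was segmented from.
#' @param hysteresis crossing hysteresis in signal units; defaults to 10%
#'   of the bout's peak deflection.
#' @return list with `frequency_hz` and `n_reversals`.
#' @export
beat_frequency <- function(bout, angle, hysteresis = NULL) {
  sig_col <- intersect(c("angle_deg", "curvature"), names(angle))[1]
  idx <- which(angle$time_s >= bout$t_start & angle$time_s <= bout$t_end)
  x <- angle[[sig_col]][idx]
  x[is.na(x)] <- 0
  if (is.null(hysteresis)) hysteresis <- 0.1 * max(abs(x))
  sw <- sign_switches(x, hysteresis)
  if (length(sw) < 3) {
    stop("not a swim bout: fewer than 3 sign reversals", call. = FALSE)
  }
  tt <- angle$time_s[idx]
  list(frequency_hz = (length(sw) - 1) / (2 * (tt[sw[length(sw)]] - tt[sw[1]])),
       n_reversals = length(sw))
}

#' Co-occurrence of movement bouts and calcium bursts
#'
#' Assigns each bout to the burst windows (onset to offset, widened by
#' `max_lag` on both sides) it overlaps, per channel, and tabulates bout
#' types against the categories `L_only`, `R_only`, `both`, `neither`.
#'
#' @param bouts data frame from [segment_bouts()].
#' @param trains named list of [burst_train] objects (`L`, `R`).
#' @param max_lag tolerance in seconds added around each burst window
#'   (default 2).
#' @return list with `assignments` (per-bout category) and `table`
#'   (bout type x category counts).
#' @export
cooccurrence <- function(bouts, trains, max_lag = 2) {
  overlaps <- function(b, ev) {
    any(b$t_start <= ev$offset_s + max_lag &
        b$t_end >= ev$onset_s - max_lag)
  }
  cat_levels <- c("L_only", "R_only", "both", "neither")
  cats <- vapply(seq_len(nrow(bouts)), function(i) {
    b <- bouts[i, ]
    in_l <- nrow(trains$L$events) > 0 && overlaps(b, trains$L$events)
    in_r <- nrow(trains$R$events) > 0 && overlaps(b, trains$R$events)
    if (in_l && in_r) "both" else if (in_l) "L_only"
    else if (in_r) "R_only" else "neither"
  }, character(1))
  assignments <- cbind(bouts, category = cats)
  tab <- table(factor(bouts$type, levels = c("lETF", "rETF", "swim")),
               factor(cats, levels = cat_levels))
  list(assignments = assignments, table = tab)
}
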