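#' Assign cycle-anchored phase angles to left-channel bursts
#'
#' Anchors each right-channel (MN2R) burst peak at phase 0 degrees and the
#' next right peak at 360 degrees; a left-channel (MN2L) peak at time `t`
#' inside the cycle `[t_i, t_{i+1})` maps to
#' `360 * (t - t_i) / (t_{i+1} - t_i)`, then wraps to the signed interval
#' (-180, 180]. Left peaks before the first or at/after the last right
#' peak fall outside any cycle and are discarded (their count is
#' reported). A left peak exactly at a right peak belongs to the cycle it
#' starts, i.e. phase 0.
#'
#' @param train_L,train_R [burst_train] objects (or numeric vectors of
#'   peak times). `train_R` needs at least 2 events.
#' @param signed wrap angles to (-180, 180] (default); `FALSE` returns
#'   raw [0, 360).
#' @return list with `angles` (degrees), `n`, `n_discarded`.
#' @examples
#' assign_cycle_phases(c(10, 90), c(0, 100))$angles  # 36, -36
#' @export
assign_cycle_phases <- function(train_L, train_R, signed = TRUE) {
  tl <- peak_times(train_L)
  tr <- peak_times(train_R)
  if (length(tr) < 2) {
    stop("need at least 2 right-channel events to define cycles",
         call. = FALSE)
  }
  cyc <- findInterval(tl, tr)           # 0 = before first R peak
  inside <- cyc >= 1 & tl < tr[length(tr)]
  ang <- 360 * (tl[inside] - tr[cyc[inside]]) /
    (tr[cyc[inside] + 1] - tr[cyc[inside]])
  if (signed) ang <- wrap_signed(ang)
  list(angles = ang, n = length(ang), n_discarded = sum(!inside))
}

peak_times <- function(x) {
  if (inherits(x, "burst_train")) x$events$peak_s else as.numeric(x)
}

#' Rayleigh test of circular uniformity
#'
#' Computes the mean resultant vector of the phase angles: its length
#' \eqn{R = |\sum e^{i\theta}| / n} measures concentration (0 = uniform,
#' 1 = fully phase-locked) and its argument is the mean angle. The p-value
#' uses the classical small-sample approximation
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n))} with
#' \eqn{R_n = nR}.
#'
#' @param angles phase angles in degrees (any wrapping).
#' @return object of class `"circular_phase_result"`: `angles`, `n`,
#'   `mean_angle` (degrees in (-180, 180]; `NA` when `R = 0`),
#'   `resultant_R`, `rayleigh_p`.
#' @examples
#' rayleigh_test(c(0, 90))  # R = sqrt(2)/2, mean 45
#' @export
rayleigh_test <- function(angles) {
  angles <- as.numeric(angles)
  n <- length(angles)
  if (n < 1) stop("empty angle list", call. = FALSE)
  th <- angles * pi / 180
  C <- sum(cos(th))
  S <- sum(sin(th))
  Rn <- sqrt(C^2 + S^2)
  R <- Rn / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  structure(list(angles = angles, n = n,
                 mean_angle = if (R > 0) wrap_signed(atan2(S, C) * 180 / pi)
                              else NA_real_,
                 resultant_R = R,
                 rayleigh_p = min(p, 1)),
            class = "circular_phase_result")
}

#' @export
print.circular_phase_result <- function(x, ...) {
  cat(sprintf("<circular_phase_result> n = %d, mean = %s, R = %.3f, p = %.3g\n",
              x$n,
              if (is.na(x$mean_angle)) "undefined"
              else sprintf("%.1f deg", x$mean_angle),
              x$resultant_R, x$rayleigh_p))
  invisible(x)
}

#' Circular histogram of phase angles
#'
#' Bin counts over an equal-width partition of (-180, 180], with
#' right-closed bins, so the counts always sum to the number of angles.
#'
#' @param angles phase angles in degrees.
#' @param n_bins number of bins (>= 2), default 18 (20-degree bins).
#' @return data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
circular_histogram <- function(angles, n_bins = 18) {
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  angles <- wrap_signed(as.numeric(angles))
  breaks <- seq(-180, 180, length.out = n_bins + 1)
  idx <- findInterval(angles, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[angles <= breaks[1]] <- 1L   # unreachable after wrapping; safety
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lo = breaks[-(n_bins + 1)], bin_hi = breaks[-1],
             count = counts)
}
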