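#' Phase parameter set for the synthetic burst generator
#'
#' Bundles the statistical description of one developmental phase of the
#' bilateral MN2 oscillator: marginal inter-burst-interval distribution,
#' left-right coupling, and long-burst occurrence.
#'
#' @param label phase identifier, one of `"I".."VII"` (free-form labels are
#'   allowed for custom regimes).
#' @param mean_interval mean inter-burst interval of the right channel, in
#'   seconds. Must be positive.
#' @param interval_cv coefficient of variation of the interval distribution
#'   (dimensionless, >= 0). Intervals are gamma-distributed with this
#'   mean/CV; `0` gives a strictly periodic train.
#' @param coupling_prob probability in \[0, 1\] that a right-channel event
#'   spawns a synchronous left-channel event. `0` leaves the two channels
#'   as independent renewal processes; `1` makes the left channel a
#'   jittered copy of the right.
#' @param sync_jitter_sd standard deviation (seconds) of the Gaussian
#'   left-right timing jitter applied to coupled events.
#' @param long_burst_prob per-event probability of a long burst
#'   (duration above 30 s).
#' @param long_burst_duration_range length-2 numeric, seconds; long-burst
#'   durations are drawn uniformly in this range. Both ends must exceed the
#'   30 s long-burst threshold.
#' @param short_burst_duration_range length-2 numeric, seconds, for
#'   ordinary bursts.
#' @param onset_drift linear drift of the mean interval over the segment,
#'   seconds of interval per second of elapsed time (0 = stationary).
#'
#' @return an object of class `"phase_params"`.
#' @seealso [phase_defaults()] for the built-in per-phase registry.
#' @export
phase_params <- function(label,
                         mean_interval,
                         interval_cv,
                         coupling_prob,
                         sync_jitter_sd = 0.5,
                         long_burst_prob = 0,
                         long_burst_duration_range = c(31, 45),
                         short_burst_duration_range = c(3, 8),
                         onset_drift = 0) {
  stopifnot(length(label) == 1L)
  if (!is.numeric(mean_interval) || mean_interval <= 0) {
    stop("'mean_interval' must be > 0", call. = FALSE)
  }
  if (interval_cv < 0) stop("'interval_cv' must be >= 0", call. = FALSE)
  if (coupling_prob < 0 || coupling_prob > 1) {
    stop("'coupling_prob' must lie in [0, 1]", call. = FALSE)
  }
  if (sync_jitter_sd < 0) stop("'sync_jitter_sd' must be >= 0", call. = FALSE)
  if (long_burst_prob < 0 || long_burst_prob > 1) {
    stop("'long_burst_prob' must lie in [0, 1]", call. = FALSE)
  }
  if (long_burst_prob > 0 &&
      any(long_burst_duration_range <= LONG_BURST_THRESHOLD_S)) {
    stop("long-burst durations must exceed the 30 s threshold", call. = FALSE)
  }
  structure(
    list(label = as.character(label),
         mean_interval = mean_interval,
         interval_cv = interval_cv,
         coupling_prob = coupling_prob,
         sync_jitter_sd = sync_jitter_sd,
         long_burst_prob = long_burst_prob,
         long_burst_duration_range = as.numeric(long_burst_duration_range),
         short_burst_duration_range = as.numeric(short_burst_duration_range),
         onset_drift = onset_drift),
    class = "phase_params"
  )
}

#' Default generator parameters for developmental phases I-VII
#'
#' Registry of the per-phase regimes the generator emulates. Interval means
#' follow the reported developmental progression: phases II-IV converge on a
#' ~40 s rhythm, phase V runs at ~55 s, phases VI-VII at ~85 s with sporadic
#' long bursts (> 30 s). Coupling goes from independent channels (I-III)
#' through intermittent synchronization (IV) to full synchronization (V-VII).
#' Interval dispersions (CVs), coupling probabilities and jitter are package
#' defaults chosen to reproduce those qualitative regimes; they are not
#' measured quantities.
#'
#' @param label phase identifier `"I".."VII"`.
#' @return a [phase_params()] object.
#' @examples
#' phase_defaults("VI")$mean_interval  # 85
#' phase_defaults("III")$coupling_prob # 0
#' @export
phase_defaults <- function(label) {
  registry <- list(
    I   = list(mean_interval = 40, interval_cv = 0.80, coupling_prob = 0),
    II  = list(mean_interval = 40, interval_cv = 0.35, coupling_prob = 0),
    III = list(mean_interval = 40, interval_cv = 0.12, coupling_prob = 0),
    IV  = list(mean_interval = 40, interval_cv = 0.12, coupling_prob = 0.5),
    V   = list(mean_interval = 55, interval_cv = 0.12, coupling_prob = 1),
    VI  = list(mean_interval = 85, interval_cv = 0.12, coupling_prob = 1,
               long_burst_prob = 0.15),
    VII = list(mean_interval = 85, interval_cv = 0.70, coupling_prob = 1,
               long_burst_prob = 0.15)
  )
  if (!label %in% names(registry)) {
    stop("unknown phase label: '", label, "' (expected I..VII)", call. = FALSE)
  }
  do.call(phase_params, c(list(label = label), registry[[label]]))
}

#' Construct an event train
#'
#' Ground-truth container for one channel's burst events: strictly
#' increasing event times and positive durations.
#'
#' @param channel `"L"` or `"R"`.
#' @param event_times numeric, seconds, strictly increasing.
#' @param event_durations numeric, seconds, same length, all positive.
#' @return object of class `"event_train"`.
#' @export
event_train <- function(channel, event_times, event_durations) {
  channel <- match.arg(channel, c("L", "R"))
  if (length(event_times) != length(event_durations)) {
    stop("times and durations must have equal length", call. = FALSE)
  }
  if (length(event_times) > 1 && any(diff(event_times) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  if (any(event_durations <= 0)) {
    stop("event durations must be positive", call. = FALSE)
  }
  structure(list(channel = channel,
                 event_times = as.numeric(event_times),
                 event_durations = as.numeric(event_durations)),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat("<event_train> channel", x$channel, "-", length(x$event_times),
      "events\n")
  invisible(x)
}

# Draw one renewal train of event times on (0, span), gamma intervals with
# the given mean/CV; the mean may drift linearly over the segment.
draw_renewal_times <- function(mean_interval, cv, span, onset_drift = 0,
                               start_offset = NULL) {
  t <- if (is.null(start_offset)) runif(1, 0, mean_interval) else start_offset
  times <- numeric(0)
  while (t < span) {
    if (t > 0) times <- c(times, t)
    m <- max(mean_interval + onset_drift * t, 1e-3)
    dt <- if (cv <= 0) m else {
      shape <- 1 / cv^2
      rgamma(1, shape = shape, rate = shape / m)
    }
    t <- t + dt
  }
  times
}

# Durations: long bursts with prob long_burst_prob, otherwise short; each
# capped at 80% of the gap to the next event so ground-truth events stay
# resolvable in the rendered trace.
draw_durations <- function(times, params, span) {
  n <- length(times)
  if (n == 0) return(numeric(0))
  is_long <- runif(n) < params$long_burst_prob
  dur <- runif(n, params$short_burst_duration_range[1],
               params$short_burst_duration_range[2])
  if (any(is_long)) {
    dur[is_long] <- runif(sum(is_long), params$long_burst_duration_range[1],
                          params$long_burst_duration_range[2])
  }
  gaps <- c(diff(times), span - times[n])
  pmax(pmin(dur, 0.8 * gaps), 0.5)
}

#' Sample coupled left/right event trains for one phase regime
#'
#' The right channel is a gamma renewal process with the requested
#' mean/CV (optionally drifting). Each right event spawns a coincident
#' left event, jittered by `Normal(0, sync_jitter_sd)`, with probability
#' `coupling_prob`; the remaining left activity is an independent renewal
#' process thinned so the left marginal event rate matches the right.
#'
#' @param params a [phase_params()] object.
#' @param span recording span in seconds (> 0).
#' @param rng_seed integer seed; identical seeds give identical trains.
#' @return list with elements `L` and `R`, both [event_train()] objects.
#' @examples
#' tr <- sample_event_trains(phase_defaults("V"), span = 600, rng_seed = 1)
#' length(tr$R$event_times)
#' @export
sample_event_trains <- function(params, span, rng_seed = NULL) {
  stopifnot(inherits(params, "phase_params"))
  if (!is.numeric(span) || span <= 0) {
    stop("'span' must be positive", call. = FALSE)
  }
  with_seed(rng_seed, {
    r_times <- draw_renewal_times(params$mean_interval, params$interval_cv,
                                  span, params$onset_drift)

    coupled <- if (length(r_times)) {
      runif(length(r_times)) < params$coupling_prob
    } else logical(0)
    l_times <- r_times[coupled] +
      rnorm(sum(coupled), 0, params$sync_jitter_sd)

    if (params$coupling_prob < 1) {
      # independent component at rate (1 - p) / mean keeps the left
      # marginal rate equal to the right
      m_indep <- params$mean_interval / (1 - params$coupling_prob)
      l_times <- c(l_times,
                   draw_renewal_times(m_indep, params$interval_cv, span,
                                      params$onset_drift /
                                        (1 - params$coupling_prob)))
    }
    l_times <- sort(l_times[l_times > 0 & l_times < span])
    # enforce a 2 s refractory gap on the merged left train
    if (length(l_times) > 1) {
      keep <- c(TRUE, diff(l_times) > 2)
      l_times <- l_times[keep]
    }

    r_dur <- draw_durations(r_times, params, span)
    l_dur <- draw_durations(l_times, params, span)
    list(L = event_train("L", l_times, l_dur),
         R = event_train("R", r_times, r_dur))
  })
}

#' Fluorescence read-out kernel parameters
#'
#' Describes how a burst event is rendered into indicator fluorescence:
#' a saturating rise held for the burst duration, then first-order decay
#' at rate `k_off`. The defaults correspond to a GCaMP6s-like read-out
#' (`k_off` 1.1 per second, i.e. decay time constant ~0.91 s); use
#' `k_off = 3.9` for a GCaMP6f-like fast indicator. `k_off` is interpreted
#' in units of s^-1.
#'
#' @param rise_tau rise time constant, seconds.
#' @param k_off fluorescence decay rate, per second (> 0).
#' @param amplitude_mean mean burst amplitude, dF/F0 units.
#' @param amplitude_cv amplitude coefficient of variation.
#' @param noise_sd additive Gaussian noise SD, dF/F0 units.
#' @param baseline resting fluorescence intensity, camera units.
#' @param frame_interval sampling interval, seconds (default 0.2 s/frame,
#'   the canonical slow-imaging rate).
#' @return object of class `"kernel_params"`.
#' @export
kernel_params <- function(rise_tau = 0.5,
                          k_off = 1.1,
                          amplitude_mean = 1.0,
                          amplitude_cv = 0.1,
                          noise_sd = 0.05,
                          baseline = 100,
                          frame_interval = 0.2) {
  if (k_off <= 0) stop("'k_off' must be > 0", call. = FALSE)
  if (frame_interval <= 0) stop("'frame_interval' must be > 0", call. = FALSE)
  if (rise_tau <= 0) stop("'rise_tau' must be > 0", call. = FALSE)
  if (noise_sd < 0 || amplitude_cv < 0) {
    stop("'noise_sd' and 'amplitude_cv' must be >= 0", call. = FALSE)
  }
  structure(list(rise_tau = rise_tau, k_off = k_off,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
                 noise_sd = noise_sd, baseline = baseline,
                 frame_interval = frame_interval),
            class = "kernel_params")
}

# Additive contribution of one event on the time grid. Ordinary bursts are
# double-exponential transients A * (1 - exp(-s/rise_tau)) * exp(-s*k_off)
# with a sharp interior maximum; the support extends over the burst window
# or the full transient, whichever is longer. Long bursts (> 30 s) hold a
# saturating rise with a mild droop over the plateau, then decay at k_off.
event_kernel <- function(times, t0, duration, amplitude, kernel) {
  s <- times - t0
  out <- numeric(length(times))
  tau_d <- 1 / kernel$k_off
  if (duration > LONG_BURST_THRESHOLD_S) {
    hold <- s >= 0 & s <= duration
    droop <- 1 - 0.15 * s[hold] / duration
    out[hold] <- amplitude * (1 - exp(-s[hold] / kernel$rise_tau)) * droop
    level <- 0.85 * amplitude * (1 - exp(-duration / kernel$rise_tau))
    dec <- s > duration
    out[dec] <- level * exp(-(s[dec] - duration) * kernel$k_off)
  } else {
    # normalized so the kernel maximum equals `amplitude` (peak dF/F0)
    s_star <- kernel$rise_tau * log(1 + tau_d / kernel$rise_tau)
    peak <- (1 - exp(-s_star / kernel$rise_tau)) * exp(-s_star * kernel$k_off)
    sup <- s >= 0 & s <= max(duration, 8 * tau_d)
    out[sup] <- (amplitude / peak) * (1 - exp(-s[sup] / kernel$rise_tau)) *
      exp(-s[sup] * kernel$k_off)
  }
  out
}

#' Render event trains into a two-channel fluorescence trace
#'
#' Each event contributes a saturating-rise/exponential-decay kernel
#' (see [kernel_params()]); contributions sum, Gaussian noise is added in
#' dF/F0 units, and the result is expressed as raw intensity
#' `baseline * (1 + signal + noise)` on a uniform time grid.
#'
#' @param trains list with [event_train()] elements `L` and `R` (either may
#'   be empty, giving a noise-only channel).
#' @param kernel a [kernel_params()] object.
#' @param span trace length, seconds; must be at least one frame.
#' @param rng_seed integer seed for amplitudes and noise.
#' @return a [fluorescence_trace()] with channels `L` and `R` (raw,
#'   un-normalized).
#' @examples
#' tr <- sample_event_trains(phase_defaults("III"), 400, rng_seed = 2)
#' fl <- render_trace(tr, kernel_params(), span = 400, rng_seed = 2)
#' @export
render_trace <- function(trains, kernel = kernel_params(), span,
                         rng_seed = NULL) {
  stopifnot(inherits(kernel, "kernel_params"))
  if (kernel$frame_interval > span) {
    stop("'span' must cover at least one frame interval", call. = FALSE)
  }
  times <- seq(0, span, by = kernel$frame_interval)
  with_seed(rng_seed, {
    channels <- lapply(trains[c("L", "R")], function(tr) {
      sig <- numeric(length(times))
      n_ev <- length(tr$event_times)
      if (n_ev) {
        amps <- if (kernel$amplitude_cv <= 0) {
          rep(kernel$amplitude_mean, n_ev)
        } else {
          shape <- 1 / kernel$amplitude_cv^2
          rgamma(n_ev, shape = shape, rate = shape / kernel$amplitude_mean)
        }
        for (i in seq_len(n_ev)) {
          sig <- sig + event_kernel(times, tr$event_times[i],
                                    tr$event_durations[i], amps[i], kernel)
        }
      }
      if (kernel$noise_sd > 0) {
        sig <- sig + rnorm(length(times), 0, kernel$noise_sd)
      }
      kernel$baseline * (1 + sig)
    })
    names(channels) <- c("L", "R")
    fluorescence_trace(times, channels,
                       frame_interval = kernel$frame_interval,
                       normalized = FALSE)
  })
}

#' Simulate a tail-movement track from a bout plan
#'
#' Builds a bending-angle time course from a plan of movement bouts and
#' converts it to coordinates of the three tracked body parts (ocellus,
#' mid-tail, tail tip). Early tail flicks (`"lETF"`/`"rETF"`) are rendered
#' as single-signed half-sine excursions; `"swim"` bouts as sign-alternating
#' oscillation at the planned frequency under a tapered envelope;
#' quiescence elsewhere. Left bends are positive angles.
#'
#' @param bout_plan data frame with columns `type` (`"lETF"`, `"rETF"`,
#'   `"swim"`), `start`, `duration` (seconds), `frequency` (Hz, swim only;
#'   `NA` for flicks). Bouts must not overlap.
#' @param fps frames per second: 200-400 for high-speed-camera-style
#'   tracks or 2 for fluorescence-style tracks.
#' @param rng_seed integer seed for tracking noise.
#' @param span total track length, seconds; default covers the plan plus 1 s.
#' @param etf_amp_deg,swim_amp_deg excursion amplitudes, degrees.
#' @param noise_px coordinate tracking noise SD, pixels.
#' @param dropout_prob per-frame probability of a low-likelihood dropout.
#' @return a [midline_track()].
#' @examples
#' plan <- data.frame(type = "swim", start = 1, duration = 5, frequency = 9.7)
#' trk <- simulate_tail(plan, fps = 200, rng_seed = 1)
#' @export
simulate_tail <- function(bout_plan, fps, rng_seed = NULL, span = NULL,
                          etf_amp_deg = 30, swim_amp_deg = 25,
                          noise_px = 0.3, dropout_prob = 0) {
  if (!(fps %in% 200:400 || fps == 2)) {
    stop("'fps' must be in [200, 400] (high-speed) or 2 (fluorescence-style)",
         call. = FALSE)
  }
  if (nrow(bout_plan)) {
    ord <- order(bout_plan$start)
    bout_plan <- bout_plan[ord, , drop = FALSE]
    ends <- bout_plan$start + bout_plan$duration
    if (nrow(bout_plan) > 1 &&
        any(bout_plan$start[-1] < ends[-nrow(bout_plan)])) {
      stop("bouts in 'bout_plan' overlap", call. = FALSE)
    }
  }
  if (is.null(span)) {
    span <- if (nrow(bout_plan)) {
      max(bout_plan$start + bout_plan$duration) + 1
    } else 1
  }
  times <- seq(0, span, by = 1 / fps)
  theta <- numeric(length(times))
  for (i in seq_len(nrow(bout_plan))) {
    b <- bout_plan[i, ]
    idx <- which(times >= b$start & times <= b$start + b$duration)
    u <- (times[idx] - b$start) / b$duration   # 0..1 within bout
    if (b$type %in% c("lETF", "rETF")) {
      pulse <- sin(pi * u)                     # single-signed excursion
      theta[idx] <- etf_amp_deg * pulse * if (b$type == "lETF") 1 else -1
    } else if (b$type == "swim") {
      env <- pmin(1, pmin(u, 1 - u) / 0.1)     # 10% taper each side
      theta[idx] <- swim_amp_deg * env *
        sin(2 * pi * b$frequency * (times[idx] - b$start))
    } else {
      stop("unknown bout type: '", b$type, "'", call. = FALSE)
    }
  }
  with_seed(rng_seed, {
    # ocellus fixed at origin, mid-tail 100 px caudal; tail tip placed so
    # the bending angle at the mid-tail equals theta (left positive)
    phi <- -theta * pi / 180
    n <- length(times)
    noise <- function() if (noise_px > 0) rnorm(n, 0, noise_px) else 0
    parts <- list(
      bodypart1 = data.frame(x = 0 + noise(), y = 0 + noise(),
                             likelihood = rep(0.99, n)),
      bodypart2 = data.frame(x = 100 + noise(), y = 0 + noise(),
                             likelihood = rep(0.99, n)),
      bodypart3 = data.frame(x = 100 + 80 * cos(phi) + noise(),
                             y = 80 * sin(phi) + noise(),
                             likelihood = rep(0.99, n))
    )
    if (dropout_prob > 0) {
      drop <- runif(n) < dropout_prob
      for (p in names(parts)) parts[[p]]$likelihood[drop] <- 0.3
    }
    midline_track(times, parts, fps = fps)
  })
}

#' Simulate a cohort onset-laterality table
#'
#' Draws, for each embryo, which channel begins oscillating first. The
#' default right-first probability 13/17 reflects the observed dominance of
#' the right motor neuron (76% of embryos).
#'
#' @param n_embryos number of embryos (> 0).
#' @param p_right_first probability the right channel starts first.
#' @param rng_seed integer seed.
#' @return data frame with columns `embryo_id`, `first_onset` (`"L"`/`"R"`).
#' @examples
#' simulate_cohort(5, p_right_first = 1, rng_seed = 1)
#' @export
simulate_cohort <- function(n_embryos, p_right_first = 13 / 17,
                            rng_seed = NULL) {
  if (n_embryos <= 0) stop("'n_embryos' must be positive", call. = FALSE)
  if (p_right_first < 0 || p_right_first > 1) {
    stop("'p_right_first' must lie in [0, 1]", call. = FALSE)
  }
  with_seed(rng_seed, {
    right <- runif(n_embryos) < p_right_first
    data.frame(embryo_id = seq_len(n_embryos),
               first_onset = ifelse(right, "R", "L"),
               stringsAsFactors = FALSE)
  })
}

#' Build a photostimulation trial table from per-category counts
#'
#' Convenience constructor for the long-format trial table consumed by
#' [stim_response_percentages()].
#'
#' @param stimulated_side `"L"` or `"R"`.
#' @param counts named integer vector over the response categories
#'   `left_contraction`, `right_contraction`, `continuous_swimming`,
#'   `no_response` (missing names count as zero).
#' @return data frame with columns `stimulated_side`, `response`.
#' @examples
#' make_stim_trials("R", c(right_contraction = 29, left_contraction = 1,
#'                         continuous_swimming = 2, no_response = 2))
#' @export
make_stim_trials <- function(stimulated_side, counts) {
  stimulated_side <- match.arg(stimulated_side, c("L", "R"))
  bad <- setdiff(names(counts), STIM_RESPONSE_CATEGORIES)
  if (length(bad)) {
    stop("unknown response categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    stimulated_side = rep(stimulated_side, sum(counts)),
    response = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
}
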