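# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# noise-free kernel for exact-recovery checks
quiet_kernel <- function(...) {
  kernel_params(noise_sd = 0, amplitude_cv = 0, ...)
}

# one-channel trace from explicit event times/durations, second channel empty
render_single_channel <- function(times_s, durations_s, span,
                                  kernel = quiet_kernel(), seed = 1) {
  trains <- list(L = event_train("L", times_s, durations_s),
                 R = event_train("R", numeric(0), numeric(0)))
  render_trace(trains, kernel, span = span, rng_seed = seed)
}

# run normalization + derivative + detection with package defaults
detect_pipeline <- function(trace, ...) {
  dff <- compute_dff(trace)
  deriv <- denoised_derivative(dff)
  detect_bursts(deriv, dff, ...)
}

# independent circumradius oracle: solve the circle through three points
# from the perpendicular-bisector linear system, return 1/radius
circumradius_curvature <- function(A, B, C) {
  M <- rbind(c(B[1] - A[1], B[2] - A[2]),
             c(C[1] - B[1], C[2] - B[2]))
  rhs <- c(sum(B^2 - A^2) / 2, sum(C^2 - B^2) / 2)
  center <- solve(M, rhs)
  1 / sqrt(sum((A - center)^2))
}

# concatenated ground-truth recording through all seven phases
concat_phase_trains <- function(seed, cycles = 50) {
  phases <- c("I", "II", "III", "IV", "V", "VI", "VII")
  l_t <- l_d <- r_t <- r_d <- numeric(0)
  off <- 0
  truth <- data.frame(phase = phases, t_start = NA_real_, t_end = NA_real_)
  for (i in seq_along(phases)) {
    p <- phase_defaults(phases[i])
    span <- cycles * p$mean_interval
    tr <- sample_event_trains(p, span, rng_seed = seed * 100 + i)
    l_t <- c(l_t, tr$L$event_times + off)
    l_d <- c(l_d, tr$L$event_durations)
    r_t <- c(r_t, tr$R$event_times + off)
    r_d <- c(r_d, tr$R$event_durations)
    truth$t_start[i] <- off
    truth$t_end[i] <- off + span
    off <- off + span
  }
  list(L = as_burst_train(event_train("L", l_t, l_d)),
       R = as_burst_train(event_train("R", r_t, r_d)),
       truth = truth)
}

# true phase label at each window midpoint
truth_labels <- function(features, truth) {
  mid <- (features$t_start + features$t_end) / 2
  vapply(mid, function(m) {
    i <- which(m >= truth$t_start & m < truth$t_end)[1]
    truth$phase[i]
  }, character(1))
}
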