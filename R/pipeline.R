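#' Default run configuration
#'
#' Collects every tunable threshold of the pipeline with its documented
#' default, plus the seed and I/O paths. The configuration round-trips
#' through YAML via [read_run_config()] / [write_run_config()].
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    trace_csv = NULL,
    dlc_csv = NULL,
    dlc_fps = 2,
    out_dir = NULL,
    # normalization
    baseline_method = "rolling_quantile",
    baseline_window = 120,
    baseline_q = 0.2,
    # detection
    sg_window = 7,
    sg_order = 3,
    prominence_k = 4,
    min_separation = 2,
    # classification
    window_cycles = 10,
    step_cycles = 2,
    ref_interval = NULL,
    thresholds = phase_thresholds(),
    monotone_segments = FALSE,
    # kinematics
    bout_thresholds = bout_thresholds(),
    likelihood_threshold = 0.9,
    cooccurrence_max_lag = 2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return a [run_config()] with the file's overrides applied.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate a complete recording from a developmental phase plan
#'
#' Samples coupled event trains segment by segment from the plan, renders
#' the two-channel fluorescence trace, and (optionally) writes everything
#' to disk: the trace CSV, the ground-truth events TSV and the true
#' segment table. Fully deterministic for a given seed.
#'
#' @param phase_plan data frame with columns `phase` (label `"I".."VII"`)
#'   and `duration_s`; defaults to a short run through all seven phases.
#' @param kernel a [kernel_params()].
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, directory to write `trace.csv`,
#'   `truth_events.tsv`, `truth_segments.tsv` (created if absent).
#' @return list with `trace`, `trains` (ground truth), `segments`
#'   (true phase windows), and `files` (paths written, or `NULL`).
#' @export
simulate_recording <- function(phase_plan = NULL, kernel = kernel_params(),
                               seed = 1, out_dir = NULL) {
  if (is.null(phase_plan)) {
    phase_plan <- data.frame(
      phase = c("I", "II", "III", "IV", "V", "VI", "VII"),
      duration_s = c(400, 400, 400, 400, 550, 850, 850))
  }
  if (!all(phase_plan$phase %in% PHASE_LEVELS)) {
    stop("invalid phase plan: unknown phase label", call. = FALSE)
  }
  if (any(phase_plan$duration_s <= 0)) {
    stop("invalid phase plan: non-positive segment duration", call. = FALSE)
  }
  offs <- cumsum(c(0, phase_plan$duration_s))
  span <- offs[length(offs)]

  l_times <- l_dur <- r_times <- r_dur <- numeric(0)
  for (i in seq_len(nrow(phase_plan))) {
    seg <- sample_event_trains(phase_defaults(phase_plan$phase[i]),
                               span = phase_plan$duration_s[i],
                               rng_seed = seed * 1000 + i)
    l_times <- c(l_times, seg$L$event_times + offs[i])
    l_dur <- c(l_dur, seg$L$event_durations)
    r_times <- c(r_times, seg$R$event_times + offs[i])
    r_dur <- c(r_dur, seg$R$event_durations)
  }
  trains <- list(L = event_train("L", l_times, l_dur),
                 R = event_train("R", r_times, r_dur))
  trace <- render_trace(trains, kernel, span = span,
                        rng_seed = seed * 1000 + nrow(phase_plan) + 1)
  segments <- data.frame(label = phase_plan$phase,
                         t_start = offs[-length(offs)],
                         t_end = offs[-1])
  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- c(trace = file.path(out_dir, "trace.csv"),
               events = file.path(out_dir, "truth_events.tsv"),
               segments = file.path(out_dir, "truth_segments.tsv"))
    write_trace_csv(trace, files["trace"])
    write_events_tsv(lapply(trains, as_burst_train), files["events"])
    write.table(segments, files["segments"], sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  list(trace = trace, trains = trains, segments = segments, files = files)
}

#' Run the full analysis pipeline on a recording
#'
#' Normalizes the trace, detects bursts on both channels, assigns
#' cycle-anchored phases of left bursts to the right rhythm with a
#' Rayleigh test (overall and per classified segment), extracts
#' sliding-window features, classifies and smooths the seven-phase
#' segmentation, and determines onset laterality. If a pose track is
#' supplied, tail kinematics and burst-bout co-occurrence are added.
#'
#' @param trace a raw [fluorescence_trace()] or a path to a trace CSV.
#' @param track optional [midline_track()] or path to a DeepLabCut CSV.
#' @param config a [run_config()].
#' @return a report list: `trains`, `intervals`, `circular`,
#'   `segment_circular`, `features`, `labels`, `segments`, `laterality`,
#'   `angle`, `bouts`, `cooccurrence`, `thresholds`. Written to
#'   `config$out_dir` via [write_results()] when set.
#' @export
analyze_recording <- function(trace, track = NULL, config = run_config()) {
  if (is.character(trace)) trace <- read_trace_csv(trace)
  if (is.character(track)) track <- read_dlc_csv(track, fps = config$dlc_fps)

  dff <- compute_dff(trace, baseline_method = config$baseline_method,
                     window = config$baseline_window, q = config$baseline_q)
  deriv <- denoised_derivative(dff, sg_window = config$sg_window,
                               sg_order = config$sg_order)
  trains <- detect_bursts(deriv, dff, prominence_k = config$prominence_k,
                          min_separation = config$min_separation,
                          channels = c("L", "R"))
  intervals <- lapply(trains, compute_intervals)

  circular <- NULL
  if (nrow(trains$R$events) >= 2 && nrow(trains$L$events) >= 1) {
    ph <- assign_cycle_phases(trains$L, trains$R)
    if (ph$n >= 1) circular <- rayleigh_test(ph$angles)
  }

  features <- window_features(trains$L, trains$R,
                              window_cycles = config$window_cycles,
                              step_cycles = config$step_cycles,
                              ref_interval = config$ref_interval,
                              thresholds = config$thresholds)
  labels <- classify_windows(features, config$thresholds)
  segments <- smooth_segments(features, labels,
                              monotone = config$monotone_segments)

  segment_circular <- NULL
  if (nrow(segments)) {
    segment_circular <- list()
    for (i in seq_len(nrow(segments))) {
      tl <- trains$L$events$peak_s
      tr <- trains$R$events$peak_s
      sel_r <- tr >= segments$t_start[i] & tr <= segments$t_end[i]
      sel_l <- tl >= segments$t_start[i] & tl <= segments$t_end[i]
      if (sum(sel_r) >= 2 && sum(sel_l) >= 1) {
        ph <- assign_cycle_phases(tl[sel_l], tr[sel_r])
        if (ph$n >= 1) {
          segment_circular[[segments$label[i]]] <- rayleigh_test(ph$angles)
        }
      }
    }
  }

  laterality <- tryCatch(
    onset_laterality(trains$L, trains$R,
                     frame_interval = trace$frame_interval),
    error = function(e) NA_character_)

  angle <- bouts <- cooc <- NULL
  if (!is.null(track)) {
    angle <- bending_angle(track,
                           likelihood_threshold = config$likelihood_threshold)
    bouts <- segment_bouts(angle, thresholds = config$bout_thresholds)
    if (nrow(bouts)) {
      cooc <- cooccurrence(bouts, trains,
                           max_lag = config$cooccurrence_max_lag)
    }
  }

  report <- list(trains = trains, intervals = intervals,
                 circular = circular, segment_circular = segment_circular,
                 features = features, labels = labels, segments = segments,
                 laterality = laterality,
                 angle = angle, bouts = bouts, cooccurrence = cooc,
                 thresholds = c(config$thresholds,
                                list(prominence_k = config$prominence_k,
                                     min_separation = config$min_separation,
                                     sg_window = config$sg_window,
                                     sg_order = config$sg_order)))
  if (!is.null(config$out_dir)) write_results(report, config$out_dir)
  report
}
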