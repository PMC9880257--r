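#' Uniformly sampled multi-channel fluorescence trace
#'
#' @param times numeric vector of sample times, seconds, strictly
#'   increasing on a uniform grid (relative tolerance 1e-6).
#' @param channels named list of numeric intensity vectors (raw or dF/F0),
#'   each the same length as `times`.
#' @param frame_interval sampling interval in seconds; inferred from
#'   `times` when omitted.
#' @param normalized logical flag: are the channels dF/F0?
#' @return object of class `"fluorescence_trace"`.
#' @export
fluorescence_trace <- function(times, channels, frame_interval = NULL,
                               normalized = FALSE) {
  times <- as.numeric(times)
  if (length(times) < 2) stop("need at least two samples", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (is.null(frame_interval)) frame_interval <- median(dts)
  if (frame_interval <= 0) stop("'frame_interval' must be > 0", call. = FALSE)
  if (any(abs(dts - frame_interval) > 1e-6 * frame_interval)) {
    stop("times are not on a uniform grid", call. = FALSE)
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("'channels' must be a named list", call. = FALSE)
  }
  for (nm in names(channels)) {
    if (length(channels[[nm]]) != length(times)) {
      stop("channel '", nm, "' length differs from times", call. = FALSE)
    }
  }
  structure(list(times = times,
                 channels = lapply(channels, as.numeric),
                 frame_interval = frame_interval,
                 normalized = isTRUE(normalized)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat("<fluorescence_trace>", length(x$times), "frames @",
      x$frame_interval, "s,",
      if (x$normalized) "dF/F0" else "raw", "channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Three-point midline pose track
#'
#' @param times frame times, seconds.
#' @param parts named list of data frames `bodypart1` (ocellus),
#'   `bodypart2` (mid-tail), `bodypart3` (tail tip), each with columns
#'   `x`, `y`, `likelihood` and one row per frame.
#' @param fps frames per second.
#' @return object of class `"midline_track"`.
#' @export
midline_track <- function(times, parts, fps) {
  needed <- c("bodypart1", "bodypart2", "bodypart3")
  missing_parts <- setdiff(needed, names(parts))
  if (length(missing_parts)) {
    stop("missing body part(s): ", paste(missing_parts, collapse = ", "),
         call. = FALSE)
  }
  parts <- parts[needed]
  for (nm in needed) {
    p <- parts[[nm]]
    if (!all(c("x", "y", "likelihood") %in% names(p))) {
      stop("part '", nm, "' must have x, y, likelihood", call. = FALSE)
    }
    if (nrow(p) != length(times)) {
      stop("part '", nm, "' length differs from times", call. = FALSE)
    }
    if (any(p$likelihood < 0 | p$likelihood > 1, na.rm = TRUE)) {
      stop("likelihood must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), parts = parts, fps = fps),
            class = "midline_track")
}

#' @export
print.midline_track <- function(x, ...) {
  cat("<midline_track>", length(x$times), "frames @", x$fps, "fps\n")
  invisible(x)
}

# serialize doubles at 9 significant digits (round-trip stable)
fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "NA"
  out
}

channel_column <- function(channel) paste0("mn2", tolower(channel))

#' Write a fluorescence trace as CSV
#'
#' Columns: `time_s`, then one column per channel (`mn2l`, `mn2r` for the
#' canonical L/R pair). Floats are serialized with 9 significant digits so
#' write/read round-trips are bit-stable.
#'
#' @param trace a [fluorescence_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  df <- data.frame(time_s = fmt_num(trace$times))
  for (nm in names(trace$channels)) {
    df[[channel_column(nm)]] <- fmt_num(trace$channels[[nm]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fluorescence trace from CSV
#'
#' Expects a header with a time column (`time_s`, or any name containing
#' "time") and at least one channel column. The time grid is validated for
#' monotonicity and uniformity. Channel columns named `mn2l`/`mn2r` are
#' mapped back to channels `L`/`R`.
#'
#' @param path CSV file path.
#' @param nan_policy `"error"` (default) rejects non-finite intensities;
#'   `"interpolate"` fills interior runs of up to 3 missing frames
#'   linearly and rejects longer runs.
#' @return a [fluorescence_trace()] (raw; `normalized = FALSE`).
#' @export
read_trace_csv <- function(path, nan_policy = c("error", "interpolate")) {
  nan_policy <- match.arg(nan_policy)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) {
                   stop("cannot parse trace CSV '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (!nrow(df) || ncol(df) < 2) {
    stop("trace CSV '", path, "' must have a time column and >= 1 channel",
         call. = FALSE)
  }
  tcol <- if ("time_s" %in% names(df)) "time_s" else {
    hit <- grep("time", names(df), ignore.case = TRUE, value = TRUE)
    if (!length(hit)) stop("no time column found in '", path, "'",
                           call. = FALSE)
    hit[1]
  }
  times <- as.numeric(df[[tcol]])
  if (any(!is.finite(times))) stop("non-numeric time values", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("time column is not strictly increasing", call. = FALSE)
  }
  chan_cols <- setdiff(names(df), tcol)
  channels <- list()
  for (cc in chan_cols) {
    x <- as.numeric(df[[cc]])
    bad <- !is.finite(x)
    if (any(bad)) {
      if (nan_policy == "error") {
        stop("non-finite intensities in column '", cc,
             "' (set nan_policy = \"interpolate\" to fill short runs)",
             call. = FALSE)
      }
      x <- interpolate_short_runs(x, max_run = 3)
      if (any(!is.finite(x))) {
        stop("missing-value run longer than 3 frames in column '", cc, "'",
             call. = FALSE)
      }
    }
    nm <- if (grepl("^mn2[lr]$", cc)) toupper(sub("mn2", "", cc)) else cc
    channels[[nm]] <- x
  }
  fluorescence_trace(times, channels, normalized = FALSE)
}

# linear interpolation of interior NA runs of length <= max_run
interpolate_short_runs <- function(x, max_run = 3) {
  na <- which(!is.finite(x))
  if (!length(na)) return(x)
  runs <- split(na, cumsum(c(1, diff(na) != 1)))
  ok <- which(is.finite(x))
  for (r in runs) {
    if (length(r) <= max_run && min(r) > 1 && max(r) < length(x)) {
      x[r] <- approx(ok, x[ok], xout = r)$y
    }
  }
  x
}

#' Write a midline track in DeepLabCut CSV dialect
#'
#' Three header rows (scorer / bodyparts / coords) followed by one row per
#' frame: frame index then `x`, `y`, `likelihood` triplets per body part.
#'
#' @param track a [midline_track()].
#' @param path output file path.
#' @param scorer scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path, scorer = "cionaphase") {
  stopifnot(inherits(track, "midline_track"))
  parts <- names(track$parts)
  h1 <- c("scorer", rep(scorer, 3 * length(parts)))
  h2 <- c("bodyparts", rep(parts, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  n <- length(track$times)
  body <- matrix("", nrow = n, ncol = 1 + 3 * length(parts))
  body[, 1] <- as.character(seq_len(n) - 1L)
  for (i in seq_along(parts)) {
    p <- track$parts[[parts[i]]]
    body[, 3 * i - 1] <- fmt_num(p$x)
    body[, 3 * i]     <- fmt_num(p$y)
    body[, 3 * i + 1] <- fmt_num(p$likelihood)
  }
  lines <- c(paste(h1, collapse = ","),
             paste(h2, collapse = ","),
             paste(h3, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a DeepLabCut-dialect pose CSV
#'
#' Expects the standard three header rows (scorer / bodyparts / coords)
#' with `x`, `y`, `likelihood` triplets for `bodypart1` (ocellus),
#' `bodypart2` (mid-tail) and `bodypart3` (tail tip). Frame times are
#' derived from `fps`.
#'
#' @param path CSV file path.
#' @param fps frames per second of the source video (default 2, the
#'   500 ms/frame fluorescence-camera rate).
#' @return a [midline_track()].
#' @export
read_dlc_csv <- function(path, fps = 2) {
  lines <- readLines(path)
  if (length(lines) < 4) {
    stop("DLC CSV '", path, "' lacks the 3 header rows + data", call. = FALSE)
  }
  h2 <- strsplit(lines[2], ",")[[1]]
  h3 <- strsplit(lines[3], ",")[[1]]
  if (!identical(tolower(h2[1]), "bodyparts") ||
      !identical(tolower(h3[1]), "coords")) {
    stop("malformed DLC header (need scorer / bodyparts / coords rows)",
         call. = FALSE)
  }
  dat <- read.csv(text = lines[-(1:3)], header = FALSE)
  parts <- list()
  for (part in c("bodypart1", "bodypart2", "bodypart3")) {
    cols <- which(h2 == part)
    if (!length(cols)) {
      stop("body part '", part, "' missing from '", path, "'", call. = FALSE)
    }
    coord_of <- function(what) {
      j <- cols[h3[cols] == what]
      if (!length(j)) {
        stop("'", what, "' column missing for '", part,
             "' (dialect requires x,y,likelihood triplets)", call. = FALSE)
      }
      as.numeric(dat[[j[1]]])
    }
    parts[[part]] <- data.frame(x = coord_of("x"), y = coord_of("y"),
                                likelihood = coord_of("likelihood"))
  }
  times <- (seq_len(nrow(dat)) - 1) / fps
  midline_track(times, parts, fps = fps)
}

#' Write detected burst events as TSV
#'
#' Columns: `channel`, `onset_s`, `peak_s`, `offset_s`, `duration_s`,
#' `peak_dff`, `is_long`, `truncated`. An empty train writes a header-only
#' file.
#'
#' @param trains a single [burst_train] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(trains, path) {
  if (inherits(trains, "burst_train")) trains <- list(trains)
  evs <- do.call(rbind, lapply(trains, function(tr) {
    if (!nrow(tr$events)) return(NULL)
    cbind(channel = tr$channel, tr$events)
  }))
  if (is.null(evs)) {
    evs <- data.frame(channel = character(0), onset_s = numeric(0),
                      peak_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), peak_dff = numeric(0),
                      is_long = logical(0), truncated = logical(0))
  }
  num <- c("onset_s", "peak_s", "offset_s", "duration_s", "peak_dff")
  for (cc in num) evs[[cc]] <- fmt_num(evs[[cc]])
  write.table(evs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read burst events written by [write_events_tsv()]
#'
#' @param path TSV file path.
#' @return named list of [burst_train] objects, one per channel present
#'   (empty list for a header-only file).
#' @export
read_events_tsv <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  out <- lapply(split(df, df$channel), function(d) {
    d <- d[order(d$peak_s), ]
    burst_train(d$channel[1],
                data.frame(onset_s = d$onset_s, peak_s = d$peak_s,
                           offset_s = d$offset_s, duration_s = d$duration_s,
                           peak_dff = d$peak_dff, is_long = d$is_long,
                           truncated = d$truncated))
  })
  out
}

#' Write a full analysis report to disk
#'
#' Writes `events.tsv`, `window_features.tsv`, `segments.tsv` and
#' `summary.json` (schema-versioned; per-segment circular statistics and
#' the thresholds used) into `dir`.
#'
#' @param report a report list as returned by [analyze_recording()].
#' @param dir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)

  p <- file.path(dir, "events.tsv")
  write_events_tsv(report$trains, p)
  paths <- c(paths, p)

  p <- file.path(dir, "window_features.tsv")
  feats <- report$features
  if (is.null(feats)) feats <- data.frame()
  write.table(feats, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "segments.tsv")
  segs <- report$segments
  if (is.null(segs)) segs <- data.frame()
  write.table(segs, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "summary.json")
  jsonlite::write_json(report_summary(report), p, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

# JSON-serializable summary of an analysis report
report_summary <- function(report) {
  circ_entry <- function(cp, label = NULL) {
    list(phase_label = label,
         n = cp$n,
         mean_deg = if (is.na(cp$mean_angle)) NULL else cp$mean_angle,
         R = cp$resultant_R,
         p = cp$rayleigh_p)
  }
  segments <- NULL
  if (!is.null(report$segment_circular)) {
    segments <- lapply(seq_along(report$segment_circular), function(i) {
      circ_entry(report$segment_circular[[i]],
                 names(report$segment_circular)[i])
    })
  }
  list(
    schema_version = "1.0",
    n_events = sum(vapply(report$trains, function(tr) nrow(tr$events), 1L)),
    circular = if (!is.null(report$circular)) {
      circ_entry(report$circular, "overall")
    },
    segments = segments,
    laterality = report$laterality,
    thresholds = report$thresholds
  )
}

#' Check a summary JSON against the shipped schema
#'
#' Lightweight structural validation: required top-level fields and, for
#' every circular-statistics entry, the `n` / `R` / `p` triple. The schema
#' document itself ships at
#' `system.file("extdata", "summary-schema.json", package = "cionaphase")`.
#'
#' @param x path to a summary JSON file, or an already-parsed list.
#' @return `TRUE` (invisibly) if valid; otherwise an error naming the
#'   missing field.
#' @export
validate_summary <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x)
  for (field in c("schema_version", "n_events")) {
    if (is.null(x[[field]])) {
      stop("summary JSON missing required field '", field, "'",
           call. = FALSE)
    }
  }
  check_circ <- function(entry, where) {
    for (field in c("n", "R", "p")) {
      if (is.null(entry[[field]])) {
        stop("summary JSON ", where, " missing '", field, "'", call. = FALSE)
      }
    }
  }
  if (!is.null(x$circular)) check_circ(x$circular, "circular block")
  for (seg in x$segments) check_circ(seg, "segment entry")
  invisible(TRUE)
}
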