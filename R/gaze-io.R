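#' Construct a gaze sample stream
#'
#' A sample stream is the raw record of one trial: ordered gaze samples at a
#' nominal rate (500 Hz for the tasks this package models, recorded
#' monocularly), in degrees of visual angle, screen-centered (+x rightward,
#' +y upward).  Time is trial-relative milliseconds with stimulus onset at
#' t = 0; samples before onset (the fixation period) carry negative times.
#' Samples lost to blinks or tracker dropout are kept in place and flagged
#' invalid, never deleted, so event detection can account for them.
#'
#' @param t numeric vector of sample times, ms (strictly increasing).
#' @param x,y gaze position in degrees; may be `NA` where `valid` is FALSE.
#' @param valid logical vector; FALSE during blinks/dropout.
#' @param nominal_rate_hz nominal sampling rate (default 500).
#' @return A `gaze_stream`: a data.frame with columns `t`, `x`, `y`,
#'   `valid` and attribute `nominal_rate_hz`.
#' @export
gaze_stream <- function(t, x, y, valid = NULL, nominal_rate_hz = 500) {
  n <- length(t)
  if (is.null(valid)) valid <- !(is.na(x) | is.na(y))
  stopifnot(length(x) == n, length(y) == n, length(valid) == n,
            nominal_rate_hz > 0)
  if (n > 1 && any(diff(t) <= 0))
    stop("gaze_stream: timestamps must be strictly increasing")
  valid <- valid & !is.na(x) & !is.na(y)
  df <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                   valid = as.logical(valid))
  df$x[!df$valid] <- NA_real_
  df$y[!df$valid] <- NA_real_
  attr(df, "nominal_rate_hz") <- nominal_rate_hz
  class(df) <- c("gaze_stream", "data.frame")
  df
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> %d samples, %.0f Hz nominal, t in [%.1f, %.1f] ms, %d invalid\n",
              nrow(x), attr(x, "nominal_rate_hz"), min(x$t), max(x$t),
              sum(!x$valid)))
  invisible(x)
}

#' Detection and exclusion configuration
#'
#' Thresholds and filters governing event parsing and trial/participant
#' exclusion.  Defaults are the standard values for 500 Hz video
#' eye-tracking of these paradigms: saccades flagged at 22 deg/s velocity or
#' 8000 deg/s^2 acceleration; first-saccade latency accepted in [70, 500] ms
#' (inclusive at both ends); minimum fixation duration 32 ms (16 consecutive
#' samples at 500 Hz); participants retained only if gaze was captured on at
#' least 75% of trials in the relevant condition(s).
#'
#' @param velocity_threshold saccade velocity criterion, deg/s.
#' @param acceleration_threshold saccade acceleration criterion, deg/s^2.
#' @param min_latency_ms,max_latency_ms accepted first-saccade latency
#'   window, ms (boundaries inclusive).
#' @param min_fixation_ms shortest fixation retained, ms.
#' @param capture_fraction minimum proportion of usable trials per condition
#'   for a participant to be included.
#' @param min_saccade_amplitude_deg smallest saccade eligible as a trial's
#'   "first saccade" (microsaccade guard), deg.
#' @param blink_margin_ms samples within this margin of an invalid span are
#'   excluded from event detection (velocity artifacts around blinks).
#' @param merge_gap_ms threshold crossings closer than this are merged into
#'   one saccade.
#' @return A `detection_config` list.
#' @export
detection_config <- function(velocity_threshold = 22,
                             acceleration_threshold = 8000,
                             min_latency_ms = 70,
                             max_latency_ms = 500,
                             min_fixation_ms = 32,
                             capture_fraction = 0.75,
                             min_saccade_amplitude_deg = 1,
                             blink_margin_ms = 20,
                             merge_gap_ms = 20) {
  stopifnot(velocity_threshold > 0, acceleration_threshold > 0,
            min_latency_ms < max_latency_ms, min_fixation_ms > 0,
            capture_fraction > 0, capture_fraction <= 1,
            min_saccade_amplitude_deg >= 0, blink_margin_ms >= 0,
            merge_gap_ms >= 0)
  structure(list(velocity_threshold = velocity_threshold,
                 acceleration_threshold = acceleration_threshold,
                 min_latency_ms = min_latency_ms,
                 max_latency_ms = max_latency_ms,
                 min_fixation_ms = min_fixation_ms,
                 capture_fraction = capture_fraction,
                 min_saccade_amplitude_deg = min_saccade_amplitude_deg,
                 blink_margin_ms = blink_margin_ms,
                 merge_gap_ms = merge_gap_ms),
            class = "detection_config")
}

#' Read an analysis configuration file
#'
#' A single declarative YAML file carries both the detection thresholds and
#' the screen geometry; absent fields fall back to the defaults of
#' [detection_config()] and [screen_geometry()].
#'
#' @param path path to a YAML file with optional top-level keys
#'   `detection:` (fields of [detection_config()]) and `geometry:` (fields
#'   `resolution_px`, `viewing_distance_m`, `pixel_pitch_mm`,
#'   `refresh_rate_hz`).
#' @return list with elements `detection` and `geometry` (geometry NULL if
#'   not supplied: it has no universal default and must come from the
#'   recording setup).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  det <- do.call(detection_config, raw$detection %||% list())
  geom <- if (!is.null(raw$geometry)) do.call(screen_geometry, raw$geometry)
  list(detection = det, geometry = geom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gaze samples from a tabular (CSV) file
#'
#' Expected header: `trial_id,t_ms,x,y,valid` (`trial_id` and `valid`
#' optional).  Coordinates may be in degrees (already screen-centered) or in
#' pixels; pass `geometry` to convert pixel input.  Rows with missing x or y
#' are flagged invalid and kept in place.
#'
#' @param path CSV file path.
#' @param units `"deg"` (default) or `"px"`.
#' @param geometry a [screen_geometry()]; required when `units = "px"`.
#' @param nominal_rate_hz nominal sampling rate.
#' @return A single [gaze_stream()] if the file holds one trial, otherwise a
#'   named list of streams keyed by `trial_id`.
#' @export
read_gaze_csv <- function(path, units = c("deg", "px"), geometry = NULL,
                          nominal_rate_hz = 500) {
  units <- match.arg(units)
  if (units == "px" && is.null(geometry))
    stop("read_gaze_csv: geometry is required for pixel-coded input")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_ms", "x", "y")
  if (!all(need %in% names(df)))
    stop("read_gaze_csv: missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      coerced <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(coerced))
      if (col == "t_ms" && length(bad))
        stop(sprintf("read_gaze_csv: unparseable value in column '%s' at line %d",
                     col, bad[1] + 1L))
      df[[col]] <- coerced
    }
  }
  valid <- if ("valid" %in% names(df)) {
    as.logical(df$valid) & !is.na(df$x) & !is.na(df$y)
  } else !(is.na(df$x) | is.na(df$y))

  one_stream <- function(sub, sub_valid) {
    if (any(diff(sub$t_ms) <= 0))
      stop("read_gaze_csv: non-monotone timestamps")
    x <- sub$x; y <- sub$y
    if (units == "px") {
      xy <- px_to_deg(cbind(ifelse(sub_valid, x, NA), ifelse(sub_valid, y, NA)),
                      geometry)
      x <- xy[, 1]; y <- xy[, 2]
    }
    gaze_stream(sub$t_ms, x, y, sub_valid, nominal_rate_hz)
  }

  if ("trial_id" %in% names(df) && length(unique(df$trial_id)) > 1) {
    ids <- unique(df$trial_id)
    out <- lapply(ids, function(id) {
      sel <- df$trial_id == id
      one_stream(df[sel, , drop = FALSE], valid[sel])
    })
    names(out) <- as.character(ids)
    out
  } else {
    one_stream(df, valid)
  }
}

#' Write a gaze stream to CSV
#'
#' Inverse of [read_gaze_csv()] for degree-coded data; a write/read
#' round-trip reproduces the stream to the written precision.
#'
#' @param stream a [gaze_stream()].
#' @param path output CSV path.
#' @param trial_id optional id written in a `trial_id` column.
#' @param digits significant digits for coordinates (default 10).
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(stream, path, trial_id = NULL, digits = 10) {
  df <- data.frame(t_ms = stream$t,
                   x = signif(stream$x, digits),
                   y = signif(stream$y, digits),
                   valid = stream$valid)
  if (!is.null(trial_id)) df <- cbind(trial_id = trial_id, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read gaze samples from an EyeLink-ASC-like text file
#'
#' Parses the plain-text sample dialect written by EyeLink conversion
#' tools: whitespace-separated sample lines `<t> <x> <y> <pupil>` (pixel
#' coordinates), `SBLINK`/`EBLINK` lines bracketing blink spans, and `MSG`
#' lines.  A `MSG <t> <onset_marker>` line (default marker
#' `"STIMULUS_ONSET"`) rebases time so stimulus onset is t = 0.  Samples
#' whose x or y field is non-numeric (EyeLink writes `.` during signal
#' loss), or that fall inside an SBLINK/EBLINK span, are flagged invalid.
#'
#' @param path file path.
#' @param geometry a [screen_geometry()] used to convert pixels to degrees.
#' @param onset_marker MSG payload marking stimulus onset.
#' @param nominal_rate_hz nominal sampling rate.
#' @return A [gaze_stream()].
#' @export
read_gaze_asc <- function(path, geometry, onset_marker = "STIMULUS_ONSET",
                          nominal_rate_hz = 500) {
  lines <- readLines(path, warn = FALSE)
  t <- x <- y <- numeric(0)
  valid <- logical(0)
  in_blink <- FALSE
  onset <- NA_real_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (tok[1] == "MSG") {
      if (length(tok) >= 3 && tok[3] == onset_marker)
        onset <- as.numeric(tok[2])
      next
    }
    if (tok[1] == "SBLINK") { in_blink <- TRUE; next }
    if (tok[1] == "EBLINK") { in_blink <- FALSE; next }
    if (grepl("^[A-Za-z*]", tok[1])) next  # other event/header lines
    ts <- suppressWarnings(as.numeric(tok[1]))
    if (is.na(ts))
      stop(sprintf("read_gaze_asc: unparseable sample line %d", i))
    xs <- suppressWarnings(as.numeric(tok[2]))
    ys <- suppressWarnings(as.numeric(tok[3]))
    ok <- !in_blink && !is.na(xs) && !is.na(ys)
    t <- c(t, ts); x <- c(x, xs); y <- c(y, ys); valid <- c(valid, ok)
  }
  if (length(t) == 0) stop("read_gaze_asc: no sample lines found")
  if (any(diff(t) <= 0)) stop("read_gaze_asc: non-monotone timestamps")
  if (!is.na(onset)) t <- t - onset
  xy <- px_to_deg(cbind(ifelse(valid, x, NA), ifelse(valid, y, NA)), geometry)
  gaze_stream(t, xy[, 1], xy[, 2], valid, nominal_rate_hz)
}

#' Summarize and write an exclusion log
#'
#' Aggregates machine-readable exclusion records (one row per excluded trial
#' or participant, with a reason code) into per-reason counts, an overall
#' removal percentage, and the mean number of excluded trials per
#' participant — the accounting a report reader needs to audit the filters.
#'
#' @param exclusions data.frame with columns `participant`, `unit`
#'   (`"trial"` or `"participant"`) and `reason`; zero rows allowed.
#' @param n_total_trials total trials entering the filters.
#' @param n_participants number of participants entering the filters.
#' @param path optional file path; when given, a plain-text log is written.
#' @return list with `counts` (per reason), `n_trials_excluded`,
#'   `percent_trials_excluded`, `mean_trials_excluded_per_participant`,
#'   `n_participants_excluded`.
#' @export
exclusion_log <- function(exclusions, n_total_trials, n_participants,
                          path = NULL) {
  stopifnot(is.data.frame(exclusions))
  if (nrow(exclusions) > 0)
    stopifnot(all(c("participant", "unit", "reason") %in% names(exclusions)))
  trials <- exclusions[exclusions$unit == "trial", , drop = FALSE]
  parts <- exclusions[exclusions$unit == "participant", , drop = FALSE]
  counts <- if (nrow(exclusions)) table(exclusions$reason) else table(character(0))
  res <- list(
    counts = counts,
    n_trials_excluded = nrow(trials),
    percent_trials_excluded = 100 * nrow(trials) / n_total_trials,
    mean_trials_excluded_per_participant = nrow(trials) / n_participants,
    n_participants_excluded = nrow(parts))
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("trials excluded: %d of %d (%.3f%%)", res$n_trials_excluded,
              n_total_trials, res$percent_trials_excluded),
      sprintf("mean excluded trials per participant: %.3f",
              res$mean_trials_excluded_per_participant),
      sprintf("participants excluded: %d", res$n_participants_excluded),
      "counts by reason:",
      if (length(counts)) sprintf("  %s: %d", names(counts), as.integer(counts))
      else "  (none)"), con)
  }
  res
}
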