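#' Per-sample velocity and acceleration traces
#'
#' Differentiates a gaze stream into angular speed (deg/s) and its rate of
#' change (deg/s^2), aligned to the sample times.  Velocity components are
#' estimated by central differences on position, the resulting speed is
#' smoothed with a 3-sample moving average (stabilizing the acceleration
#' estimate, as common EyeLink-style parsers do), and acceleration is the
#' central difference of smoothed speed.  Invalid samples (blinks, dropout)
#' propagate as `NA` through the differentiation window.
#'
#' @param stream a [gaze_stream()] with at least 3 valid samples.
#' @return data.frame with columns `t`, `velocity` (deg/s) and
#'   `acceleration` (deg/s^2); `NA` where undefined (stream ends, invalid
#'   spans).
#' @export
velocity_acceleration_trace <- function(stream) {
  n <- nrow(stream)
  if (n < 3) stop("velocity_acceleration_trace: need at least 3 samples")
  if (sum(stream$valid) < 3)
    stop("velocity_acceleration_trace: need at least 3 valid samples")
  t <- stream$t; x <- stream$x; y <- stream$y
  idx <- 2:(n - 1)
  dt <- (t[idx + 1] - t[idx - 1]) / 1000  # s
  vx <- (x[idx + 1] - x[idx - 1]) / dt
  vy <- (y[idx + 1] - y[idx - 1]) / dt
  v <- rep(NA_real_, n)
  v[idx] <- sqrt(vx^2 + vy^2)
  # 3-sample moving average; NA at invalid neighbours propagates
  vs <- rep(NA_real_, n)
  vs[idx] <- (v[idx - 1] + v[idx] + v[idx + 1]) / 3
  vs[2] <- mean(v[2:3])        # edges: average over available neighbours
  vs[n - 1] <- mean(v[(n - 2):(n - 1)])
  a <- rep(NA_real_, n)
  inner <- 3:(n - 2)
  if (length(inner))
    a[inner] <- (vs[inner + 1] - vs[inner - 1]) / ((t[inner + 1] - t[inner - 1]) / 1000)
  data.frame(t = t, velocity = vs, acceleration = a)
}

#' Detect blinks in a gaze stream
#'
#' Maximal runs of invalid samples become blink events.
#'
#' @param stream a [gaze_stream()].
#' @return data.frame with columns `onset_ms`, `offset_ms` (zero rows if no
#'   invalid samples).
#' @export
detect_blinks <- function(stream) {
  runs <- .runs_of(!stream$valid)
  data.frame(onset_ms = stream$t[runs$start], offset_ms = stream$t[runs$end])
}

#' Detect saccades by velocity/acceleration criteria
#'
#' A candidate saccade sample is one whose smoothed speed exceeds the
#' velocity threshold OR whose |acceleration| exceeds the acceleration
#' threshold; a saccade runs from the first such sample to the last before
#' both measures fall back below threshold.  Runs separated by less than
#' `merge_gap_ms` are merged; events touching a blink (within
#' `blink_margin_ms`) are discarded as artifacts.
#'
#' @param stream a [gaze_stream()].
#' @param config a [detection_config()].
#' @return data.frame of saccades ordered by onset, with columns
#'   `onset_ms`, `offset_ms`, `start_x`, `start_y`, `end_x`, `end_y`,
#'   `amplitude_deg`, `peak_velocity`, `latency_ms` (onset relative to the
#'   t = 0 stimulus onset).  Zero rows if none.
#' @export
detect_saccades <- function(stream, config = detection_config()) {
  tr <- velocity_acceleration_trace(stream)
  cand <- (!is.na(tr$velocity) & tr$velocity >= config$velocity_threshold) |
    (!is.na(tr$acceleration) & abs(tr$acceleration) >= config$acceleration_threshold)
  cand[!stream$valid] <- FALSE
  runs <- .runs_of(cand)
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      start_x = numeric(0), start_y = numeric(0),
                      end_x = numeric(0), end_y = numeric(0),
                      amplitude_deg = numeric(0), peak_velocity = numeric(0),
                      latency_ms = numeric(0))
  if (nrow(runs) == 0) return(empty)
  # merge runs separated by < merge_gap_ms
  if (nrow(runs) > 1) {
    keep_start <- runs$start[1]
    merged <- list()
    cur_start <- runs$start[1]; cur_end <- runs$end[1]
    for (k in 2:nrow(runs)) {
      gap <- stream$t[runs$start[k]] - stream$t[cur_end]
      if (gap < config$merge_gap_ms) {
        cur_end <- runs$end[k]
      } else {
        merged[[length(merged) + 1]] <- c(cur_start, cur_end)
        cur_start <- runs$start[k]; cur_end <- runs$end[k]
      }
    }
    merged[[length(merged) + 1]] <- c(cur_start, cur_end)
    runs <- data.frame(start = vapply(merged, `[`, 0, 1),
                       end = vapply(merged, `[`, 0, 2))
  }
  # drop events adjacent to blinks (within margin)
  blink_mask <- .expand_mask(!stream$valid, stream$t, config$blink_margin_ms)
  near_blink <- vapply(seq_len(nrow(runs)), function(k)
    any(blink_mask[runs$start[k]:runs$end[k]]), logical(1))
  runs <- runs[!near_blink, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  i0 <- runs$start; i1 <- runs$end
  data.frame(
    onset_ms = stream$t[i0], offset_ms = stream$t[i1],
    start_x = stream$x[i0], start_y = stream$y[i0],
    end_x = stream$x[i1], end_y = stream$y[i1],
    amplitude_deg = sqrt((stream$x[i1] - stream$x[i0])^2 +
                           (stream$y[i1] - stream$y[i0])^2),
    peak_velocity = vapply(seq_along(i0), function(k)
      max(tr$velocity[i0[k]:i1[k]], na.rm = TRUE), numeric(1)),
    latency_ms = stream$t[i0])
}

#' Detect fixations between saccades and blinks
#'
#' Fixations are the maximal valid spans left over once saccade and blink
#' samples (plus the blink margin) are removed; spans shorter than the
#' configured minimum duration (32 ms = 16 consecutive samples at 500 Hz by
#' default) are dropped.
#'
#' @param stream a [gaze_stream()].
#' @param saccades result of [detect_saccades()] on the same stream.
#' @param blinks result of [detect_blinks()] on the same stream (computed if
#'   omitted).
#' @param config a [detection_config()].
#' @return data.frame with columns `onset_ms`, `offset_ms`, `duration_ms`,
#'   `centroid_x`, `centroid_y`.
#' @export
detect_fixations <- function(stream, saccades = NULL, blinks = NULL,
                             config = detection_config()) {
  if (is.null(saccades)) saccades <- detect_saccades(stream, config)
  in_event <- .expand_mask(!stream$valid, stream$t, config$blink_margin_ms)
  if (nrow(saccades) > 0) {
    lo <- findInterval(saccades$onset_ms - 1e-9, stream$t) + 1L
    hi <- findInterval(saccades$offset_ms + 1e-9, stream$t)
    for (k in seq_along(lo))
      if (lo[k] <= hi[k]) in_event[lo[k]:hi[k]] <- TRUE
  }
  runs <- .runs_of(stream$valid & !in_event)
  if (nrow(runs) == 0)
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0)))
  i0 <- runs$start; i1 <- runs$end
  fix <- data.frame(
    onset_ms = stream$t[i0], offset_ms = stream$t[i1],
    duration_ms = stream$t[i1] - stream$t[i0] + .sample_interval(stream),
    centroid_x = vapply(seq_along(i0), function(k)
      mean(stream$x[i0[k]:i1[k]]), numeric(1)),
    centroid_y = vapply(seq_along(i0), function(k)
      mean(stream$y[i0[k]:i1[k]]), numeric(1)))
  fix[fix$duration_ms >= config$min_fixation_ms, , drop = FALSE]
}

#' Parse a stream into saccades, fixations and blinks
#'
#' Convenience wrapper running the full event-detection stage.
#'
#' @inheritParams detect_saccades
#' @return list with elements `saccades`, `fixations`, `blinks`.
#' @export
parse_events <- function(stream, config = detection_config()) {
  blinks <- detect_blinks(stream)
  saccades <- detect_saccades(stream, config)
  fixations <- detect_fixations(stream, saccades, blinks, config)
  list(saccades = saccades, fixations = fixations, blinks = blinks)
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end) indices
.runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# expand TRUE spans of a mask by margin_ms on each side (time-based)
.expand_mask <- function(mask, t, margin_ms) {
  if (!any(mask) || margin_ms <= 0) return(mask)
  runs <- .runs_of(mask)
  out <- mask
  for (k in seq_len(nrow(runs))) {
    lo <- t[runs$start[k]] - margin_ms
    hi <- t[runs$end[k]] + margin_ms
    out <- out | (t >= lo & t <= hi)
  }
  out
}

# median inter-sample interval, ms
.sample_interval <- function(stream) {
  if (nrow(stream) > 1) stats::median(diff(stream$t)) else
    1000 / attr(stream, "nominal_rate_hz")
}
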