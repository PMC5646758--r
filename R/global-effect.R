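#' Construct a global-effect trial
#'
#' One trial of the global-effect (center-of-gravity) task: the fixation
#' cross jumps from screen center to 6 deg left or right on the horizontal
#' meridian while a vertical pair of images — one social, one nonsocial —
#' flanks the target location above and below the meridian.  The signed
#' deviation of the first saccade toward the social image is the trial's
#' statistic.
#'
#' @param stream a [gaze_stream()] (t = 0 at target onset).
#' @param target_side `"left"` or `"right"`.
#' @param social_position `"top"` or `"bottom"`: which flanker is the social
#'   image.
#' @param scrambled logical: grid-scrambled control stimuli?
#' @param target_eccentricity_deg target distance from center (default 6).
#' @param origin_xy fixation origin in deg (default screen center).
#' @return A `ge_trial` list.
#' @export
ge_trial <- function(stream, target_side = c("right", "left"),
                     social_position = c("top", "bottom"),
                     scrambled = FALSE, target_eccentricity_deg = 6,
                     origin_xy = c(0, 0)) {
  target_side <- match.arg(target_side)
  social_position <- match.arg(social_position)
  sgn <- if (target_side == "right") 1 else -1
  structure(list(stream = stream, target_side = target_side,
                 social_position = social_position, scrambled = scrambled,
                 origin_xy = origin_xy,
                 target_xy = origin_xy + c(sgn * target_eccentricity_deg, 0)),
            class = "ge_trial")
}

#' First saccade of a trial
#'
#' The earliest detected saccade whose onset is at or after stimulus onset
#' (t = 0) and whose amplitude reaches the configured floor (default 1 deg,
#' guarding against microsaccades).  Anticipatory saccades launched before
#' onset are ignored.
#'
#' @param saccades data.frame from [detect_saccades()].
#' @param config a [detection_config()].
#' @return One-row data.frame, or NULL if no eligible saccade.
#' @export
first_saccade <- function(saccades, config = detection_config()) {
  eligible <- saccades[saccades$onset_ms >= 0 &
                         saccades$amplitude_deg >= config$min_saccade_amplitude_deg, ,
                       drop = FALSE]
  if (nrow(eligible) == 0) return(NULL)
  eligible[which.min(eligible$onset_ms), , drop = FALSE]
}

#' Latency filter for the first saccade
#'
#' Trials whose first saccade starts before 70 ms (anticipatory) or after
#' 500 ms (inattentive) are excluded; boundary latencies are kept.
#'
#' @param latency_ms first-saccade latency.
#' @param config a [detection_config()].
#' @return TRUE to keep the trial.
#' @export
latency_filter <- function(latency_ms, config = detection_config()) {
  latency_ms >= config$min_latency_ms & latency_ms <= config$max_latency_ms
}

#' Signed deviation angle of a saccade toward the social image
#'
#' The angle between the saccade displacement vector (start to end) and the
#' direct path from the fixation origin to the target, in degrees.  The
#' sign encodes sociality: positive when the saccade endpoint lies on the
#' social image's side of the origin-target line, negative toward the
#' nonsocial side, zero on the line.  Averaged over trials, a positive value
#' means saccades are pulled toward social content.
#'
#' @param saccade one-row saccade data.frame (from [first_saccade()]).
#' @param trial a [ge_trial()].
#' @return Signed angle in degrees.
#' @export
deviation_angle <- function(saccade, trial) {
  u <- trial$target_xy - trial$origin_xy            # direct path
  v <- c(saccade$end_x - saccade$start_x,           # saccade displacement
         saccade$end_y - saccade$start_y)
  if (sqrt(sum(v^2)) == 0) stop("deviation_angle: zero-length saccade vector")
  ang <- atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
  # targets sit on the horizontal meridian: "toward the social image" is a
  # vertical question, so the sign comes from the saccade's vertical motion
  vertical <- sign(v[2])
  social_sign <- if (trial$social_position == "top") vertical else -vertical
  abs(ang) * social_sign
}

#' Per-trial global-effect statistic with exclusion accounting
#'
#' Runs event detection on a trial's stream, selects the first saccade,
#' applies the latency filter and computes the signed deviation angle.
#'
#' @param trial a [ge_trial()].
#' @param config a [detection_config()].
#' @return list with `deviation_deg` (NA if excluded), `latency_ms`,
#'   `excluded_reason` (`NA`, `"no_saccade"`, or `"latency"`).
#' @export
ge_trial_statistic <- function(trial, config = detection_config()) {
  saccades <- detect_saccades(trial$stream, config)
  fs <- first_saccade(saccades, config)
  if (is.null(fs))
    return(list(deviation_deg = NA_real_, latency_ms = NA_real_,
                excluded_reason = "no_saccade"))
  if (!latency_filter(fs$latency_ms, config))
    return(list(deviation_deg = NA_real_, latency_ms = fs$latency_ms,
                excluded_reason = "latency"))
  list(deviation_deg = deviation_angle(fs, trial), latency_ms = fs$latency_ms,
       excluded_reason = NA_character_)
}

#' Summarize a participant's global-effect trials
#'
#' Mean signed deviation per condition (scrambled / unscrambled) over
#' retained trials, capture fractions, and the inclusion flag: a
#' participant is excluded if gaze was captured on fewer than 75% (the
#' configured `capture_fraction`) of trials in either condition.
#'
#' @param deviations numeric vector of per-trial deviations (NA = excluded
#'   trial).
#' @param scrambled logical vector parallel to `deviations`.
#' @param config a [detection_config()].
#' @return list with `mean_deviation_unscrambled`, `mean_deviation_scrambled`,
#'   `captured_fraction_unscrambled`, `captured_fraction_scrambled`,
#'   `included`, `excluded_reason`.
#' @export
summarize_ge_participant <- function(deviations, scrambled,
                                     config = detection_config()) {
  stopifnot(length(deviations) == length(scrambled))
  res <- list()
  for (cond in c("unscrambled", "scrambled")) {
    sel <- if (cond == "scrambled") scrambled else !scrambled
    d <- deviations[sel]
    res[[paste0("captured_fraction_", cond)]] <-
      if (length(d)) mean(!is.na(d)) else NA_real_
    res[[paste0("mean_deviation_", cond)]] <-
      if (any(!is.na(d))) mean(d, na.rm = TRUE) else NA_real_
  }
  low_capture <-
    res$captured_fraction_unscrambled < config$capture_fraction ||
    res$captured_fraction_scrambled < config$capture_fraction
  no_data <- is.na(res$mean_deviation_unscrambled) ||
    is.na(res$mean_deviation_scrambled)
  res$included <- !low_capture && !no_data
  res$excluded_reason <- if (low_capture) "capture<75%"
    else if (no_data) "no_retained_trials" else NA_character_
  res
}
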