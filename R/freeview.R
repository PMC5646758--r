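#' Construct a freeview (preferential-looking) trial
#'
#' One trial of the preferential-looking task: a social and a nonsocial
#' image (each 5.59 x 4.19 deg) presented side by side for 5 s while the
#' participant looks freely.  The proportion of dwell time spent on the
#' social image is the trial's statistic.
#'
#' @param stream a [gaze_stream()] (t = 0 at image onset).
#' @param social_side `"left"` or `"right"`.
#' @param scrambled logical: grid-scrambled control pair?
#' @param image_size_deg image width and height in deg (default
#'   `c(5.59, 4.19)`).
#' @param center_eccentricity_deg horizontal distance of each image center
#'   from screen center (default 4.5, leaving a gap between the inner
#'   edges).
#' @param aoi_padding_deg padding added around each image rectangle to form
#'   its area of interest (default 0: AOI = exact image extent).
#' @param duration_ms trial duration (default 5000).
#' @return An `fv_trial` list with AOI rectangles `aoi_left`, `aoi_right`
#'   as `c(xmin, xmax, ymin, ymax)` in deg.
#' @export
fv_trial <- function(stream, social_side = c("left", "right"),
                     scrambled = FALSE, image_size_deg = c(5.59, 4.19),
                     center_eccentricity_deg = 4.5, aoi_padding_deg = 0,
                     duration_ms = 5000) {
  social_side <- match.arg(social_side)
  hw <- image_size_deg[1] / 2 + aoi_padding_deg
  hh <- image_size_deg[2] / 2 + aoi_padding_deg
  mk <- function(cx) c(cx - hw, cx + hw, -hh, hh)
  aoi_left <- mk(-center_eccentricity_deg)
  aoi_right <- mk(center_eccentricity_deg)
  if (aoi_left[2] > aoi_right[1])
    stop("fv_trial: AOIs overlap; reduce padding or increase eccentricity")
  structure(list(stream = stream, social_side = social_side,
                 scrambled = scrambled, aoi_left = aoi_left,
                 aoi_right = aoi_right, duration_ms = duration_ms),
            class = "fv_trial")
}

.in_rect <- function(x, y, rect) {
  x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
}

#' Assign fixation dwell time to the social and nonsocial images
#'
#' Each fixation's full duration is credited to the area of interest
#' containing its centroid; fixations landing outside both AOIs (e.g. on
#' the former fixation-cross location between the images) count toward
#' neither.  The first fixation is not treated specially by default (set
#' `drop_first = TRUE` for a sensitivity check that discards it).
#'
#' @param fixations data.frame from [detect_fixations()].
#' @param trial an [fv_trial()].
#' @param drop_first discard the first fixation of the trial?
#' @return list with `dwell_social_ms` and `dwell_nonsocial_ms`.
#' @export
assign_dwell <- function(fixations, trial, drop_first = FALSE) {
  if (drop_first && nrow(fixations) > 0)
    fixations <- fixations[-1, , drop = FALSE]
  if (nrow(fixations) == 0)
    return(list(dwell_social_ms = 0, dwell_nonsocial_ms = 0))
  in_left <- .in_rect(fixations$centroid_x, fixations$centroid_y, trial$aoi_left)
  in_right <- .in_rect(fixations$centroid_x, fixations$centroid_y, trial$aoi_right)
  dwell_left <- sum(fixations$duration_ms[in_left])
  dwell_right <- sum(fixations$duration_ms[in_right])
  if (trial$social_side == "left")
    list(dwell_social_ms = dwell_left, dwell_nonsocial_ms = dwell_right)
  else
    list(dwell_social_ms = dwell_right, dwell_nonsocial_ms = dwell_left)
}

#' Social dwell proportion
#'
#' Dwell time on the social image divided by total dwell time on both
#' images: 0.5 means equal looking, values above 0.5 a bias toward social
#' content.  Undefined (NA) when no fixation landed in either image.
#'
#' @param dwell_social_ms,dwell_nonsocial_ms dwell times in ms.
#' @return Proportion in \[0, 1\], or NA if both dwells are zero.
#' @export
social_proportion <- function(dwell_social_ms, dwell_nonsocial_ms) {
  total <- dwell_social_ms + dwell_nonsocial_ms
  ifelse(total > 0, dwell_social_ms / total, NA_real_)
}

#' Per-trial freeview statistic
#'
#' Runs event detection on the trial's stream and computes the social dwell
#' proportion.
#'
#' @param trial an [fv_trial()].
#' @param config a [detection_config()].
#' @param drop_first passed to [assign_dwell()].
#' @return list with `proportion_social` (NA if no in-AOI fixation time),
#'   `dwell_social_ms`, `dwell_nonsocial_ms`.
#' @export
fv_trial_statistic <- function(trial, config = detection_config(),
                               drop_first = FALSE) {
  ev <- parse_events(trial$stream, config)
  dw <- assign_dwell(ev$fixations, trial, drop_first)
  list(proportion_social = social_proportion(dw$dwell_social_ms,
                                             dw$dwell_nonsocial_ms),
       dwell_social_ms = dw$dwell_social_ms,
       dwell_nonsocial_ms = dw$dwell_nonsocial_ms)
}

#' Summarize a participant's freeview trials
#'
#' Mean social dwell proportion per condition over trials with defined
#' proportions.  Following the task's exclusion rule, a participant is
#' excluded only when gaze was captured on less than 75% (the configured
#' `capture_fraction`) of scrambled trials.
#'
#' @param proportions numeric vector of per-trial social proportions (NA =
#'   no usable gaze).
#' @param scrambled logical vector parallel to `proportions`.
#' @param config a [detection_config()].
#' @return list with `mean_proportion_unscrambled`,
#'   `mean_proportion_scrambled`, `captured_fraction_scrambled`,
#'   `captured_fraction_unscrambled`, `included`, `excluded_reason`.
#' @export
summarize_fv_participant <- function(proportions, scrambled,
                                     config = detection_config()) {
  stopifnot(length(proportions) == length(scrambled))
  res <- list()
  for (cond in c("unscrambled", "scrambled")) {
    sel <- if (cond == "scrambled") scrambled else !scrambled
    p <- proportions[sel]
    res[[paste0("captured_fraction_", cond)]] <-
      if (length(p)) mean(!is.na(p)) else NA_real_
    res[[paste0("mean_proportion_", cond)]] <-
      if (any(!is.na(p))) mean(p, na.rm = TRUE) else NA_real_
  }
  low_capture <- res$captured_fraction_scrambled < config$capture_fraction
  no_data <- is.na(res$mean_proportion_unscrambled) ||
    is.na(res$mean_proportion_scrambled)
  res$included <- !low_capture && !no_data
  res$excluded_reason <- if (low_capture) "capture<75%"
    else if (no_data) "no_retained_trials" else NA_character_
  res
}
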