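#' Screen geometry for pixel/degree conversion
#'
#' Describes the display used to record gaze: pixel resolution, physical
#' pixel pitch, viewing distance and refresh rate.  All gaze analysis in
#' this package is carried out in degrees of visual angle in a
#' screen-centered frame (+x rightward, +y upward); this object carries the
#' information needed to convert raw pixel coordinates into that frame.
#'
#' The conversion is exact per axis: an offset of `d` pixels from screen
#' center corresponds to `atan(d * pixel_pitch_mm / distance_mm)` radians.
#' Because `atan` is strictly monotone the mapping is invertible everywhere
#' on screen.
#'
#' @param resolution_px integer length-2, screen width and height in pixels.
#' @param viewing_distance_m viewing distance in meters (default 1, eyes
#'   in-line with the screen's horizontal meridian).
#' @param pixel_pitch_mm physical size of one pixel in millimeters.
#' @param refresh_rate_hz display refresh rate in Hz (default 75).
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(c(1024, 768), 1, 0.3851)
#' px_to_deg(c(512, 384), geom)  # screen center -> (0, 0)
#' @export
screen_geometry <- function(resolution_px, viewing_distance_m = 1,
                            pixel_pitch_mm, refresh_rate_hz = 75) {
  stopifnot(length(resolution_px) == 2, all(resolution_px > 0),
            viewing_distance_m > 0, pixel_pitch_mm > 0, refresh_rate_hz > 0)
  structure(list(resolution_px = as.numeric(resolution_px),
                 viewing_distance_m = viewing_distance_m,
                 pixel_pitch_mm = pixel_pitch_mm,
                 refresh_rate_hz = refresh_rate_hz),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, pitch %.4g mm, distance %.3g m, %g Hz\n",
              x$resolution_px[1], x$resolution_px[2], x$pixel_pitch_mm,
              x$viewing_distance_m, x$refresh_rate_hz))
  invisible(x)
}

#' Convert pixel coordinates to screen-centered degrees
#'
#' Pixel coordinates follow the usual image convention (origin at top-left,
#' y increasing downward); the returned degrees are screen-centered with +x
#' rightward and +y upward.
#'
#' @param xy numeric vector `c(x, y)` or a 2-column matrix of pixel
#'   coordinates.
#' @param geometry a [screen_geometry()].
#' @return Coordinates in degrees of visual angle, same shape as `xy`.
#' @export
px_to_deg <- function(xy, geometry) {
  m <- .as_xy_matrix(xy)
  cx <- geometry$resolution_px[1] / 2
  cy <- geometry$resolution_px[2] / 2
  dist_mm <- geometry$viewing_distance_m * 1000
  dx_mm <- (m[, 1] - cx) * geometry$pixel_pitch_mm
  dy_mm <- (cy - m[, 2]) * geometry$pixel_pitch_mm  # flip: +y upward
  out <- cbind(atan2(dx_mm, dist_mm), atan2(dy_mm, dist_mm)) * 180 / pi
  .restore_xy_shape(out, xy)
}

#' Convert screen-centered degrees to pixel coordinates
#'
#' Inverse of [px_to_deg()].
#'
#' @inheritParams px_to_deg
#' @param xy coordinates in degrees (vector `c(x, y)` or 2-column matrix).
#' @return Pixel coordinates, same shape as `xy`.
#' @export
deg_to_px <- function(xy, geometry) {
  m <- .as_xy_matrix(xy)
  cx <- geometry$resolution_px[1] / 2
  cy <- geometry$resolution_px[2] / 2
  dist_mm <- geometry$viewing_distance_m * 1000
  dx_mm <- tan(m[, 1] * pi / 180) * dist_mm
  dy_mm <- tan(m[, 2] * pi / 180) * dist_mm
  out <- cbind(cx + dx_mm / geometry$pixel_pitch_mm,
               cy - dy_mm / geometry$pixel_pitch_mm)
  .restore_xy_shape(out, xy)
}

.as_xy_matrix <- function(xy) {
  if (is.matrix(xy)) {
    stopifnot(ncol(xy) == 2)
    xy
  } else {
    stopifnot(length(xy) == 2)
    matrix(xy, ncol = 2)
  }
}

.restore_xy_shape <- function(m, template) {
  if (is.matrix(template)) m else drop(m)
}
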