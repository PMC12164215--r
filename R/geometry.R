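#' Screen geometry for pixel/degree conversion
#'
#' Describes the presentation monitor and viewing distance so that pixel
#' extents can be converted to visual angles. The default matches the study
#' setup: a 1920 x 1080 px monitor with a visible area of 533 x 300 mm,
#' refreshing at 120 Hz, viewed from 570 mm.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_mm,height_mm physical screen size in mm.
#' @param distance_mm viewing distance in mm.
#' @param refresh_hz refresh rate in Hz (metadata only).
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_mm = 533, height_mm = 300,
                            distance_mm = 570, refresh_hz = 120) {
  vals <- c(width_px, height_px, width_mm, height_mm, distance_mm, refresh_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("screen_geometry: all fields must be positive and finite", call. = FALSE)
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_mm = width_mm, height_mm = height_mm,
         distance_mm = distance_mm, refresh_hz = refresh_hz,
         pitch_x_mm = width_mm / width_px,
         pitch_y_mm = height_mm / height_px),
    class = "screen_geometry"
  )
}

#' Convert a pixel extent to a visual angle
#'
#' Uses the exact subtense formula
#' `angle = 2 * atan(extent_mm / (2 * distance_mm))` with the axis-specific
#' pixel pitch, so horizontal and vertical pixels need not be square.
#'
#' @param extent_px extent in pixels (vectorised).
#' @param axis `"horizontal"` or `"vertical"`; selects the pixel pitch.
#' @param geometry a [screen_geometry()].
#' @return visual angle(s) in degrees.
#' @examples
#' px_to_deg(210, "horizontal", screen_geometry()) # ~5.85 deg (head AOI)
#' px_to_deg(140, "horizontal", screen_geometry()) # ~3.91 deg (hand AOI)
#' @export
px_to_deg <- function(extent_px, axis = c("horizontal", "vertical"), geometry) {
  axis <- match.arg(axis)
  stopifnot(inherits(geometry, "screen_geometry"))
  if (geometry$distance_mm <= 0) stop("px_to_deg: non-positive viewing distance", call. = FALSE)
  pitch <- if (axis == "horizontal") geometry$pitch_x_mm else geometry$pitch_y_mm
  2 * atan((extent_px * pitch) / (2 * geometry$distance_mm)) * 180 / pi
}

#' Convert a visual angle to a pixel extent (inverse of [px_to_deg()])
#' @inheritParams px_to_deg
#' @param angle_deg visual angle(s) in degrees.
#' @return extent in pixels.
#' @export
deg_to_px <- function(angle_deg, axis = c("horizontal", "vertical"), geometry) {
  axis <- match.arg(axis)
  stopifnot(inherits(geometry, "screen_geometry"))
  pitch <- if (axis == "horizontal") geometry$pitch_x_mm else geometry$pitch_y_mm
  2 * geometry$distance_mm * tan(angle_deg / 2 * pi / 180) / pitch
}
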