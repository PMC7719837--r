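#' Screen geometry for pixel / visual-angle conversion
#'
#' Describes the physical display and viewing distance of a screen-based
#' eye-tracking setup. The defaults match a 17.3-inch 1920 x 1080 laptop
#' display viewed from 60 cm, the canonical geometry for the analyses in
#' this package. Pixel pitch is derived from the physical diagonal and
#' the pixel diagonal, assuming square pixels.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param diagonal_mm Physical diagonal of the display in millimetres
#'   (default 17.3 inches).
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @return An object of class `screen_geometry`: a list with the four
#'   inputs plus `pitch_mm_px`, the physical size of one pixel.
#' @examples
#' geom <- screen_geometry()
#' px_to_visual_angle(100, geom) # ~1.9 degrees
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            diagonal_mm = 17.3 * 25.4,
                            viewing_distance_mm = 600) {
  vals <- c(width_px = width_px, height_px = height_px,
            diagonal_mm = diagonal_mm,
            viewing_distance_mm = viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("screen_geometry: all fields must be finite and strictly positive")
  }
  pitch <- diagonal_mm / sqrt(width_px^2 + height_px^2)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         diagonal_mm = diagonal_mm,
         viewing_distance_mm = viewing_distance_mm,
         pitch_mm_px = pitch),
    class = "screen_geometry"
  )
}

#' Convert an on-screen extent in pixels to visual angle
#'
#' Uses the symmetric small-target formula
#' `angle = 2 * atan(px * pitch / 2 / distance)`, i.e. the angle subtended
#' by an extent centred on the line of sight.
#'
#' @param px Extent in pixels (vectorised).
#' @param geometry A [screen_geometry()].
#' @return Visual angle in degrees.
#' @export
px_to_visual_angle <- function(px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  2 * atan((px * geometry$pitch_mm_px / 2) / geometry$viewing_distance_mm) *
    180 / pi
}

#' @rdname px_to_visual_angle
#' @param degrees Visual angle in degrees (vectorised).
#' @export
visual_angle_to_px <- function(degrees, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  2 * geometry$viewing_distance_mm * tan(degrees / 2 * pi / 180) /
    geometry$pitch_mm_px
}
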