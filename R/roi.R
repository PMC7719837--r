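#' Axis-aligned screen rectangle
#'
#' Rectangles are in screen pixel coordinates (origin top-left, x rightward,
#' y downward). Containment is half-open: closed on the minimum edges, open
#' on the maximum edges, so adjacent disjoint rectangles never share a point.
#'
#' @param x_min,y_min,x_max,y_max Rectangle edges in pixels; minima must be
#'   strictly below maxima.
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(x_min, y_min, x_max, y_max) {
  vals <- c(x_min, y_min, x_max, y_max)
  if (length(vals) != 4L || any(!is.finite(vals))) {
    stop("roi_rect: edges must be four finite numbers")
  }
  if (x_min >= x_max || y_min >= y_max) {
    stop("roi_rect: degenerate rectangle (x_min >= x_max or y_min >= y_max)")
  }
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "roi_rect")
}

#' Rectangle area in square pixels
#' @param rect A [roi_rect()].
#' @return `(x_max - x_min) * (y_max - y_min)`.
#' @export
roi_area <- function(rect) {
  stopifnot(inherits(rect, "roi_rect"))
  (rect$x_max - rect$x_min) * (rect$y_max - rect$y_min)
}

#' Point-in-rectangle test (half-open convention)
#'
#' @param x,y Point coordinates in pixels (vectorised).
#' @param rect A [roi_rect()].
#' @return Logical vector.
#' @export
point_in_rect <- function(x, y, rect) {
  stopifnot(inherits(rect, "roi_rect"))
  x >= rect$x_min & x < rect$x_max & y >= rect$y_min & y < rect$y_max
}

#' Edgewise average of subject-drawn rectangles
#'
#' The consensus ROI for one tool part is the plain arithmetic mean of each
#' edge across all subjects who drew it; no subject is excluded.
#'
#' @param rects A list of [roi_rect()] objects (one per subject).
#' @return A [roi_rect()] with averaged edges.
#' @export
average_rois <- function(rects) {
  if (length(rects) < 1L) stop("average_rois: empty input")
  ok <- vapply(rects, inherits, logical(1), what = "roi_rect")
  if (!all(ok)) stop("average_rois: all inputs must be roi_rect objects")
  edge <- function(nm) mean(vapply(rects, `[[`, numeric(1), nm))
  x_min <- edge("x_min"); y_min <- edge("y_min")
  x_max <- edge("x_max"); y_max <- edge("y_max")
  if (x_min >= x_max || y_min >= y_max) {
    stop("average_rois: averaged rectangle is degenerate")
  }
  roi_rect(x_min, y_min, x_max, y_max)
}

#' Build a tool's ROI set from its functional and grasping rectangles
#'
#' The tool center is the midpoint of the centers of the two rectangles.
#' The outer edges anchor the standardized horizontal coordinate: the right
#' (outer) edge of the functional ROI maps to +100 and the left (outer) edge
#' of the grasping ROI maps to -100. The grasping part must lie left of the
#' functional part (tools are displayed with the grip on the left).
#'
#' @param functional,grasp [roi_rect()] objects.
#' @param tool Tool identifier.
#' @param familiarity `"familiar"` or `"unfamiliar"`.
#' @return An object of class `tool_roi_set`.
#' @export
build_roi_set <- function(functional, grasp, tool = NA_character_,
                          familiarity = NA_character_) {
  stopifnot(inherits(functional, "roi_rect"), inherits(grasp, "roi_rect"))
  f_cx <- (functional$x_min + functional$x_max) / 2
  g_cx <- (grasp$x_min + grasp$x_max) / 2
  if (g_cx >= f_cx) {
    stop("build_roi_set: grasp rectangle must lie left of the functional rectangle")
  }
  f_cy <- (functional$y_min + functional$y_max) / 2
  g_cy <- (grasp$y_min + grasp$y_max) / 2
  center_x <- (f_cx + g_cx) / 2
  center_y <- (f_cy + g_cy) / 2
  out <- structure(
    list(tool = tool, familiarity = familiarity,
         functional = functional, grasp = grasp,
         center_x_px = center_x, center_y_px = center_y,
         functional_outer_edge_x = functional$x_max,
         grasp_outer_edge_x = grasp$x_min),
    class = "tool_roi_set"
  )
  if (!(out$grasp_outer_edge_x < center_x &&
        center_x < out$functional_outer_edge_x)) {
    stop("build_roi_set: center does not lie between the ROI outer edges")
  }
  out
}

#' Standardized horizontal gaze coordinate
#'
#' Piecewise-linear map placing the tool center at 0, the outer edge of the
#' functional ROI at +100 and the outer edge of the grasping ROI at -100.
#' Only the horizontal axis enters the coordinate; whether a sample counts
#' as missing is decided separately by 2-D containment ([classify_sample()]).
#'
#' @param x_px Horizontal screen coordinate(s) in pixels.
#' @param roiset A [build_roi_set()] result.
#' @return Standardized coordinate(s); strictly increasing in `x_px`.
#' @export
standardize_x <- function(x_px, roiset) {
  stopifnot(inherits(roiset, "tool_roi_set"))
  cx <- roiset$center_x_px
  right <- roiset$functional_outer_edge_x - cx
  left <- cx - roiset$grasp_outer_edge_x
  ifelse(x_px >= cx,
         100 * (x_px - cx) / right,
         100 * (x_px - cx) / left)
}

#' Assign a gaze sample to the functional ROI, grasping ROI, or outside
#'
#' Samples outside both rectangles (including the central gap between them)
#' are missing for all standardized-coordinate analyses. Containment is
#' half-open so no point belongs to two disjoint rectangles.
#'
#' @param x_px,y_px Sample coordinates (vectorised).
#' @param roiset A [build_roi_set()] result.
#' @return Character vector in `c("functional", "grasp", "outside")`.
#' @export
classify_sample <- function(x_px, y_px, roiset) {
  stopifnot(inherits(roiset, "tool_roi_set"))
  out <- rep("outside", length(x_px))
  out[point_in_rect(x_px, y_px, roiset$grasp)] <- "grasp"
  out[point_in_rect(x_px, y_px, roiset$functional)] <- "functional"
  out
}
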