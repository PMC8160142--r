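#' Viewing geometry of the simulation screen
#'
#' Describes the physical screen and the observer's position in front of it:
#' physical width/height in cm, pixel resolution, and eye-to-screen distance.
#' All angular quantities in the package are derived from this object through
#' a tangent-plane (gnomonic) mapping with the screen center as the
#' straight-ahead axis.
#'
#' The defaults describe a 59.9 x 33.6 cm monitor at 1600 x 900 pixels viewed
#' from 70 cm, which under the tangent mapping subtends about 46.3 x 27.0
#' degrees of visual angle.
#'
#' @param width_cm,height_cm Physical screen size in cm.
#' @param width_px,height_px Screen resolution in pixels.
#' @param distance_cm Eye-to-screen distance in cm.
#'
#' @return A `viewing_geometry` object (a validated list).
#' @export
#' @examples
#' geom <- viewing_geometry()
#' screen_to_deg(tibble::tibble(x_px = 800, y_px = 450), geom)
viewing_geometry <- function(width_cm = 59.9, height_cm = 33.6,
                             width_px = 1600, height_px = 900,
                             distance_cm = 70) {
  vals <- c(width_cm = width_cm, height_cm = height_cm,
            width_px = width_px, height_px = height_px,
            distance_cm = distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all viewing_geometry fields must be finite and strictly positive",
         call. = FALSE)
  }
  # square-pixel assumption: cm/px must agree between axes within 5%
  cm_per_px_x <- width_cm / width_px
  cm_per_px_y <- height_cm / height_px
  if (abs(cm_per_px_x - cm_per_px_y) / cm_per_px_x > 0.05) {
    stop("pixel aspect implied by cm and px fields differs by more than 5%; ",
         "pixels are assumed square", call. = FALSE)
  }
  structure(
    list(width_cm = width_cm, height_cm = height_cm,
         width_px = width_px, height_px = height_px,
         distance_cm = distance_cm,
         cm_per_px = (cm_per_px_x + cm_per_px_y) / 2),
    class = "viewing_geometry"
  )
}

#' @export
print.viewing_geometry <- function(x, ...) {
  ext <- screen_extent_deg(x)
  cat(sprintf(
    "<viewing_geometry> %.1f x %.1f cm, %d x %d px, %.1f cm distance (%.1f x %.1f deg)\n",
    x$width_cm, x$height_cm, x$width_px, x$height_px, x$distance_cm,
    2 * ext$half_az, 2 * ext$half_el))
  invisible(x)
}

is_viewing_geometry <- function(x) inherits(x, "viewing_geometry")

#' Angular half-extent of the screen
#'
#' @param geom A [viewing_geometry()].
#' @return A list with `half_az` and `half_el`, the azimuth/elevation of the
#'   screen edges in degrees under the tangent mapping.
#' @export
screen_extent_deg <- function(geom) {
  stopifnot(is_viewing_geometry(geom))
  list(half_az = atan2(geom$width_cm / 2, geom$distance_cm) * 180 / pi,
       half_el = atan2(geom$height_cm / 2, geom$distance_cm) * 180 / pi)
}

#' Construct a direction table
#'
#' Directions are visual angles relative to straight ahead: positive azimuth
#' is rightward, positive elevation is upward. They are carried as plain
#' tibbles with columns `azimuth_deg` and `elevation_deg` so that traces and
#' other per-sample tables compose with the usual verbs.
#'
#' @param azimuth_deg,elevation_deg Numeric vectors of equal length, degrees.
#' @return A tibble with columns `azimuth_deg`, `elevation_deg`.
#' @export
direction <- function(azimuth_deg = 0, elevation_deg = 0) {
  d <- tibble::tibble(azimuth_deg = as.numeric(azimuth_deg),
                      elevation_deg = as.numeric(elevation_deg))
  check_direction(d)
  d
}

check_direction <- function(d) {
  if (!all(c("azimuth_deg", "elevation_deg") %in% names(d))) {
    stop("direction must have columns azimuth_deg and elevation_deg",
         call. = FALSE)
  }
  if (any(!is.finite(d$azimuth_deg)) || any(!is.finite(d$elevation_deg))) {
    stop("direction components must be finite", call. = FALSE)
  }
  if (any(abs(d$azimuth_deg) > 90) || any(abs(d$elevation_deg) > 90)) {
    stop("direction components must lie within +/-90 degrees", call. = FALSE)
  }
  invisible(d)
}

#' Construct a pose table (head direction + eye-in-head rotation)
#'
#' A pose holds the head (camera-mount) direction and the rotation of the eye
#' within the head, each a 2-DOF visual direction. Angular composition is
#' additive in degrees (small-angle approximation; task angles stay well
#' below 25 degrees). Torsion and eye translation are ignored.
#'
#' @param head_az,head_el Head direction, degrees.
#' @param eye_az,eye_el Eye-in-head rotation, degrees.
#' @return A tibble with columns `head_az`, `head_el`, `eye_az`, `eye_el`.
#' @export
#' @examples
#' pose(head_az = -15, eye_az = 15) |> gaze_direction()
pose <- function(head_az = 0, head_el = 0, eye_az = 0, eye_el = 0) {
  p <- tibble::tibble(head_az = as.numeric(head_az),
                      head_el = as.numeric(head_el),
                      eye_az = as.numeric(eye_az),
                      eye_el = as.numeric(eye_el))
  check_pose(p)
  p
}

check_pose <- function(p) {
  cols <- c("head_az", "head_el", "eye_az", "eye_el")
  if (!all(cols %in% names(p))) {
    stop("pose must have columns head_az, head_el, eye_az, eye_el",
         call. = FALSE)
  }
  vals <- as.matrix(p[cols])
  if (any(!is.finite(vals))) stop("pose components must be finite", call. = FALSE)
  if (any(abs(vals) > 90)) {
    stop("pose components must lie within +/-90 degrees", call. = FALSE)
  }
  invisible(p)
}

check_steering_mode <- function(mode) {
  if (!(is.character(mode) && length(mode) == 1 &&
        mode %in% c("full_gaze", "head_only"))) {
    stop('steering mode must be one of "full_gaze", "head_only"',
         call. = FALSE)
  }
  mode
}

#' Map screen pixel coordinates to visual directions
#'
#' Tangent-plane mapping with the screen center on the straight-ahead axis:
#' `azimuth = atan((x_cm - width_cm/2) / distance_cm)` and analogously for
#' elevation, with the vertical axis flipped so that positive elevation is
#' upward (pixel origin is top-left with y downward).
#'
#' @param points A data frame with columns `x_px`, `y_px` (continuous pixel
#'   coordinates; the screen spans `[0, width_px] x [0, height_px]`).
#' @param geom A [viewing_geometry()].
#' @return A direction tibble (`azimuth_deg`, `elevation_deg`).
#' @export
screen_to_deg <- function(points, geom) {
  stopifnot(is_viewing_geometry(geom))
  x <- points$x_px
  y <- points$y_px
  if (is.null(x) || is.null(y)) {
    stop("points must have columns x_px and y_px", call. = FALSE)
  }
  if (any(x < 0 | x > geom$width_px | y < 0 | y > geom$height_px)) {
    stop("point outside screen bounds", call. = FALSE)
  }
  px_to_deg(x, y, geom)
}

# unchecked tangent mapping, used internally where off-screen coordinates
# are meaningful (extended pixel grid); plain lists, no tibble overhead in
# the per-phosphene hot loops
px_to_deg_num <- function(x_px, y_px, geom) {
  x_cm <- x_px * (geom$width_cm / geom$width_px) - geom$width_cm / 2
  y_cm <- geom$height_cm / 2 - y_px * (geom$height_cm / geom$height_px)
  list(azimuth_deg = atan2(x_cm, geom$distance_cm) * 180 / pi,
       elevation_deg = atan2(y_cm, geom$distance_cm) * 180 / pi)
}

deg_to_px_num <- function(azimuth_deg, elevation_deg, geom) {
  x_cm <- geom$distance_cm * tan(azimuth_deg * pi / 180)
  y_cm <- geom$distance_cm * tan(elevation_deg * pi / 180)
  list(x_px = (x_cm + geom$width_cm / 2) * (geom$width_px / geom$width_cm),
       y_px = (geom$height_cm / 2 - y_cm) * (geom$height_px / geom$height_cm))
}

px_to_deg <- function(x_px, y_px, geom) {
  tibble::as_tibble(px_to_deg_num(x_px, y_px, geom))
}

deg_to_px <- function(azimuth_deg, elevation_deg, geom) {
  tibble::as_tibble(deg_to_px_num(azimuth_deg, elevation_deg, geom))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Map visual directions to screen pixel coordinates
#'
#' Exact inverse of [screen_to_deg()] up to the sub-pixel rounding policy
#' (round half away from zero when `round = TRUE`).
#'
#' @param dir A direction table (`azimuth_deg`, `elevation_deg`).
#' @param geom A [viewing_geometry()].
#' @param round Round to whole pixels? Default `FALSE` (continuous
#'   coordinates).
#' @return A tibble with columns `x_px`, `y_px`.
#' @export
deg_to_screen <- function(dir, geom, round = FALSE) {
  stopifnot(is_viewing_geometry(geom))
  check_direction(dir)
  p <- deg_to_px(dir$azimuth_deg, dir$elevation_deg, geom)
  off <- p$x_px < 0 | p$x_px > geom$width_px |
    p$y_px < 0 | p$y_px > geom$height_px
  if (any(off)) {
    clamped <- tibble::tibble(
      x_px = pmin(pmax(p$x_px, 0), geom$width_px),
      y_px = pmin(pmax(p$y_px, 0), geom$height_px)
    )
    cond <- structure(
      class = c("phosread_offscreen_error", "error", "condition"),
      list(message = "direction maps outside the screen extent",
           call = sys.call(-1), clamped = clamped[off, ])
    )
    stop(cond)
  }
  if (round) p <- tibble::tibble(x_px = round_half_away(p$x_px),
                                 y_px = round_half_away(p$y_px))
  p
}

#' Gaze direction of a pose
#'
#' Gaze is the componentwise sum of the head direction and the eye-in-head
#' rotation (small-angle additive composition).
#'
#' @param pose A pose table from [pose()].
#' @return A direction tibble.
#' @export
gaze_direction <- function(pose) {
  check_pose(pose)
  tibble::tibble(azimuth_deg = pose$head_az + pose$eye_az,
                 elevation_deg = pose$head_el + pose$eye_el)
}

#' Scene-camera direction under a steering mode
#'
#' Under `"full_gaze"` the simulated scene camera follows gaze (head + eye);
#' under `"head_only"` it follows the head alone, ignoring eye position --
#' the source of spatial incongruence in head-steered prostheses.
#'
#' @inheritParams gaze_direction
#' @param mode `"full_gaze"` or `"head_only"`.
#' @return A direction tibble.
#' @export
camera_direction <- function(pose, mode) {
  check_pose(pose)
  check_steering_mode(mode)
  if (mode == "full_gaze") {
    gaze_direction(pose)
  } else {
    tibble::tibble(azimuth_deg = pose$head_az, elevation_deg = pose$head_el)
  }
}

#' Gaze-camera incongruence
#'
#' The angular mismatch between where the eyes point and where the camera
#' points: `gaze - camera`. Identically zero under full-gaze steering; equal
#' to the eye-in-head rotation under head-only steering.
#'
#' @inheritParams camera_direction
#' @return A direction tibble of the componentwise mismatch.
#' @export
incongruence <- function(pose, mode) {
  g <- gaze_direction(pose)
  cam <- camera_direction(pose, mode)
  tibble::tibble(azimuth_deg = g$azimuth_deg - cam$azimuth_deg,
                 elevation_deg = g$elevation_deg - cam$elevation_deg)
}
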