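#' Brightness sampled by phosphenes from a reference image
#'
#' Each phosphene samples the reference image through a Gaussian aperture
#' centered where its retinotopic position lands along the camera axis:
#' a Gaussian-weighted mean of reference luminance over a window of radius
#' 3 sigma, with weights `exp(-d^2 / (2 sigma^2))` measured in degree space.
#' Regions of the window that fall off the screen contribute zero luminance
#' at full weight (off-screen is black).
#'
#' @param ref A [render_reference()] result.
#' @param camera A single-row direction table (the scene-camera axis).
#' @param phosphenes A [generate_field()] result or any tibble with columns
#'   `azimuth_deg`, `elevation_deg`, `sigma_deg`.
#' @param geom A [viewing_geometry()].
#' @return A numeric vector of brightness values in \[0, 1\], one per
#'   phosphene.
#' @export
phosphene_brightness <- function(ref, camera, phosphenes, geom) {
  stopifnot(inherits(ref, "rendered_text"), is_viewing_geometry(geom))
  check_direction(camera)
  stopifnot(nrow(camera) == 1)
  brightness_core(ref,
                  camera$azimuth_deg + phosphenes$azimuth_deg,
                  camera$elevation_deg + phosphenes$elevation_deg,
                  phosphenes$sigma_deg, geom)
}

# hot loop shared by the brightness/coverage paths: caz/cel are the sample
# centers (camera + retinotopic position) in degrees
brightness_core <- function(ref, caz, cel, sig, geom) {
  n <- length(caz)
  out <- numeric(n)
  if (n == 0) return(out)

  # conservative pixel bounds of the 3-sigma window (tangent is monotone)
  lo <- deg_to_px_num(pmax(caz - 3 * sig, -89.9), pmin(cel + 3 * sig, 89.9),
                      geom)
  hi <- deg_to_px_num(pmin(caz + 3 * sig, 89.9), pmax(cel - 3 * sig, -89.9),
                      geom)

  # ink block bounds in pixel coordinates: outside them luminance is 0
  bx0 <- ref$origin_px[["x"]]
  by0 <- ref$origin_px[["y"]]
  bx1 <- bx0 + ncol(ref$block)
  by1 <- by0 + nrow(ref$block)
  touches_ink <- hi$x_px > bx0 & lo$x_px < bx1 & hi$y_px > by0 & lo$y_px < by1

  for (i in which(touches_ink)) {
    cols <- floor(lo$x_px[i]):ceiling(hi$x_px[i])
    rows <- floor(lo$y_px[i]):ceiling(hi$y_px[i])
    if (length(cols) < 1 || length(rows) < 1) next
    d <- px_to_deg_num(rep(cols - 0.5, each = length(rows)),
                       rep(rows - 0.5, times = length(cols)), geom)
    d2 <- matrix((d$azimuth_deg - caz[i])^2 + (d$elevation_deg - cel[i])^2,
                 nrow = length(rows))
    w <- exp(-d2 / (2 * sig[i]^2))
    w[d2 > (3 * sig[i])^2] <- 0
    lum <- ref_luminance_at(ref, cols, rows)
    tot <- sum(w)
    if (tot > 0) out[i] <- sum(w * lum) / tot
  }
  # windows that never touch ink sample only black: brightness stays 0
  out
}

#' Pixel sigma of a phosphene at a live viewing distance
#'
#' The drawn blob must subtend `sigma_deg` at the current head-to-screen
#' distance; its pixel radius is therefore recomputed per frame as
#' `sigma_px = live_distance_cm * tan(sigma_deg) / cm_per_px`.
#'
#' @param sigma_deg Gaussian radius in degrees (vectorized).
#' @param geom A [viewing_geometry()].
#' @param live_distance_cm Current head-to-screen distance in cm.
#' @return Sigma in pixels.
#' @export
compensated_sigma_px <- function(sigma_deg, geom,
                                 live_distance_cm = geom$distance_cm) {
  stopifnot(is_viewing_geometry(geom))
  if (!is.finite(live_distance_cm) || live_distance_cm <= 0) {
    stop("live_distance_cm must be positive", call. = FALSE)
  }
  live_distance_cm * tan(sigma_deg * pi / 180) / geom$cm_per_px
}

#' Render one frame of simulated phosphene vision
#'
#' Sampling follows the camera axis (set by the steering mode), while the
#' display is locked to the retina: each phosphene is drawn as a Gaussian
#' blob at `gaze + retinotopic position` with peak `brightness * gain`.
#' Overlapping blobs combine by maximum, keeping luminance bounded.
#' Phosphenes whose centers map off the screen are skipped.
#'
#' @param field A [generate_field()] result.
#' @param ref A [render_reference()] result.
#' @param pose A single-row [pose()].
#' @param mode `"full_gaze"` or `"head_only"`.
#' @param geom A [viewing_geometry()].
#' @param live_distance_cm Per-frame head-to-screen distance for blob size
#'   compensation.
#' @param timestamp_ms Frame timestamp carried in the result.
#' @return A `phosphene_frame`: luminance matrix in \[0, 1\] at screen
#'   resolution plus the pose and mode that produced it.
#' @export
render_frame <- function(field, ref, pose, mode, geom,
                         live_distance_cm = geom$distance_cm,
                         timestamp_ms = 0) {
  check_pose(pose)
  stopifnot(nrow(pose) == 1)
  check_steering_mode(mode)
  cam <- camera_direction(pose, mode)
  gaze <- gaze_direction(pose)

  b <- phosphene_brightness(ref, cam, field, geom) * field$gain
  pos_px <- deg_to_px_num(gaze$azimuth_deg + field$azimuth_deg,
                          gaze$elevation_deg + field$elevation_deg, geom)
  sigma_px <- compensated_sigma_px(field$sigma_deg, geom, live_distance_cm)

  w <- geom$width_px
  h <- geom$height_px
  frame <- matrix(0, nrow = h, ncol = w)
  on_screen <- pos_px$x_px >= 0 & pos_px$x_px <= w &
    pos_px$y_px >= 0 & pos_px$y_px <= h
  for (i in which(on_screen & b > 0)) {
    r <- 3 * sigma_px[i]
    cols <- max(1L, floor(pos_px$x_px[i] - r)):min(w, ceiling(pos_px$x_px[i] + r))
    rows <- max(1L, floor(pos_px$y_px[i] - r)):min(h, ceiling(pos_px$y_px[i] + r))
    dx2 <- (cols - 0.5 - pos_px$x_px[i])^2
    dy2 <- (rows - 0.5 - pos_px$y_px[i])^2
    blob <- b[i] * exp(-outer(dy2, dx2, "+") / (2 * sigma_px[i]^2))
    patch <- frame[rows, cols, drop = FALSE]
    frame[rows, cols] <- pmax(patch, blob)
  }
  structure(list(luminance = frame, pose = pose, mode = mode,
                 timestamp_ms = timestamp_ms),
            class = "phosphene_frame")
}

#' @export
print.phosphene_frame <- function(x, ...) {
  cat(sprintf("<phosphene_frame> %d x %d px, mode %s, peak %.3f\n",
              ncol(x$luminance), nrow(x$luminance), x$mode, max(x$luminance)))
  invisible(x)
}

#' Export a phosphene frame as PNG
#'
#' @param frame A [render_frame()] result.
#' @param path Output file.
#' @param tint Optional RGB multipliers (length 3) for a light-blue
#'   phosphene look; rendering itself is grayscale.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path, tint = NULL) {
  lum <- frame$luminance
  if (is.null(tint)) {
    png::writePNG(lum, path)
  } else {
    stopifnot(length(tint) == 3)
    arr <- array(0, dim = c(nrow(lum), ncol(lum), 3))
    for (k in 1:3) arr[, , k] <- pmin(lum * tint[k], 1)
    png::writePNG(arr, path)
  }
  invisible(path)
}

#' Number of phosphenes activated by a stimulus
#'
#' A phosphene counts as activated when the brightness it samples along the
#' camera axis exceeds `threshold` (default 0.01 of full scale) and its
#' percept (at `gaze + position`) lands on the monitor.
#'
#' @param field A [generate_field()] result.
#' @param ref A [render_reference()] result.
#' @param camera,gaze Single-row direction tables.
#' @param geom A [viewing_geometry()].
#' @param threshold Activation threshold in \[0, 1).
#' @return Integer count.
#' @export
activated_count <- function(field, ref, camera = direction(0, 0),
                            gaze = camera, geom, threshold = 0.01) {
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  b <- phosphene_brightness(ref, camera, field, geom)
  pos_px <- deg_to_px_num(gaze$azimuth_deg + field$azimuth_deg,
                          gaze$elevation_deg + field$elevation_deg, geom)
  on_screen <- pos_px$x_px >= 0 & pos_px$x_px <= geom$width_px &
    pos_px$y_px >= 0 & pos_px$y_px <= geom$height_px
  sum(b > threshold & on_screen)
}

#' Per-word phosphene coverage of a rendered sentence
#'
#' For each word of the stimulus, counts the activated phosphenes whose
#' sampling center falls inside the word's tight glyph box, and normalizes
#' by the word's width expressed in x-height units. This coverage is the
#' legibility input of the synthetic observer.
#'
#' @inheritParams activated_count
#' @param word_idx Optional integer vector restricting the computation to
#'   those rows of `ref$words` (other rows return `NA`).
#' @return A tibble with one row per word: `line`, `word`, `n_activated`,
#'   `width_xh`, `coverage`.
#' @export
word_coverage <- function(field, ref, camera = direction(0, 0), geom,
                          threshold = 0.01, word_idx = NULL) {
  words <- ref$words
  stopifnot(nrow(words) > 0)
  caz <- camera$azimuth_deg + field$azimuth_deg
  cel <- camera$elevation_deg + field$elevation_deg
  pos_px <- deg_to_px_num(caz, cel, geom)
  out <- words[c("line", "word")]
  out$n_activated <- NA_integer_
  out$width_xh <- (words$x1 - words$x0) / ref$xheight_px
  if (is.null(word_idx)) word_idx <- seq_len(nrow(words))
  out$n_activated[word_idx] <- 0L
  for (i in word_idx) {
    inside <- which(pos_px$x_px >= words$x0[i] & pos_px$x_px <= words$x1[i] &
                      pos_px$y_px >= words$y0[i] & pos_px$y_px <= words$y1[i])
    if (length(inside) > 0) {
      b <- brightness_core(ref, caz[inside], cel[inside],
                           field$sigma_deg[inside], geom)
      out$n_activated[i] <- sum(b > threshold)
    }
  }
  out$coverage <- out$n_activated / pmax(out$width_xh, 0.5)
  tibble::as_tibble(out)
}
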