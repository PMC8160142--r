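#' Eccentricity-dependent phosphene spacing profile
#'
#' The simulated prosthesis places its electrodes at constant tissue density
#' in a retinotopically magnified structure, so phosphene spacing in the
#' visual field grows with eccentricity. The package uses the simplest such
#' law, linear growth of spacing with eccentricity:
#' `s(e) = s0_deg * (1 + e / e2_deg)`, where `s0_deg` is the foveal spacing
#' and `e2_deg` the eccentricity at which spacing has doubled.
#'
#' @param s0_deg Foveal phosphene spacing, degrees (> 0).
#' @param e2_deg Doubling eccentricity, degrees (> 0; `Inf` gives a uniform
#'   field).
#' @param emax_deg Maximum eccentricity of the field, degrees in (0, 90].
#' @return A `density_profile` object.
#' @export
density_profile <- function(s0_deg, e2_deg, emax_deg = 90) {
  if (!is.finite(s0_deg) || s0_deg <= 0) stop("s0_deg must be > 0", call. = FALSE)
  if (is.na(e2_deg) || e2_deg <= 0) stop("e2_deg must be > 0", call. = FALSE)
  if (!is.finite(emax_deg) || emax_deg <= 0 || emax_deg > 90) {
    stop("emax_deg must lie in (0, 90]", call. = FALSE)
  }
  structure(list(s0_deg = s0_deg, e2_deg = e2_deg, emax_deg = emax_deg),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> s0 = %.4g deg, e2 = %.4g deg, emax = %g deg\n",
              x$s0_deg, x$e2_deg, x$emax_deg))
  invisible(x)
}

#' Local phosphene spacing at an eccentricity
#'
#' @param profile A [density_profile()].
#' @param ecc_deg Eccentricity (degrees), vectorized; must lie in
#'   `[0, emax_deg]`.
#' @return Spacing in degrees, same length as `ecc_deg`.
#' @export
spacing_at <- function(profile, ecc_deg) {
  stopifnot(inherits(profile, "density_profile"))
  if (any(ecc_deg < 0 | ecc_deg > profile$emax_deg)) {
    stop("eccentricity outside [0, emax_deg]", call. = FALSE)
  }
  if (is.infinite(profile$e2_deg)) return(rep(profile$s0_deg, length(ecc_deg)))
  profile$s0_deg * (1 + ecc_deg / profile$e2_deg)
}

#' Expected phosphene count within a central disc
#'
#' Integrates the areal density `1 / s(e)^2` over a disc of radius `E` about
#' fixation: `integral 2*pi*e / s(e)^2 de`. For the linear spacing law this
#' has the closed form `2*pi*e2^2/s0^2 * (log U + 1/U - 1)` with
#' `U = 1 + E/e2`; the uniform limit (`e2 = Inf`) is `pi E^2 / s0^2`.
#'
#' @param profile A [density_profile()].
#' @param radius_deg Disc radius `E` in degrees, `<= emax_deg` (vectorized).
#' @return Expected (real-valued) count.
#' @export
expected_count <- function(profile, radius_deg) {
  stopifnot(inherits(profile, "density_profile"))
  if (any(radius_deg < 0 | radius_deg > profile$emax_deg)) {
    stop("radius outside [0, emax_deg]", call. = FALSE)
  }
  s0 <- profile$s0_deg
  e2 <- profile$e2_deg
  if (is.infinite(e2)) return(pi * radius_deg^2 / s0^2)
  U <- 1 + radius_deg / e2
  2 * pi * e2^2 / s0^2 * (log(U) + 1 / U - 1)
}

#' Calibrate a density profile from count constraints
#'
#' Solves for the `(s0, e2)` pair whose expected counts match a total count
#' over the whole field and a prescribed fraction within a central disc
#' (defaults: 2000 phosphenes, one quarter within the central 10 degrees,
#' i.e. a 5 degree radius, field extent 90 degrees). The central fraction
#' depends on `e2` only, so `e2` is found by bisection and `s0` follows in
#' closed form from the total.
#'
#' @param n_total Total expected phosphene count over the field.
#' @param central_fraction Fraction of phosphenes expected inside the central
#'   disc, in (0, 1).
#' @param r_central_deg Radius of the central disc, degrees (< `emax_deg`).
#' @param emax_deg Field extent, degrees.
#' @return A calibrated [density_profile()]; both constraint residuals are
#'   below 1e-6 in relative terms.
#' @export
#' @examples
#' prof <- calibrate_profile()
#' expected_count(prof, prof$emax_deg)       # ~2000
#' expected_count(prof, 5) / 2000            # ~0.25
calibrate_profile <- function(n_total = 2000, central_fraction = 0.25,
                              r_central_deg = 5, emax_deg = 90) {
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  if (central_fraction <= 0 || central_fraction >= 1) {
    stop("central_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (r_central_deg <= 0 || r_central_deg >= emax_deg) {
    stop("r_central_deg must lie in (0, emax_deg)", call. = FALSE)
  }
  shape <- function(U) log(U) + 1 / U - 1 # disc integral up to a constant
  frac_for_e2 <- function(e2) {
    shape(1 + r_central_deg / e2) / shape(1 + emax_deg / e2)
  }
  # fraction decreases monotonically with e2, from 1 (point-concentrated)
  # to the uniform area ratio (r/emax)^2
  lo <- 1e-6
  hi <- 1e9
  f_uniform <- (r_central_deg / emax_deg)^2
  if (abs(central_fraction - f_uniform) < 1e-9) {
    # area-proportional counts: the uniform limit (e2 -> Inf)
    return(density_profile(sqrt(pi * emax_deg^2 / n_total), Inf, emax_deg))
  }
  if (central_fraction <= f_uniform) {
    stop(sprintf(paste0(
      "infeasible central_fraction %.4g: a non-increasing density cannot put ",
      "less than the uniform area fraction %.4g inside the central disc"),
      central_fraction, f_uniform), call. = FALSE)
  }
  f <- function(e2) frac_for_e2(e2) - central_fraction
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)
  e2 <- root$root
  s0 <- sqrt(2 * pi * e2^2 * shape(1 + emax_deg / e2) / n_total)
  prof <- density_profile(s0, e2, emax_deg)
  res_total <- abs(expected_count(prof, emax_deg) - n_total) / n_total
  res_frac <- abs(expected_count(prof, r_central_deg) / n_total -
                    central_fraction) / central_fraction
  if (res_total > 1e-6 || res_frac > 1e-6) {
    stop("profile calibration failed to meet 1e-6 relative residuals",
         call. = FALSE)
  }
  prof
}

# inverse-CDF sampler of eccentricity under the areal density 1/s(e)^2
sample_eccentricity <- function(profile, n) {
  grid <- seq(0, profile$emax_deg, length.out = 4096)
  cdf <- expected_count(profile, grid)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, grid, xout = stats::runif(n), ties = "ordered")$y
}

#' Generate a center-weighted phosphene field
#'
#' Dart-throwing (blue-noise-like) placement: candidate positions are drawn
#' from the profile's areal density; a candidate at eccentricity `e` is kept
#' only if no previously accepted phosphene lies within `0.7 * s(e)`.
#' Each phosphene gets a Gaussian radius `sigma_deg = 0.3 * s(e)` and unit
#' gain. Generation is bit-reproducible for a fixed seed and profile.
#'
#' @param profile A calibrated [density_profile()].
#' @param n Number of phosphenes to place (default 2000).
#' @param seed Integer RNG seed.
#' @param min_dist_factor Exclusion radius as a multiple of the local
#'   spacing (default 0.7).
#' @param max_tries Candidate budget as a multiple of `n`.
#' @return A `phosphene_field`: a tibble with one row per phosphene and
#'   columns `azimuth_deg`, `elevation_deg`, `eccentricity_deg`, `sigma_deg`,
#'   `gain`, carrying the profile and seed as attributes.
#' @export
#' @examples
#' field <- generate_field(calibrate_profile(), n = 200, seed = 1)
#' nrow(field)
generate_field <- function(profile, n = 2000, seed = 1,
                           min_dist_factor = 0.7, max_tries = 500L) {
  stopifnot(inherits(profile, "density_profile"), n >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  az <- numeric(n)
  el <- numeric(n)
  ecc <- numeric(n)
  placed <- 0L
  budget <- as.integer(max_tries) * n
  batch <- max(256L, n)
  tried <- 0L
  while (placed < n && tried < budget) {
    m <- min(batch, budget - tried)
    e_cand <- sample_eccentricity(profile, m)
    th <- stats::runif(m, 0, 2 * pi)
    xc <- e_cand * cos(th)
    yc <- e_cand * sin(th)
    r_cand <- min_dist_factor * spacing_at(profile, e_cand)
    for (i in seq_len(m)) {
      tried <- tried + 1L
      if (placed > 0L) {
        d2 <- (az[seq_len(placed)] - xc[i])^2 + (el[seq_len(placed)] - yc[i])^2
        if (min(d2) < r_cand[i]^2) next
      }
      placed <- placed + 1L
      az[placed] <- xc[i]
      el[placed] <- yc[i]
      ecc[placed] <- e_cand[i]
      if (placed == n) break
    }
  }
  if (placed < n) {
    stop(sprintf(paste0(
      "placed only %d of %d phosphenes within the candidate budget; ",
      "consider a smaller min_dist_factor than %.2f"),
      placed, n, min_dist_factor), call. = FALSE)
  }
  out <- tibble::tibble(
    azimuth_deg = az,
    elevation_deg = el,
    eccentricity_deg = ecc,
    sigma_deg = 0.3 * spacing_at(profile, ecc),
    gain = 1
  )
  structure(out,
            profile = profile, seed = as.integer(seed),
            class = c("phosphene_field", class(out)))
}

field_profile <- function(field) attr(field, "profile")

#' Count phosphenes falling inside a degree-space rectangle
#'
#' The retinotopic pattern rides on gaze, so the screen-relative position of
#' a phosphene is its retinotopic position plus the gaze direction; `offset`
#' plays that role.
#'
#' @param field A [generate_field()] result.
#' @param rect A list/vector with `az_min`, `az_max`, `el_min`, `el_max`
#'   (degrees), e.g. [screen_rect_deg()].
#' @param offset A single-row direction table (gaze direction); default
#'   straight ahead.
#' @return Integer count.
#' @export
count_in_rect <- function(field, rect, offset = direction(0, 0)) {
  check_direction(offset)
  stopifnot(nrow(offset) == 1)
  az <- field$azimuth_deg + offset$azimuth_deg
  el <- field$elevation_deg + offset$elevation_deg
  sum(az >= rect$az_min & az <= rect$az_max &
        el >= rect$el_min & el <= rect$el_max)
}

#' Screen rectangle in degree space
#'
#' @param geom A [viewing_geometry()].
#' @return A list with `az_min`, `az_max`, `el_min`, `el_max` under the
#'   tangent mapping (about +/-23.2 x +/-13.5 degrees for the default
#'   geometry).
#' @export
screen_rect_deg <- function(geom) {
  ext <- screen_extent_deg(geom)
  list(az_min = -ext$half_az, az_max = ext$half_az,
       el_min = -ext$half_el, el_max = ext$half_el)
}

#' Theoretical acuity of a field region
#'
#' Characterizes local resolution as the mean nearest-neighbour
#' center-to-center spacing of the phosphenes in a region, expressed on the
#' logMAR scale: `log10(mean NN spacing in arcmin)`, so a 1 arcmin grid reads
#' 0.0 logMAR and a 10 arcmin grid 1.0 logMAR. Nearest neighbours are found
#' over the whole field, membership in the region selects which phosphenes
#' are averaged.
#'
#' @param field A [generate_field()] result.
#' @param r_outer_deg Outer radius of the region about fixation (degrees).
#' @param r_inner_deg Inner radius (default 0 for a disc; > 0 for an
#'   annulus).
#' @return Acuity in logMAR.
#' @export
theoretical_acuity <- function(field, r_outer_deg, r_inner_deg = 0) {
  ecc <- field$eccentricity_deg
  sel <- ecc >= r_inner_deg & ecc <= r_outer_deg
  if (sum(sel) < 2) {
    stop("fewer than 2 phosphenes in the region", call. = FALSE)
  }
  nn <- nearest_neighbour_dist(field$azimuth_deg, field$elevation_deg)
  log10(mean(nn[sel]) * 60)
}

# nearest-neighbour distances, chunked O(n^2)
nearest_neighbour_dist <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  chunk <- 256L
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Write / read a phosphene field as JSON
#'
#' Serializes the profile parameters, seed, and the per-phosphene table.
#'
#' @param field A [generate_field()] result.
#' @param path File path.
#' @return `write_field` returns `path` invisibly; `read_field` returns the
#'   field.
#' @export
write_field <- function(field, path) {
  prof <- field_profile(field)
  payload <- list(
    profile = list(s0_deg = prof$s0_deg, e2_deg = prof$e2_deg,
                   emax_deg = prof$emax_deg),
    seed = attr(field, "seed"),
    phosphenes = as.data.frame(field)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- density_profile(payload$profile$s0_deg, payload$profile$e2_deg,
                          payload$profile$emax_deg)
  out <- tibble::as_tibble(payload$phosphenes)
  structure(out, profile = prof, seed = payload$seed,
            class = c("phosphene_field", class(out)))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
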