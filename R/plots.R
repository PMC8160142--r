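#' Plot a phosphene field
#'
#' Dot plot of phosphene positions in the visual field, sized by their
#' Gaussian radius, with the monitor rectangle overlaid.
#'
#' @param object A [generate_field()] result.
#' @param geom A [viewing_geometry()] for the monitor outline (or `NULL`).
#' @param max_ecc_deg Plot limit in degrees.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phosphene_field
#' @export
autoplot.phosphene_field <- function(object, geom = viewing_geometry(),
                                     max_ecc_deg = 30, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$azimuth_deg,
                                        .data$elevation_deg)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$sigma_deg),
                        alpha = 0.5, colour = "#4477CC", stroke = 0) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::coord_equal(xlim = c(-max_ecc_deg, max_ecc_deg),
                         ylim = c(-max_ecc_deg, max_ecc_deg)) +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  title = "Phosphene field (retinotopic)") +
    ggplot2::theme_minimal()
  if (!is.null(geom)) {
    r <- screen_rect_deg(geom)
    p <- p + ggplot2::annotate("rect", xmin = r$az_min, xmax = r$az_max,
                               ymin = r$el_min, ymax = r$el_max,
                               fill = NA, colour = "grey30",
                               linetype = "dashed")
  }
  p
}

#' Plot population psychometric curves
#'
#' Median lines with 16/84 percentile ribbons per viewing condition,
#' faceted by metric (reading accuracy and speed), mirroring the standard
#' presentation of reading-performance data.
#'
#' @param object A [psychometric_curves()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psychometric_curve
#' @export
autoplot.psychometric_curve <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      metric = dplyr::recode(.data$metric,
                                             accuracy_pct = "reading accuracy (%)",
                                             speed_wpm = "reading speed (WPM)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$logmar, .data$median,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$median - .data$lower,
                                      ymax = .data$median + .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(normal = "grey15", full_gaze = "#C03030",
                 head_only = "#E08020"), aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "print size (logMAR)", y = NULL,
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot an equivalent-acuity fit
#'
#' @param object An [fit_equivalent_acuity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acuity_fit
#' @export
autoplot.acuity_fit <- function(object, ...) {
  grid <- tibble::tibble(
    logmar = seq(min(object$sizes) - 0.1, max(object$sizes) + 0.1,
                 length.out = 200))
  grid$fit <- logistic100(grid$logmar, object$midpoint_logmar, object$slope)
  pts <- tibble::tibble(logmar = object$sizes, accuracy = object$accuracies)
  ggplot2::ggplot(pts, ggplot2::aes(.data$logmar, .data$accuracy)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "#C03030") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$midpoint_logmar,
                        linetype = "dotted") +
    ggplot2::labs(x = "print size (logMAR)", y = "reading accuracy (%)",
                  title = sprintf("equivalent acuity %.2f logMAR",
                                  object$midpoint_logmar)) +
    ggplot2::theme_minimal()
}

#' Plot gaze and head traces of a trial
#'
#' Side-by-side spatial traces (start marked with an open, end with a
#' filled point), the usual way single-trial scanning behavior is shown.
#'
#' @param record A one-row trial record with stored traces.
#' @return A ggplot object.
#' @export
plot_traces <- function(record) {
  gz <- record$gaze_trace[[1]]
  hd <- record$head_trace[[1]]
  if (is.null(gz) || is.null(hd)) {
    stop("trial record has no stored traces (store_traces = FALSE?)",
         call. = FALSE)
  }
  df <- dplyr::bind_rows(
    dplyr::mutate(gz, what = "gaze"),
    dplyr::mutate(hd, what = "head")
  )
  ends <- dplyr::slice_tail(dplyr::group_by(df, .data$what), n = 1)
  starts <- dplyr::slice_head(dplyr::group_by(df, .data$what), n = 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$azimuth_deg, .data$elevation_deg)) +
    ggplot2::geom_path(alpha = 0.7, colour = "#4477CC") +
    ggplot2::geom_point(data = starts, shape = 1, size = 2.5) +
    ggplot2::geom_point(data = ends, shape = 16, size = 2.5) +
    ggplot2::facet_wrap(~what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}
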