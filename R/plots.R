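#' Plot transmural inclination-angle profiles
#'
#' Inclination angle versus wall depth from the epicardium for a set of
#' segments, with the fitted regression line per segment - the profile view
#' in which infarct thinning appears as a steepened slope.
#'
#' @param voxels a [voxel_table()] (optionally pre-filtered).
#' @param segment_ids segments to show (default: up to 12 with most voxels).
#' @return A ggplot object.
#' @export
plot_transmural_profile <- function(voxels, segment_ids = NULL) {
  dat <- dplyr::filter(voxels, .data$valid, is.finite(.data$inclination_deg))
  if (is.null(segment_ids)) {
    segment_ids <- dat |>
      dplyr::count(.data$segment_id, sort = TRUE) |>
      dplyr::slice_head(n = 12) |>
      dplyr::pull(.data$segment_id)
  }
  dat <- dplyr::filter(dat, .data$segment_id %in% segment_ids)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$depth_mm,
                                    y = .data$inclination_deg)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "firebrick") +
    ggplot2::facet_wrap(~segment_id) +
    ggplot2::labs(x = "depth from epicardium (mm)",
                  y = "inclination angle (deg)") +
    ggplot2::theme_minimal()
}

#' Short-axis map of a scalar volume
#'
#' Raster view of one z-slice of an angle or scalar map (NA transparent).
#'
#' @param vol 3-D array.
#' @param slice z index (middle slice by default).
#' @param name legend title.
#' @return A ggplot object.
#' @export
plot_slice_map <- function(vol, slice = NULL, name = "value") {
  if (is.null(slice)) slice <- round(dim(vol)[3] / 2)
  sl <- vol[, , slice]
  dat <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  dat$value <- sl[cbind(dat$x, dat$y)]
  ggplot2::ggplot(dat[is.finite(dat$value), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::theme_void()
}

#' @export
#' @rdname plot_group_comparison
autoplot.group_comparison <- function(object, ...) plot_group_comparison(object)

#' Plot a group comparison
#'
#' Dot-and-error (mean +/- SD) view of every metric, infarcted versus
#' control, faceted on free scales.
#'
#' @param object a [summarize_groups()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_infarcted", "mean_control"),
                        names_to = "group", names_prefix = "mean_",
                        values_to = "mean") |>
    dplyr::mutate(sd = ifelse(.data$group == "infarcted",
                              .data$sd_infarcted, .data$sd_control))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_uncertainty_curve
autoplot.uncertainty_curve <- function(object, ...) plot_uncertainty_curve(object)

#' Plot eigenvector-uncertainty curves
#'
#' Mean angular deviation of the fitted primary eigenvector versus SNR, one
#' line per FA condition.
#'
#' @param object an [uncertainty_curve()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_uncertainty_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$snr,
                                       y = .data$mean_deviation_deg,
                                       colour = factor(.data$fa))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "SNR", y = "mean angular deviation (deg)",
                  colour = "FA") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
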