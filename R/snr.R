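#' Measure image SNR from tissue and background regions
#'
#' SNR = mean(tissue signal) / sigma, with the noise standard deviation
#' estimated from a signal-free background region of the magnitude image.
#' Background magnitudes of complex Gaussian noise are Rayleigh distributed,
#' whose standard deviation is sigma * sqrt(2 - pi/2) = 0.6551 sigma, so
#' sigma = sd(background) / 0.6551.
#'
#' @param b0 3-D array, the non-diffusion-weighted magnitude volume.
#' @param tissue_mask,background_mask disjoint, nonempty logical arrays.
#' @return An `snr_report`: list with `mean_signal`, `noise_sigma`, `snr`
#'   and `roi_labels`. If the background has zero variance the SNR is
#'   undefined (NA) and a warning is raised.
#' @export
measure_snr <- function(b0, tissue_mask, background_mask) {
  if (!any(tissue_mask) || !any(background_mask))
    stop("both masks must be nonempty")
  if (any(tissue_mask & background_mask))
    stop("tissue and background masks must be disjoint")
  mean_signal <- mean(b0[tissue_mask])
  bg_sd <- sd(b0[background_mask])
  rayleigh <- sqrt(2 - pi / 2)
  if (!is.finite(bg_sd) || bg_sd == 0) {
    warning("zero-variance background: SNR undefined")
    sigma <- NA_real_
  } else {
    sigma <- bg_sd / rayleigh
  }
  structure(list(mean_signal = mean_signal, noise_sigma = sigma,
                 snr = mean_signal / sigma,
                 roi_labels = c(tissue = sum(tissue_mask),
                                background = sum(background_mask))),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> mean signal %.3g / sigma %.3g = SNR %.1f (%d tissue, %d background voxels)\n",
              x$mean_signal, x$noise_sigma, x$snr,
              x$roi_labels["tissue"], x$roi_labels["background"]))
  invisible(x)
}
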