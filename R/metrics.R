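#' Scar transmurality of a segment
#'
#' Ratio of the number of fibrotic voxels (from the LGE channel) in a
#' transmural segment to the total number of voxels in the segment.
#'
#' @param n_fibrotic,n_voxels voxel counts (vectorized).
#' @return Fraction in [0, 1]; NA for empty segments.
#' @export
scar_transmurality <- function(n_fibrotic, n_voxels) {
  ifelse(n_voxels >= 1, n_fibrotic / n_voxels, NA_real_)
}

#' Linear fit of the transmural inclination-angle profile
#'
#' Ordinary least-squares line of inclination angle versus wall depth
#' measured from the epicardium, returning the slope (degrees/mm), the
#' intercept (degrees, the extrapolated epicardial angle) and R-squared.
#' Requires at least `min_voxels` voxels spanning at least two distinct
#' depths.
#'
#' @param inclination_deg angle values, degrees.
#' @param depth_mm depths from the epicardium, mm.
#' @param min_voxels reliability bound on the profile size.
#' @return A `transmural_fit` object (list with `slope`, `intercept`, `r2`,
#'   `n`); components are NA when the profile is degenerate.
#' @export
#' @examples
#' d <- seq(0, 7, by = 0.5)
#' fit <- transmural_profile_fit(-60 + 16.07 * d, d)
#' c(fit$slope, fit$intercept, fit$r2)
transmural_profile_fit <- function(inclination_deg, depth_mm, min_voxels = 4L) {
  keep <- is.finite(inclination_deg) & is.finite(depth_mm)
  y <- inclination_deg[keep]; x <- depth_mm[keep]
  out <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
              n = length(y))
  if (length(y) >= min_voxels && length(unique(x)) >= 2L) {
    fit <- stats::.lm.fit(cbind(1, x), y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    out$slope <- fit$coefficients[2]
    out$intercept <- fit$coefficients[1]
    out$r2 <- if (sst > 0) max(0, 1 - ssr / sst) else 0
  }
  structure(out, class = "transmural_fit")
}

#' @export
print.transmural_fit <- function(x, ...) {
  cat(sprintf("<transmural_fit> slope %.2f deg/mm, intercept %.1f deg, r2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Inclination-angle range of a segment
#'
#' The [1-99]\% range of the within-segment inclination-angle distribution
#' (99th minus 1st percentile, linear-interpolation percentiles), a measure
#' of the epi-to-endo angle span robust to outlier voxels.
#'
#' @param inclination_deg angle values, degrees.
#' @param min_voxels minimum sample size.
#' @return Range in degrees (>= 0), or NA below `min_voxels`.
#' @export
inclination_range <- function(inclination_deg, min_voxels = 4L) {
  v <- inclination_deg[is.finite(inclination_deg)]
  if (length(v) < min_voxels) return(NA_real_)
  q <- quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Handedness ratios of a segment
#'
#' Fractions of voxels with left-handed (inclination < -15 deg),
#' circumferential (|inclination| <= 15 deg) and right-handed
#' (inclination > 15 deg) fiber orientation. Boundary values of exactly
#' +/-15 degrees are assigned to the circumferential class; the three
#' fractions sum to one.
#'
#' @param inclination_deg angle values, degrees.
#' @return Named numeric vector `c(lh, circ, rh)`; NA if no valid voxels.
#' @export
handedness_ratios <- function(inclination_deg) {
  v <- inclination_deg[is.finite(inclination_deg)]
  if (length(v) == 0) return(c(lh = NA_real_, circ = NA_real_, rh = NA_real_))
  c(lh = mean(v < -15), circ = mean(v >= -15 & v <= 15), rh = mean(v > 15))
}

#' Mean imbrication angle of a segment
#'
#' Arithmetic mean of the signed imbrication angles; close to zero when the
#' eigenvectors run parallel to the wall.
#'
#' @param imbrication_deg angle values, degrees.
#' @return Mean in degrees; NA if no valid voxels.
#' @export
imbrication_mean <- function(imbrication_deg) {
  v <- imbrication_deg[is.finite(imbrication_deg)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Intervoxel angle incoherency per segment
#'
#' Over all 6-connected voxel pairs lying in the same segment, the mean
#' acute angular difference min(|d|, 180 - |d|) of the angle map - a proxy
#' for local fiber disarray, computed separately for the inclination and
#' imbrication maps.
#'
#' @param angle_deg 3-D array of angles, degrees (NA where invalid).
#' @param labels integer segment-label array (NA outside segments), as from
#'   [partition_lv_segments()].
#' @return A tibble: `segment_id`, `incoherency_deg`, `n_pairs`. Segments
#'   without any in-segment neighbour pair are absent (undefined).
#' @export
angle_incoherency <- function(angle_deg, labels) {
  stopifnot(all(dim(angle_deg) == dim(labels)))
  pair_list <- list()
  for (axis in 1:3) {
    nb_ang <- shift3(angle_deg, axis, 1L, NA_real_)
    nb_lab <- shift3(labels, axis, 1L, NA_integer_)
    keep <- !is.na(labels) & !is.na(nb_lab) & labels == nb_lab &
      is.finite(angle_deg) & is.finite(nb_ang)
    if (any(keep)) {
      dd <- abs(angle_deg[keep] - nb_ang[keep])
      pair_list[[axis]] <- tibble::tibble(segment_id = labels[keep],
                                          diff = pmin(dd, 180 - dd))
    }
  }
  if (length(pair_list) == 0)
    return(tibble::tibble(segment_id = integer(), incoherency_deg = double(),
                          n_pairs = integer()))
  dplyr::bind_rows(pair_list) |>
    dplyr::summarise(incoherency_deg = mean(.data$diff),
                     n_pairs = dplyr::n(), .by = "segment_id")
}

#' Voxel-level table of a segmented heart
#'
#' Joins segment labels, wall depth, fiber angles and the fibrosis mask into
#' one tibble with a row per labeled wall voxel - the tidy substrate for
#' [segment_metrics()].
#'
#' @param segments an [partition_lv_segments()] object.
#' @param angles an [angle_maps()] object.
#' @param depth a [wall_depth()] object.
#' @param fibrosis_mask optional logical array.
#' @param tensor_valid optional logical array of per-voxel tensor validity.
#' @return A tibble with columns `segment_id`, `inclination_deg`,
#'   `imbrication_deg`, `depth_mm`, `depth_norm`, `fibrotic`, `valid`.
#' @export
voxel_table <- function(segments, angles, depth, fibrosis_mask = NULL,
                        tensor_valid = NULL) {
  w <- which(!is.na(segments$labels))
  tibble::tibble(
    segment_id = segments$labels[w],
    inclination_deg = angles$inclination_deg[w],
    imbrication_deg = angles$imbrication_deg[w],
    depth_mm = depth$depth_mm[w],
    depth_norm = depth$depth_norm[w],
    fibrotic = if (is.null(fibrosis_mask)) FALSE else fibrosis_mask[w],
    valid = (if (is.null(tensor_valid)) TRUE else tensor_valid[w]) &
      !angles$undefined[w])
}

#' Per-segment structural remodeling metrics
#'
#' Computes the nine per-segment metrics - wall thickness, scar
#' transmurality, transmural inclination slope/intercept/r2, inclination
#' range, imbrication mean, handedness ratios - plus the inclination and
#' imbrication incoherencies, by delegating to the individual metric
#' functions. Angle statistics use valid voxels only; segments with wall
#' thickness below 2 mm or fewer than `min_voxels` valid transmural voxels
#' are flagged excluded and carry NA metrics.
#'
#' @param records segment records from [classify_segments()].
#' @param voxels a [voxel_table()].
#' @param thickness a [segment_wall_thickness()] table.
#' @param incoherency_inc,incoherency_imb [angle_incoherency()] tables for
#'   the two angle maps.
#' @param min_voxels minimum valid voxels per fitted profile.
#' @return A tibble, one row per segment: record keys, `excluded`, and all
#'   metric columns (`thickness_mm`, `transmurality`, `slope_deg_per_mm`,
#'   `intercept_deg`, `r2`, `inclination_range_deg`, `imbrication_mean_deg`,
#'   `lh_ratio`, `circ_ratio`, `rh_ratio`, `inclination_incoherency_deg`,
#'   `imbrication_incoherency_deg`, `n_voxels_used`).
#' @export
segment_metrics <- function(records, voxels, thickness,
                            incoherency_inc = NULL, incoherency_imb = NULL,
                            min_voxels = 4L) {
  per_seg <- voxels |>
    dplyr::filter(.data$valid) |>
    dplyr::summarise(
      n_voxels_used = dplyr::n(),
      fit = list(transmural_profile_fit(.data$inclination_deg,
                                        .data$depth_mm, min_voxels)),
      inclination_range_deg = inclination_range(.data$inclination_deg,
                                                min_voxels),
      imbrication_mean_deg = imbrication_mean(.data$imbrication_deg),
      hand = list(handedness_ratios(.data$inclination_deg)),
      .by = "segment_id") |>
    dplyr::mutate(
      slope_deg_per_mm = vapply(.data$fit, `[[`, 0, "slope"),
      intercept_deg = vapply(.data$fit, `[[`, 0, "intercept"),
      r2 = vapply(.data$fit, `[[`, 0, "r2"),
      lh_ratio = vapply(.data$hand, `[[`, 0, "lh"),
      circ_ratio = vapply(.data$hand, `[[`, 0, "circ"),
      rh_ratio = vapply(.data$hand, `[[`, 0, "rh"),
      fit = NULL, hand = NULL)
  out <- records |>
    dplyr::left_join(thickness[, c("segment_id", "thickness_mm", "excluded")],
                     by = "segment_id") |>
    dplyr::left_join(per_seg, by = "segment_id") |>
    dplyr::mutate(
      transmurality = scar_transmurality(.data$n_fibrotic_voxels,
                                         .data$n_voxels),
      n_voxels_used = dplyr::coalesce(.data$n_voxels_used, 0L),
      excluded = dplyr::coalesce(.data$excluded, TRUE) |
        .data$n_voxels_used < min_voxels)
  if (!is.null(incoherency_inc))
    out <- dplyr::left_join(
      out, dplyr::rename(incoherency_inc,
                         inclination_incoherency_deg = "incoherency_deg")[,
        c("segment_id", "inclination_incoherency_deg")], by = "segment_id")
  else out$inclination_incoherency_deg <- NA_real_
  if (!is.null(incoherency_imb))
    out <- dplyr::left_join(
      out, dplyr::rename(incoherency_imb,
                         imbrication_incoherency_deg = "incoherency_deg")[,
        c("segment_id", "imbrication_incoherency_deg")], by = "segment_id")
  else out$imbrication_incoherency_deg <- NA_real_
  metric_cols <- c("slope_deg_per_mm", "intercept_deg", "r2",
                   "inclination_range_deg", "imbrication_mean_deg",
                   "lh_ratio", "circ_ratio", "rh_ratio",
                   "inclination_incoherency_deg", "imbrication_incoherency_deg")
  out[out$excluded, metric_cols] <- NA_real_
  out
}
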