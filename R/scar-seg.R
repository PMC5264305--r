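#' Otsu threshold of an intensity sample
#'
#' Two-class Otsu threshold: the cut maximizing the between-class variance
#' w0 w1 (mu0 - mu1)^2 over a 256-bin histogram of the supplied values.
#' A two-threshold multi-level mode (`levels = 3`) is available in case the
#' intensity distribution has an intermediate class; the returned value is
#' then the upper threshold.
#'
#' @param values numeric vector (e.g. wall-voxel LGE intensities).
#' @param n_bins histogram bins.
#' @param levels 2 (default) or 3 classes.
#' @return The threshold value, or NA (with a warning) for a degenerate
#'   (constant) sample.
#' @export
otsu_threshold <- function(values, n_bins = 256L, levels = 2L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("constant intensities: no Otsu threshold")
    return(NA_real_)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  counts <- as.numeric(tabulate(findInterval(values, breaks,
                                             rightmost.closed = TRUE),
                                nbins = n_bins))
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]; mtot <- m[n_bins]
  if (levels == 2L) {
    w0 <- w[-n_bins]; m0 <- m[-n_bins]
    w1 <- n - w0
    valid <- w0 > 0 & w1 > 0
    bcv <- rep(-Inf, n_bins - 1L)
    bcv[valid] <- (mtot * w0[valid] - n * m0[valid])^2 /
      (w0[valid] * w1[valid])
    breaks[which.max(bcv) + 1L]
  } else if (levels == 3L) {
    best <- c(-Inf, NA, NA)
    for (k1 in 1:(n_bins - 2L)) for (k2 in (k1 + 1L):(n_bins - 1L)) {
      w0 <- w[k1]; w1 <- w[k2] - w[k1]; w2 <- n - w[k2]
      if (w0 == 0 || w1 == 0 || w2 == 0) next
      mu0 <- m[k1] / w0; mu1 <- (m[k2] - m[k1]) / w1; mu2 <- (mtot - m[k2]) / w2
      mu <- mtot / n
      bcv <- w0 * (mu0 - mu)^2 + w1 * (mu1 - mu)^2 + w2 * (mu2 - mu)^2
      if (bcv > best[1]) best <- c(bcv, k1, k2)
    }
    breaks[best[3] + 1L]
  } else stop("levels must be 2 or 3")
}

#' Segment fibrosis from the LGE channel
#'
#' Two-class Otsu thresholding computed over wall voxels only; voxels above
#' the threshold are classified fibrotic (enhanced). Follow with
#' [refine_mask()] for the morphological cleanup standing in for the
#' interactive level-set step of manual workflows.
#'
#' @param lge numeric 3-D array of LGE intensities.
#' @param lv_mask logical wall mask.
#' @param levels passed to [otsu_threshold()].
#' @return Logical fibrosis mask (with the threshold attached as attribute
#'   `"threshold"`); empty with a warning if the wall histogram is
#'   degenerate.
#' @export
otsu_fibrosis_mask <- function(lge, lv_mask, levels = 2L) {
  if (!any(lv_mask)) stop("empty wall mask")
  thr <- otsu_threshold(lge[lv_mask], levels = levels)
  out <- array(FALSE, dim(lv_mask))
  if (!is.na(thr)) out[lv_mask & lge > thr] <- TRUE
  attr(out, "threshold") <- thr
  out
}

#' Morphological refinement of a binary fibrosis mask
#'
#' Deterministic cleanup: 6-connected closing (radius 1) then opening, then
#' removal of connected components smaller than `min_voxels`.
#'
#' @param mask logical 3-D array.
#' @param min_voxels smallest component retained.
#' @return Refined logical mask.
#' @export
refine_mask <- function(mask, min_voxels = 10L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) return(mask)
  m <- erode6(dilate6(mask))        # closing
  m <- dilate6(erode6(m))           # opening
  if (!any(m)) return(m)
  lab <- label_components6(m)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

#' Partition the LV wall into transmural polar segments
#'
#' For each short-axis slab of `slab_thickness_mm`, a polar coordinate
#' system with origin at the blood-pool centroid divides the wall
#' circumferentially into 36 segments of 10 degrees each (angle measured
#' counterclockwise from +x). Apical slabs - those without blood pool plus
#' the apical `apical_fraction` of the wall's long-axis extent - are
#' excluded.
#'
#' @param lv_mask,blood_mask logical arrays.
#' @param voxel_size_mm voxel spacing, mm.
#' @param slab_thickness_mm short-axis slab thickness.
#' @param angle_bin_deg angular bin width (36 bins at the default 10).
#' @param apical_fraction apical fraction of the long-axis extent excluded.
#' @return An `lv_segments` object: integer `labels` array (NA outside
#'   included wall), logical `excluded` array, and a tibble `meta` with one
#'   row per (slab, bin): `segment_id`, `slice_index`, `angular_bin`,
#'   `origin_x/y_mm`, `z_mid_mm`, `theta_mid_deg`.
#' @export
partition_lv_segments <- function(lv_mask, blood_mask, voxel_size_mm = c(1, 1, 1),
                                  slab_thickness_mm = 1.2,
                                  angle_bin_deg = 10,
                                  apical_fraction = 0.1) {
  if (!any(blood_mask)) stop("no blood pool found on any slice")
  n_bins <- as.integer(round(360 / angle_bin_deg))
  ax <- voxel_coords(dim(lv_mask), voxel_size_mm)
  wall_z <- range(ax$z[apply(lv_mask, 3, any)])
  extent <- diff(wall_z) + voxel_size_mm[3]
  z_lo <- wall_z[1] - voxel_size_mm[3] / 2        # apex end of the wall
  slab_of_slice <- floor((ax$z - z_lo) / slab_thickness_mm)
  apex_cut <- z_lo + apical_fraction * extent
  d <- dim(lv_mask)
  labels <- array(NA_integer_, d)
  excluded <- lv_mask
  meta <- list()
  for (s in sort(unique(slab_of_slice[ax$z >= z_lo & ax$z <= wall_z[2] + 1e-9]))) {
    slices <- which(slab_of_slice == s)
    slab_lo <- z_lo + s * slab_thickness_mm
    blood <- blood_mask[, , slices, drop = FALSE]
    if (slab_lo < apex_cut || !any(blood)) next   # apical / no blood pool
    wb <- which(blood, arr.ind = TRUE)
    origin <- c(mean(ax$x[wb[, 1]]), mean(ax$y[wb[, 2]]))
    wall <- lv_mask[, , slices, drop = FALSE]
    ww <- which(wall, arr.ind = TRUE)
    if (nrow(ww) == 0) next
    theta <- (atan2(ax$y[ww[, 2]] - origin[2],
                    ax$x[ww[, 1]] - origin[1]) * 180 / pi) %% 360
    bin <- pmin(floor(theta / angle_bin_deg), n_bins - 1L)
    seg <- s * n_bins + bin
    lin <- cbind(ww[, 1], ww[, 2], slices[ww[, 3]])
    labels[lin] <- as.integer(seg)
    excluded[lin] <- FALSE
    meta[[length(meta) + 1L]] <- tibble::tibble(
      slice_index = s, angular_bin = 0:(n_bins - 1L),
      segment_id = s * n_bins + 0:(n_bins - 1L),
      origin_x_mm = origin[1], origin_y_mm = origin[2],
      z_mid_mm = slab_lo + slab_thickness_mm / 2,
      theta_mid_deg = (0:(n_bins - 1L) + 0.5) * angle_bin_deg)
  }
  if (length(meta) == 0) stop("no included slabs: blood pool missing everywhere")
  structure(list(labels = labels, excluded = excluded,
                 meta = dplyr::bind_rows(meta),
                 n_bins = n_bins, angle_bin_deg = angle_bin_deg,
                 slab_thickness_mm = slab_thickness_mm,
                 voxel_size_mm = voxel_size_mm),
            class = "lv_segments")
}

#' @export
print.lv_segments <- function(x, ...) {
  cat(sprintf("<lv_segments> %d slabs x %d bins; %d wall voxels labeled, %d excluded\n",
              length(unique(x$meta$slice_index)), x$n_bins,
              sum(!is.na(x$labels)), sum(x$excluded)))
  invisible(x)
}

#' Classify segments as infarcted, control or other
#'
#' For infarcted hearts, a segment is infarcted iff it contains at least one
#' fibrotic voxel on the LGE-derived mask. For control hearts, segments
#' whose angular midpoint falls inside the configured anteroseptal span
#' (180 degrees by default) are labeled control.
#'
#' @param segments an [partition_lv_segments()] object.
#' @param fibrosis_mask logical array (required for infarcted hearts).
#' @param heart_type `"infarcted"` or `"control"`.
#' @param control_span_deg angular interval of control segments, within
#'   [0, 360].
#' @param heart_id identifier copied into the records.
#' @return A tibble of segment records: `heart_id`, `segment_id`,
#'   `slice_index`, `angular_bin`, `status`, `n_voxels`,
#'   `n_fibrotic_voxels`.
#' @export
classify_segments <- function(segments, fibrosis_mask = NULL,
                              heart_type = c("infarcted", "control"),
                              control_span_deg = c(0, 180),
                              heart_id = "heart") {
  heart_type <- match.arg(heart_type)
  if (any(control_span_deg < 0) || any(control_span_deg > 360))
    stop("control span must lie within [0, 360]")
  lab <- segments$labels
  inside <- !is.na(lab)
  counts <- tibble::tibble(segment_id = lab[inside]) |>
    dplyr::count(.data$segment_id, name = "n_voxels")
  if (!is.null(fibrosis_mask)) {
    fib <- tibble::tibble(segment_id = lab[inside],
                          fib = fibrosis_mask[inside]) |>
      dplyr::summarise(n_fibrotic_voxels = sum(.data$fib),
                       .by = "segment_id")
  } else {
    fib <- tibble::tibble(segment_id = counts$segment_id,
                          n_fibrotic_voxels = 0L)
  }
  rec <- segments$meta |>
    dplyr::inner_join(counts, by = "segment_id") |>
    dplyr::left_join(fib, by = "segment_id") |>
    dplyr::mutate(
      n_fibrotic_voxels = dplyr::coalesce(.data$n_fibrotic_voxels, 0L),
      status = dplyr::case_when(
        heart_type == "infarcted" & .data$n_fibrotic_voxels >= 1L ~ "infarcted",
        heart_type == "control" &
          .data$theta_mid_deg >= control_span_deg[1] &
          .data$theta_mid_deg <= control_span_deg[2] ~ "control",
        TRUE ~ "other"),
      heart_id = heart_id)
  rec[, c("heart_id", "segment_id", "slice_index", "angular_bin",
          "status", "n_voxels", "n_fibrotic_voxels")]
}

#' Per-segment wall thickness by ray casting
#'
#' For each segment, rays are cast from the slab origin at 1-degree steps
#' within the angular bin; per ray the wall thickness is the epicardial
#' minus endocardial radial intersection length with the
#' nearest-neighbour-sampled wall mask, and the segment value is the mean
#' over rays that hit the wall. Segments thinner than
#' `min_thickness_mm` are flagged excluded.
#'
#' @param segments an [partition_lv_segments()] object.
#' @param lv_mask logical wall mask.
#' @param min_thickness_mm exclusion threshold, mm (2 mm default).
#' @param ray_step_deg angular spacing of rays within a bin.
#' @return A tibble: `segment_id`, `thickness_mm`, `n_rays`, `excluded`.
#' @export
segment_wall_thickness <- function(segments, lv_mask,
                                   min_thickness_mm = 2,
                                   ray_step_deg = 1) {
  vs <- segments$voxel_size_mm
  ax <- voxel_coords(dim(lv_mask), vs)
  d <- dim(lv_mask)
  r_max <- sqrt(max(abs(ax$x))^2 + max(abs(ax$y))^2)
  r_step <- min(vs[1:2]) / 4
  radii <- seq(r_step / 2, r_max, by = r_step)
  slabs <- segments$meta |>
    dplyr::distinct(.data$slice_index, .data$origin_x_mm, .data$origin_y_mm,
                    .data$z_mid_mm)
  has_wall <- apply(lv_mask, 3, any)
  st <- segments$slab_thickness_mm
  out <- vector("list", nrow(slabs))
  for (i in seq_len(nrow(slabs))) {
    sl <- slabs[i, ]
    # wall-bearing slice nearest the slab midplane (a partial end slab's
    # midplane can fall on an empty slice)
    cand <- which(has_wall & abs(ax$z - sl$z_mid_mm) <= st / 2 + 1e-9)
    if (length(cand) == 0) cand <- which(has_wall)
    k <- cand[which.min(abs(ax$z[cand] - sl$z_mid_mm))]
    plane <- lv_mask[, , k]
    th_deg <- seq(ray_step_deg / 2, 360 - ray_step_deg / 2, by = ray_step_deg)
    px <- outer(radii, cos(th_deg * pi / 180)) + sl$origin_x_mm
    py <- outer(radii, sin(th_deg * pi / 180)) + sl$origin_y_mm
    ix <- round((px - ax$x[1]) / vs[1]) + 1L
    iy <- round((py - ax$y[1]) / vs[2]) + 1L
    ok <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2]
    hit <- matrix(FALSE, length(radii), length(th_deg))
    hit[ok] <- plane[cbind(ix[ok], iy[ok])]
    thick_ray <- apply(hit, 2, function(h) {
      w <- which(h)
      if (length(w) == 0) return(NA_real_)
      (max(w) - min(w)) * r_step
    })
    bin <- floor((th_deg %% 360) / segments$angle_bin_deg)
    tb <- tibble::tibble(bin = bin, thick = thick_ray) |>
      dplyr::summarise(thickness_mm = mean(.data$thick, na.rm = TRUE),
                       n_rays = sum(!is.na(.data$thick)), .by = "bin")
    tb$segment_id <- sl$slice_index * segments$n_bins + tb$bin
    out[[i]] <- tb[, c("segment_id", "thickness_mm", "n_rays")]
  }
  res <- dplyr::bind_rows(out)
  res$thickness_mm[res$n_rays == 0] <- NA_real_
  res$excluded <- is.na(res$thickness_mm) | res$thickness_mm < min_thickness_mm
  dplyr::semi_join(res, segments$meta, by = "segment_id")
}
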