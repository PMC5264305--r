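#' Local endocardium-tangent coordinate frame
#'
#' Builds the per-voxel orthonormal triad (n, t, f) used to reference fiber
#' angles: n is the endocardial-surface normal pointing from the endocardium
#' toward the epicardium, t = z x n (circumferential; z is the global
#' apex-to-base unit vector) and f = n x t (longitudinal-tangential). n is
#' the normalized gradient of the signed distance transform to the
#' endocardial surface; the distance field is Gaussian-smoothed
#' (`smooth_sigma` voxels) and the gradient components are smoothed again at
#' twice that scale, which suppresses the lattice staircase of the discrete
#' surface (the dominant error of voxel-based normals). With this sign
#' convention positive inclination angles are right-handed
#' (endocardial-type) fibers. Voxels where n is parallel to z
#' (|z x n| < 1e-6) are flagged undefined.
#'
#' @param lv_mask logical wall mask.
#' @param blood_mask logical blood-pool (endocardial cavity) mask.
#' @param z_axis global apex-to-base unit vector (default +z).
#' @param voxel_size_mm voxel spacing, mm.
#' @param smooth_sigma Gaussian smoothing of the signed distance field,
#'   voxels.
#' @return A `frame_field`: arrays `n`, `t`, `f` (x,y,z,3; NA where
#'   undefined), logical `defined`, and `z_axis`.
#' @export
compute_local_frame <- function(lv_mask, blood_mask, z_axis = c(0, 0, 1),
                                voxel_size_mm = c(1, 1, 1),
                                smooth_sigma = 2) {
  if (!any(lv_mask) || !any(blood_mask)) stop("empty masks")
  z_axis <- z_axis / sqrt(sum(z_axis^2))
  # signed distance to the endocardial surface (positive outside the
  # cavity); the cavity is continued axially past the coverage boundary so
  # normals near the end slices stay lateral
  blood_ext <- pad_axially(blood_mask)
  phi <- distance_to(blood_ext, voxel_size_mm) -
    distance_to(!blood_ext, voxel_size_mm)
  phi <- gaussian_smooth3(phi, smooth_sigma)
  g <- gradient3(phi, voxel_size_mm)
  if (smooth_sigma > 0)
    for (k in 1:3) g[, , , k] <- gaussian_smooth3(g[, , , k], 2 * smooth_sigma)
  d <- dim(lv_mask)
  w <- which(lv_mask)
  nv <- cbind(g[, , , 1][w], g[, , , 2][w], g[, , , 3][w])
  nrm <- sqrt(rowSums(nv^2))
  ok <- nrm > 1e-9
  nv <- nv / pmax(nrm, 1e-12)
  tv <- cbind(z_axis[2] * nv[, 3] - z_axis[3] * nv[, 2],
              z_axis[3] * nv[, 1] - z_axis[1] * nv[, 3],
              z_axis[1] * nv[, 2] - z_axis[2] * nv[, 1])
  tnorm <- sqrt(rowSums(tv^2))
  ok <- ok & tnorm > 1e-6
  tv <- tv / pmax(tnorm, 1e-12)
  fv <- cbind(nv[, 2] * tv[, 3] - nv[, 3] * tv[, 2],
              nv[, 3] * tv[, 1] - nv[, 1] * tv[, 3],
              nv[, 1] * tv[, 2] - nv[, 2] * tv[, 1])
  to_arr <- function(m) {
    out <- array(NA_real_, c(d, 3L))
    for (k in 1:3) {
      comp <- array(NA_real_, d)
      comp[w] <- ifelse(ok, m[, k], NA_real_)
      out[, , , k] <- comp
    }
    out
  }
  defined <- array(FALSE, d)
  defined[w] <- ok
  structure(list(n = to_arr(nv), t = to_arr(tv), f = to_arr(fv),
                 defined = defined, z_axis = z_axis,
                 voxel_size_mm = voxel_size_mm),
            class = "frame_field")
}

#' Transmural wall depth
#'
#' Distance from the epicardial surface (`depth_mm`) and normalized depth
#' `depth_norm` = d_epi / (d_epi + d_endo), 0 at the epicardium and 1 at the
#' endocardium, from Euclidean distance transforms to the exterior and to
#' the blood pool (each corrected by half a voxel so distances are measured
#' to the continuous interface rather than to background voxel centres).
#'
#' @param lv_mask,blood_mask logical arrays; by default the exterior is
#'   everything that is neither wall nor blood, restricted to slices that
#'   contain wall (so a short-axis stack's coverage boundary is never
#'   mistaken for the epicardial surface).
#' @param exterior_mask optional explicit epicardial-background mask.
#' @param voxel_size_mm voxel spacing, mm.
#' @param smooth_sigma optional Gaussian smoothing (voxels) of the two
#'   distance fields. Off by default: the distance fields are piecewise
#'   linear and smoothing across the zero-floored surfaces compresses the
#'   transmural scale near the boundaries, biasing profile slopes.
#' @return A `depth_field`: arrays `depth_mm` and `depth_norm`
#'   (NA outside the wall).
#' @export
wall_depth <- function(lv_mask, blood_mask, exterior_mask = NULL,
                       voxel_size_mm = c(1, 1, 1), smooth_sigma = 0) {
  if (is.null(exterior_mask)) {
    exterior_mask <- !lv_mask & !blood_mask
    has_wall <- apply(lv_mask, 3, any)
    exterior_mask[, , !has_wall] <- FALSE
  }
  exterior <- exterior_mask
  if (!any(exterior) || !any(blood_mask))
    stop("wall must be enclosed between blood pool and exterior")
  d_epi <- distance_to_surface(exterior, voxel_size_mm)
  d_endo <- distance_to_surface(pad_axially(blood_mask), voxel_size_mm)
  if (smooth_sigma > 0) {
    d_epi <- gaussian_smooth3(d_epi, smooth_sigma)
    d_endo <- gaussian_smooth3(d_endo, smooth_sigma)
  }
  depth_mm <- d_epi
  depth_norm <- d_epi / (d_epi + d_endo)
  depth_mm[!lv_mask] <- NA_real_
  depth_norm[!lv_mask] <- NA_real_
  structure(list(depth_mm = depth_mm, depth_norm = depth_norm),
            class = "depth_field")
}
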