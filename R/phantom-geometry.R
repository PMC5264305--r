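# Analytic cylindrical-annulus LV geometry. All fields are evaluated at
# voxel centres on the grid defined by the parameters; the wall is the set
# endo_radius <= r <= epi_local(theta), with the local epicardial radius
# reduced inside the scar sector to model infarct thinning.

# Per-voxel cylindrical coordinates and local wall bounds.
phantom_fields <- function(params) {
  p <- params
  ax <- voxel_coords(p$grid_shape, p$voxel_size_mm)
  d <- p$grid_shape
  X <- array(ax$x, d)
  Y <- aperm(array(ax$y, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(ax$z, d[c(3, 2, 1)]), c(3, 2, 1))
  r <- sqrt(X^2 + Y^2)
  theta <- (atan2(Y, X) * 180 / pi) %% 360
  z0 <- -p$long_axis_extent_mm / 2          # apex end of the wall
  in_z <- Z >= z0 & Z <= z0 + p$long_axis_extent_mm
  thick <- p$epi_radius_mm - p$endo_radius_mm
  epi_local <- array(p$epi_radius_mm, d)
  in_sector <- array(FALSE, d)
  if (!is.null(p$scar_sector_deg)) {
    s <- p$scar_sector_deg %% 360
    in_sector <- if (s[1] <= s[2]) theta >= s[1] & theta < s[2]
                 else theta >= s[1] | theta < s[2]
    epi_local[in_sector] <- p$endo_radius_mm + thick * p$scar_thinning_factor
  }
  # normalized depth from the (local) epicardium: 0 = epi, 1 = endo
  depth_norm <- (epi_local - r) / (epi_local - p$endo_radius_mm)
  list(r = r, theta = theta, z = Z, in_z = in_z, in_sector = in_sector,
       epi_local = epi_local, depth_norm = depth_norm, apex_z = z0)
}

#' Build the phantom wall, blood-pool and scar masks
#'
#' Constructs a cylindrical LV annulus centred on the z axis. Inside the scar
#' sector the wall thickness is scaled by `scar_thinning_factor` (the
#' epicardial surface moves inward) and the fibrotic sub-layer defined by
#' `scar_transmural_span` is marked in `scar_mask`.
#'
#' @param params a [phantom_params()] object.
#' @return List with logical arrays `lv_mask`, `blood_mask`, `scar_mask`,
#'   plus the analytic `depth_norm` field (NA outside the wall).
#' @export
#' @examples
#' g <- build_geometry(phantom_params(grid_shape = c(48, 48, 24),
#'                                    long_axis_extent_mm = 10))
#' sum(g$scar_mask) / sum(g$lv_mask)
build_geometry <- function(params) {
  p <- params
  half <- (p$grid_shape[1:2] / 2) * p$voxel_size_mm[1:2]
  if (any(p$epi_radius_mm >= half))
    stop(sprintf("grid too small: epicardial radius %.1f mm does not fit in a %.1f x %.1f mm plane",
                 p$epi_radius_mm, 2 * half[1], 2 * half[2]))
  f <- phantom_fields(p)
  lv <- f$in_z & f$r >= p$endo_radius_mm & f$r <= f$epi_local
  blood <- f$in_z & f$r < p$endo_radius_mm
  scar <- lv & f$in_sector &
    f$depth_norm >= p$scar_transmural_span[1] &
    f$depth_norm <= p$scar_transmural_span[2]
  if (is.null(p$scar_sector_deg)) scar[] <- FALSE
  depth <- f$depth_norm
  depth[!lv] <- NA_real_
  list(lv_mask = lv, blood_mask = blood, scar_mask = scar, depth_norm = depth)
}

#' Ground-truth fiber architecture of the phantom
#'
#' At each wall voxel the inclination angle rotates linearly with normalized
#' wall depth d (measured from the epicardium),
#' alpha(d) = alpha_epi + (alpha_endo - alpha_epi) d, and the fiber direction
#' is cos(alpha) t + sin(alpha) f in the analytic cylindrical frame
#' (n radial outward, t circumferential, f longitudinal). The ground-truth
#' imbrication angle is constant (`imbrication_deg`, 0 by default).
#'
#' @param geometry output of [build_geometry()].
#' @param params the matching [phantom_params()].
#' @return List with `fibers` (x,y,z,3 unit-vector array, NA outside wall),
#'   `inclination_deg` and `imbrication_deg` arrays.
#' @export
ground_truth_fibers <- function(geometry, params) {
  p <- params
  f <- phantom_fields(p)
  lv <- geometry$lv_mask
  if (!any(lv)) stop("empty wall mask")
  d <- dim(lv)
  w <- which(lv)
  alpha <- p$alpha_epi_deg + (p$alpha_endo_deg - p$alpha_epi_deg) * f$depth_norm[w]
  phi <- rep(p$imbrication_deg, length(w))
  th <- f$theta[w] * pi / 180
  nv <- cbind(cos(th), sin(th), 0)
  tv <- cbind(-sin(th), cos(th), 0)
  fv <- cbind(0, 0, 1)
  e <- tv + tan(alpha * pi / 180) * fv[rep(1, length(w)), ] +
    tan(phi * pi / 180) * nv
  e <- e / sqrt(rowSums(e^2))
  fibers <- array(NA_real_, c(d, 3L))
  for (k in 1:3) {
    comp <- array(NA_real_, d)
    comp[w] <- e[, k]
    fibers[, , , k] <- comp
  }
  inc <- imb <- array(NA_real_, d)
  inc[w] <- alpha
  imb[w] <- phi
  list(fibers = fibers, inclination_deg = inc, imbrication_deg = imb)
}

# Prolate (lambda2 = lambda3) eigenvalues with prescribed MD and FA:
# delta = FA / sqrt(3 - 2 FA^2), lambda1 = MD (1 + 2 delta),
# lambda2 = lambda3 = MD (1 - delta).
prolate_eigenvalues <- function(md, fa) {
  if (any(md <= 0)) stop("MD must be positive")
  if (any(fa < 0) || any(fa >= 1))
    stop("FA must lie in [0, 1) for a prolate tensor with positive eigenvalues")
  delta <- fa / sqrt(3 - 2 * fa^2)
  cbind(l1 = md * (1 + 2 * delta), l2 = md * (1 - delta), l3 = md * (1 - delta))
}

#' Assemble prolate diffusion tensors from a fiber field
#'
#' Builds axially symmetric (prolate, lambda2 = lambda3) tensors whose primary
#' eigenvector is the fiber direction and whose eigenvalues solve
#' MD = (l1 + 2 l2)/3 together with the standard FA formula.
#'
#' @param fibers unit-vector array (x,y,z,3) as from [ground_truth_fibers()].
#' @param md_map,fa_map scalar or array of per-voxel MD (mm^2/s) and FA.
#' @param mask logical array of voxels to populate (defaults to where the
#'   fiber field is defined).
#' @param voxel_size_mm voxel spacing, mm.
#' @return A [new_tensor_field()] object.
#' @export
assemble_tensors <- function(fibers, md_map, fa_map, mask = NULL,
                             voxel_size_mm = c(1, 1, 1)) {
  d <- dim(fibers)[1:3]
  if (is.null(mask)) mask <- !is.na(fibers[, , , 1])
  w <- which(mask)
  md <- if (length(md_map) == 1L) rep(md_map, length(w)) else md_map[w]
  fa <- if (length(fa_map) == 1L) rep(fa_map, length(w)) else fa_map[w]
  ev <- prolate_eigenvalues(md, fa)
  e <- cbind(fibers[, , , 1][w], fibers[, , , 2][w], fibers[, , , 3][w])
  a <- ev[, 1] - ev[, 2]
  comp <- cbind(a * e[, 1]^2 + ev[, 2],
                a * e[, 2]^2 + ev[, 2],
                a * e[, 3]^2 + ev[, 2],
                a * e[, 1] * e[, 2],
                a * e[, 1] * e[, 3],
                a * e[, 2] * e[, 3])
  new_tensor_field(comp, mask, voxel_size_mm)
}
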