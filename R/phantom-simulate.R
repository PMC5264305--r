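#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' Monoexponential (Stejskal-Tanner) signal model
#' S_i = S0 exp(-b_i g_i^T D g_i) per scheme entry, with Rician noise: the
#' magnitude of the complex signal after adding two independent Gaussian
#' channels of standard deviation sigma = S0 / SNR. Voxels outside the
#' tensor field's mask contain pure noise (Rayleigh background), as in a
#' magnitude image of signal-free surroundings.
#'
#' @param tensors a [new_tensor_field()] object.
#' @param scheme a `gradient_scheme`.
#' @param s0 non-diffusion-weighted signal amplitude (> 0).
#' @param snr signal-to-noise ratio; `Inf` for a noiseless simulation.
#' @param seed integer seed (noise is reproducible given the seed).
#' @return A [dwi_volume()] with the tensor field's mask attached.
#' @export
simulate_dwi <- function(tensors, scheme, s0 = 1000, snr = Inf, seed = 1L) {
  if (s0 <= 0) stop("s0 must be positive")
  if (snr <= 0) stop("snr must be positive (use Inf for noiseless)")
  mask <- tensors$mask
  d <- dim(mask)
  g <- scheme$directions
  b <- scheme$b_values
  # quadratic form per volume: rows match the compact component order
  Q <- rbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3]) * rep(b, each = 6)
  att <- tensors$tensors %*% Q                     # nvox x nvol
  S <- s0 * exp(-att)
  nvol <- length(b)
  signals <- array(0, c(d, nvol))
  flat <- matrix(signals, ncol = nvol)
  flat[which(mask), ] <- S
  if (is.finite(snr)) {
    sigma <- s0 / snr
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    n <- length(flat)
    flat <- sqrt((flat + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  }
  dwi_volume(array(flat, c(d, nvol)), scheme, mask = mask,
             voxel_size_mm = tensors$voxel_size_mm)
}

#' Simulate an LGE-like enhancement volume
#'
#' Gaussian intensities N(mu_fibrotic, sigma^2) inside the scar mask,
#' N(mu_normal, sigma^2) elsewhere in the wall, and zero background -
#' emulating the enhanced image intensity of fibrotic tissue on
#' late-gadolinium-enhancement imaging.
#'
#' @param lv_mask,scar_mask logical arrays (scar subset of wall).
#' @param mu_fibrotic,mu_normal class means, `mu_fibrotic > mu_normal`.
#' @param sigma within-class standard deviation (>= 0).
#' @param seed integer seed.
#' @return Numeric array of LGE intensities.
#' @export
simulate_lge <- function(lv_mask, scar_mask, mu_fibrotic = 200,
                         mu_normal = 100, sigma = 10, seed = 1L) {
  if (mu_fibrotic <= mu_normal) stop("mu_fibrotic must exceed mu_normal")
  if (sigma < 0) stop("sigma must be non-negative")
  if (any(scar_mask & !lv_mask)) stop("scar mask must lie inside the wall")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  out <- array(0, dim(lv_mask))
  n_w <- sum(lv_mask)
  out[lv_mask] <- rnorm(n_w, mu_normal, sigma)
  n_s <- sum(scar_mask)
  if (n_s > 0) out[scar_mask] <- rnorm(n_s, mu_fibrotic, sigma)
  out
}

#' Build a complete synthetic LV phantom
#'
#' Chains geometry, ground-truth fibers, prolate tensor assembly (fibrotic
#' MD/FA inside the scar, normal elsewhere), the Rician-noise DWI simulation
#' and the LGE channel into one bundle with known ground truth.
#'
#' @param params a [phantom_params()] object.
#' @return An object of class `phantom_bundle`: masks, `true_fibers`,
#'   `true_inclination` / `true_imbrication` (degrees), `depth_norm`
#'   (analytic), `true_tensors`, `dwi`, `lge` and `params`.
#' @export
#' @examples
#' b <- build_phantom(phantom_params(grid_shape = c(32, 32, 12),
#'                                   long_axis_extent_mm = 5, snr = Inf))
#' range(b$true_inclination, na.rm = TRUE)
build_phantom <- function(params) {
  p <- params
  geo <- build_geometry(p)
  gt <- ground_truth_fibers(geo, p)
  md <- array(p$md_normal, p$grid_shape)
  fa <- array(p$fa_normal, p$grid_shape)
  md[geo$scar_mask] <- p$md_fibrotic
  fa[geo$scar_mask] <- p$fa_fibrotic
  tensors <- assemble_tensors(gt$fibers, md, fa, mask = geo$lv_mask,
                              voxel_size_mm = p$voxel_size_mm)
  scheme <- make_gradient_scheme(p$n_directions, p$b_value, seed = p$seed)
  dwi <- simulate_dwi(tensors, scheme, s0 = p$s0, snr = p$snr, seed = p$seed)
  lge <- simulate_lge(geo$lv_mask, geo$scar_mask,
                      mu_fibrotic = p$lge_mu_fibrotic,
                      mu_normal = p$lge_mu_normal,
                      sigma = p$lge_sigma, seed = p$seed + 1L)
  structure(list(
    lv_mask = geo$lv_mask, blood_mask = geo$blood_mask,
    scar_mask = geo$scar_mask,
    depth_norm = geo$depth_norm,
    true_fibers = gt$fibers,
    true_inclination = gt$inclination_deg,
    true_imbrication = gt$imbrication_deg,
    true_tensors = tensors,
    dwi = dwi, lge = lge, params = p
  ), class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> wall %d voxels, scar %d voxels, SNR %g\n",
              sum(x$lv_mask), sum(x$scar_mask), x$params$snr))
  invisible(x)
}

#' Write a phantom bundle to disk
#'
#' Writes the DWI (NIfTI + FSL bval/bvec), the LGE channel, the masks and the
#' ground-truth angle maps as NIfTI volumes with the voxel size encoded in
#' the header.
#'
#' @param bundle a [build_phantom()] result.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- bundle$params$voxel_size_mm
  write_dwi(bundle$dwi, dir, "dwi")
  write_volume(bundle$lge, file.path(dir, "lge.nii.gz"), vs)
  write_volume(bundle$lv_mask, file.path(dir, "lv_mask.nii.gz"), vs)
  write_volume(bundle$blood_mask, file.path(dir, "blood_mask.nii.gz"), vs)
  write_volume(bundle$scar_mask, file.path(dir, "scar_mask.nii.gz"), vs)
  inc <- bundle$true_inclination; inc[is.na(inc)] <- 0
  write_volume(inc, file.path(dir, "true_inclination.nii.gz"), vs)
  invisible(dir)
}
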