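#' Diffusion-weighted image volumes
#'
#' Container for a 4-D diffusion acquisition: the signal array (x, y, z,
#' volume), the gradient scheme, a voxel-to-world affine and an optional
#' analysis mask. Signals must be non-negative (magnitude images) and the
#' volume count must match the scheme.
#'
#' @param signals 4-D numeric array.
#' @param scheme a `gradient_scheme` (see [make_gradient_scheme()]).
#' @param affine 4x4 voxel-to-world matrix; default encodes `voxel_size_mm`.
#' @param mask optional logical 3-D array.
#' @param voxel_size_mm voxel spacing used for the default affine.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signals, scheme, affine = NULL, mask = NULL,
                       voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim(signals)) == 4L)
  if (dim(signals)[4] != length(scheme$b_values))
    stop("volume count does not match the gradient scheme")
  if (min(signals, na.rm = TRUE) < 0)
    stop("magnitude signals must be non-negative")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  if (!is.null(mask)) stopifnot(all(dim(mask) == dim(signals)[1:3]))
  structure(list(signals = signals, scheme = scheme, affine = affine,
                 mask = mask,
                 voxel_size_mm = abs(diag(affine)[1:3])),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat(sprintf("<dwi_volume> %s, %d volumes (b max %g s/mm^2), voxel %s mm\n",
              paste(dim(x$signals)[1:3], collapse = "x"),
              dim(x$signals)[4], max(x$scheme$b_values),
              paste(format(x$voxel_size_mm), collapse = " x ")))
  invisible(x)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} that carry the voxel-to-world affine.
#' `write_volume()` accepts 3-D or 4-D arrays (logical masks are written as
#' uint8); `read_volume()` returns the array with the affine attached as
#' attribute `"affine"`.
#'
#' @param x numeric or logical array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel spacing written into the header.
#' @return `read_volume()` returns an array; `write_volume()` the path,
#'   invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  if (is.logical(x)) x <- array(as.integer(x), dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, length(dim(x)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "affine") <- structure(RNifti::xform(img), class = NULL)
  out
}

#' Read a DWI acquisition from NIfTI + FSL gradient files
#'
#' @param dwi_path 4-D NIfTI file.
#' @param prefix path prefix of the `.bval`/`.bvec` pair.
#' @param mask_path optional NIfTI mask.
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(dwi_path, prefix, mask_path = NULL) {
  sig <- read_volume(dwi_path)
  scheme <- read_bvals_bvecs(prefix)
  mask <- if (!is.null(mask_path)) read_volume(mask_path) > 0 else NULL
  aff <- attr(sig, "affine")
  attr(sig, "affine") <- NULL
  dwi_volume(sig, scheme, affine = aff, mask = mask)
}

#' Write a DWI acquisition as NIfTI + FSL gradient files
#'
#' @param dwi a [dwi_volume()].
#' @param dir output directory (created if needed).
#' @param stem file stem for `stem.nii.gz`, `stem.bval`, `stem.bvec`.
#' @return The NIfTI path, invisibly.
#' @export
write_dwi <- function(dwi, dir, stem = "dwi") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(stem, ".nii.gz"))
  write_volume(dwi$signals, path, dwi$voxel_size_mm)
  write_bvals_bvecs(dwi$scheme, file.path(dir, stem))
  if (!is.null(dwi$mask))
    write_volume(dwi$mask, file.path(dir, paste0(stem, "_mask.nii.gz")),
                 dwi$voxel_size_mm)
  invisible(path)
}
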