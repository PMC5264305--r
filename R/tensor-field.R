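#' Per-voxel diffusion tensor fields
#'
#' A `tensor_field` stores, for every voxel of a mask, the symmetric 3x3
#' diffusion tensor in compact form (xx, yy, zz, xy, xz, yz; mm^2/s), its
#' eigenvalues sorted descending, unit eigenvectors, the derived mean
#' diffusivity and fractional anisotropy, and a validity flag (FALSE where
#' signals were clamped or fitted eigenvalues are negative - such voxels are
#' kept, never silently dropped, so QC can count them).
#'
#' @param comp n x 6 matrix of tensor components at the masked voxels, in the
#'   order returned by `which(mask)`.
#' @param mask logical 3-D array.
#' @param voxel_size_mm voxel spacing, mm.
#' @param valid optional logical vector of per-voxel validity flags.
#' @return An object of class `tensor_field`.
#' @export
new_tensor_field <- function(comp, mask, voxel_size_mm, valid = NULL) {
  comp <- as.matrix(comp)
  stopifnot(ncol(comp) == 6L, nrow(comp) == sum(mask))
  eig <- .eig3_batch_cpp(comp)
  vec <- eig$vectors
  # deterministic sign: first component with magnitude > tol made positive
  for (j in 0:2) {
    v <- vec[, 3 * j + (1:3), drop = FALSE]
    s <- sign(v[, 1])
    use2 <- abs(v[, 1]) <= 1e-12
    s[use2] <- sign(v[use2, 2])
    use3 <- use2 & abs(v[, 2]) <= 1e-12
    s[use3] <- sign(v[use3, 3])
    s[s == 0] <- 1
    vec[, 3 * j + (1:3)] <- v * s
  }
  ev <- eig$values
  if (is.null(valid)) valid <- rep(TRUE, nrow(comp))
  # negative-eigenvalue flag with a roundoff guard (an exactly-zero tensor
  # may decompose to eigenvalues of order -1e-20)
  ev_tol <- 1e-9 * abs(ev[, 1]) + 1e-15
  valid <- valid & ev[, 3] >= -ev_tol & is.finite(rowSums(comp))
  structure(list(
    tensors = comp,
    eigenvalues = ev,
    eigenvectors = vec,
    md = mean_diffusivity(ev[, 1], ev[, 2], ev[, 3]),
    fa = fractional_anisotropy(ev[, 1], ev[, 2], ev[, 3]),
    valid = valid,
    mask = mask,
    voxel_size_mm = voxel_size_mm
  ), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("<tensor_field> %d voxels on a %s grid (%d flagged invalid)\n",
              nrow(x$tensors), paste(dim(x$mask), collapse = "x"),
              sum(!ok)))
  cat(sprintf("  MD %.3g +/- %.2g mm^2/s, FA %.3f +/- %.3f (valid voxels)\n",
              mean(x$md[ok]), sd(x$md[ok]), mean(x$fa[ok]), sd(x$fa[ok])))
  invisible(x)
}

# Primary-eigenvector rows (n x 3) of a tensor_field.
primary_eigenvectors <- function(field) field$eigenvectors[, 1:3, drop = FALSE]

# Expand a per-masked-voxel vector to a full array (NA outside the mask).
field_to_array <- function(values, mask) {
  out <- array(NA_real_, dim(mask))
  out[mask] <- values
  out
}

#' Scalar maps of a tensor field
#'
#' Expand the per-voxel MD or FA of a [new_tensor_field()] object into a full
#' 3-D array (NA outside the mask).
#'
#' @param field a `tensor_field`.
#' @return A numeric array with the dimensions of the field's mask.
#' @export
md_map <- function(field) field_to_array(field$md, field$mask)

#' @rdname md_map
#' @export
fa_map <- function(field) field_to_array(field$fa, field$mask)

#' Mean diffusivity
#'
#' MD = (e1 + e2 + e3) / 3, the average of the diffusion-tensor eigenvalues
#' (mm^2/s). Rises in scar as cellular barriers are lost.
#'
#' @param e1,e2,e3 eigenvalue vectors, mm^2/s.
#' @return Numeric vector of MD values.
#' @export
#' @examples
#' mean_diffusivity(11.11e-4, 9.03e-4, 7.09e-4)  # fibrotic tissue, 9.08e-4
mean_diffusivity <- function(e1, e2, e3) (e1 + e2 + e3) / 3

#' Fractional anisotropy
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, the normalized
#' dispersion of the eigenvalues: 0 for isotropic diffusion, 1 in the
#' stick limit. Undefined (NA, with a warning) when all eigenvalues are zero.
#'
#' @param e1,e2,e3 eigenvalue vectors.
#' @return Numeric vector of FA values in [0, 1].
#' @export
#' @examples
#' fractional_anisotropy(1, 1, 1)  # 0
#' fractional_anisotropy(1, 0, 0)  # 1
fractional_anisotropy <- function(e1, e2, e3) {
  nrm2 <- e1^2 + e2^2 + e3^2
  m <- (e1 + e2 + e3) / 3
  dev2 <- (e1 - m)^2 + (e2 - m)^2 + (e3 - m)^2
  out <- sqrt(1.5 * dev2 / nrm2)
  if (any(nrm2 == 0)) {
    warning("FA undefined for all-zero eigenvalues; returning NA")
    out[nrm2 == 0] <- NA_real_
  }
  pmin(out, 1)
}

#' Eigendecomposition of a single diffusion tensor
#'
#' Returns eigenvalues sorted descending with unit eigenvectors whose sign is
#' fixed deterministically (first nonzero component positive). Downstream
#' angle computations are invariant to this sign.
#'
#' @param tensor symmetric 3x3 matrix.
#' @param tol symmetry tolerance.
#' @return List with `values` (length 3, descending) and `vectors`
#'   (3x3, columns v1, v2, v3).
#' @export
#' @examples
#' eigendecompose(diag(c(3, 2, 1)))$values
eigendecompose <- function(tensor, tol = 1e-8) {
  stopifnot(is.matrix(tensor), all(dim(tensor) == c(3L, 3L)))
  if (max(abs(tensor - t(tensor))) > tol * max(1, max(abs(tensor))))
    stop("tensor must be symmetric")
  comp <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
            tensor[1, 2], tensor[1, 3], tensor[2, 3])
  e <- .eig3_batch_cpp(matrix(comp, nrow = 1))
  V <- matrix(e$vectors[1, ], nrow = 3)   # columns v1, v2, v3
  for (j in 1:3) {
    v <- V[, j]
    k <- which(abs(v) > 1e-12)[1]
    if (!is.na(k) && v[k] < 0) V[, j] <- -v
  }
  list(values = as.numeric(e$values[1, ]), vectors = V)
}
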