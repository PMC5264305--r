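#' Rotation factor of an affine by polar decomposition
#'
#' Extracts the rigid-rotation part R of an invertible linear map A via the
#' polar decomposition A = R P (R = U V^T from the SVD A = U S V^T); this is
#' the finite-strain reorientation rule for diffusion tensors under affine
#' registration.
#'
#' @param linear 3x3 invertible matrix.
#' @return 3x3 rotation matrix.
#' @export
polar_rotation <- function(linear) {
  stopifnot(all(dim(linear) == c(3L, 3L)))
  s <- svd(linear)
  if (min(s$d) <= 1e-12 * max(s$d)) stop("singular linear part")
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {   # keep a proper rotation
    s$u[, 3] <- -s$u[, 3]
    R <- s$u %*% t(s$v)
  }
  R
}

#' Reorient and resample a tensor field under a supplied affine
#'
#' Applies a given 4x4 affine (voxel coordinates, source -> target) to a
#' tensor field: voxels are resampled into the target grid by
#' nearest-neighbour lookup and each tensor is rotated by the finite-strain
#' rule D' = R D R^T, with R the polar-decomposition rotation of the
#' affine's linear part. MD and FA are unchanged by construction. Estimating
#' the affine is out of scope - it is an input.
#'
#' @param field a [new_tensor_field()] object.
#' @param affine 4x4 matrix mapping source voxel indices (1-based) to target.
#' @param target_shape dimensions of the target grid (defaults to source).
#' @return A reoriented `tensor_field` on the target grid.
#' @export
reorient_tensors <- function(field, affine, target_shape = dim(field$mask)) {
  stopifnot(all(dim(affine) == c(4L, 4L)))
  A <- affine[1:3, 1:3]
  R <- polar_rotation(A)
  # 6x6 operator on compact components equivalent to D' = R D R^T
  K <- matrix(0, 6, 6)
  pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (m in 1:6) {
    E <- matrix(0, 3, 3)
    E[pairs[m, 1], pairs[m, 2]] <- E[pairs[m, 2], pairs[m, 1]] <- 1
    Ep <- R %*% E %*% t(R)
    K[, m] <- Ep[cbind(pairs[, 1], pairs[, 2])]
  }
  # nearest-neighbour pullback: source voxel for each target voxel
  Ainv <- solve(affine)
  tg <- as.matrix(expand.grid(x = seq_len(target_shape[1]),
                              y = seq_len(target_shape[2]),
                              z = seq_len(target_shape[3])))
  src <- round(cbind(tg, 1) %*% t(Ainv))[, 1:3, drop = FALSE]
  d <- dim(field$mask)
  inside <- src[, 1] >= 1 & src[, 1] <= d[1] &
            src[, 2] >= 1 & src[, 2] <= d[2] &
            src[, 3] >= 1 & src[, 3] <= d[3]
  src_lin <- rep(NA_integer_, nrow(src))
  src_lin[inside] <- (src[inside, 3] - 1L) * d[1] * d[2] +
    (src[inside, 2] - 1L) * d[1] + src[inside, 1]
  voxnum <- array(0L, d)
  voxnum[field$mask] <- seq_len(sum(field$mask))
  hit <- inside & !is.na(src_lin) & voxnum[pmax(src_lin, 1)] > 0 &
    field$mask[pmax(src_lin, 1)]
  new_mask <- array(FALSE, target_shape)
  new_mask[hit] <- TRUE
  rows <- voxnum[src_lin[hit]]
  comp <- field$tensors[rows, , drop = FALSE] %*% t(K)
  new_tensor_field(comp, new_mask, field$voxel_size_mm,
                   valid = field$valid[rows])
}
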