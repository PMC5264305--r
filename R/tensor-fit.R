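#' Fit diffusion tensors by log-linear least squares
#'
#' Per masked voxel, ordinary least squares of y_i = ln S_i against the
#' design (1, -b g g^T terms), solving jointly for ln S0 and the six
#' independent tensor elements. Non-positive signals are clamped to
#' 1e-6 x S0 (per-voxel b = 0 mean) and the voxel is flagged in the validity
#' mask; voxels with negative fitted eigenvalues are likewise flagged but
#' kept, so QC can count them. OLS rather than weighted LS is the default:
#' at the SNR of fixed ex-vivo acquisitions (> 100) the heteroscedasticity
#' of log-transformed Rician noise is negligible.
#'
#' @param dwi a [dwi_volume()]; its `mask` (all voxels if absent) selects the
#'   fitted voxels.
#' @param weighted if TRUE, one reweighted pass with weights S_i^2 (the
#'   usual WLS for log-linear tensor fits).
#' @return A [new_tensor_field()] object.
#' @export
fit_tensor <- function(dwi, weighted = FALSE) {
  scheme <- dwi$scheme
  nz <- scheme$b_values > 0
  if (sum(nz) < 6L || sum(!nz) < 1L)
    stop("need >= 6 diffusion-weighted volumes and >= 1 b = 0 volume")
  mask <- dwi$mask
  if (is.null(mask)) mask <- array(TRUE, dim(dwi$signals)[1:3])
  if (!any(mask)) stop("empty fitting mask")
  X <- tensor_design(scheme)
  if (qr(X)$rank < 7L)
    stop("rank-deficient design: diffusion directions are collinear")
  nvol <- length(scheme$b_values)
  w <- which(mask)
  S <- matrix(dwi$signals, ncol = nvol)[w, , drop = FALSE]
  s0 <- rowMeans(S[, !nz, drop = FALSE])
  s0[s0 <= 0] <- max(S) * 1e-6 + .Machine$double.eps
  bad <- S <= 0
  clamped <- rowSums(bad) > 0
  if (any(bad)) S[bad] <- (1e-6 * s0)[row(S)[bad]]
  B <- solve(crossprod(X), crossprod(X, t(log(S))))   # 7 x nvox
  if (weighted) {
    # one IRLS pass: weights are the squared predicted signals
    for (i in seq_along(w)) {
      pred2 <- exp(2 * as.numeric(X %*% B[, i]))
      WX <- X * pred2
      B[, i] <- solve(crossprod(X, WX), crossprod(WX, log(S[i, ])))
    }
  }
  new_tensor_field(t(B[2:7, , drop = FALSE]), mask, dwi$voxel_size_mm,
                   valid = !clamped)
}
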