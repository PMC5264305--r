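#' Inclination (helix) angle of primary eigenvectors
#'
#' The angle between the projection of the primary eigenvector onto the
#' wall-tangent plane (spanned by t and f) and the circumferential vector t.
#' The eigenvector sign ambiguity is folded into [-90, 90] by flipping e1 so
#' that e1.t >= 0 (if e1.t = 0, so that e1.f >= 0, giving +90); negative
#' angles are left-handed (epicardial-type) fibers, positive right-handed
#' (endocardial-type). Vectors parallel to n (zero tangential projection)
#' are undefined and return NA.
#'
#' @param e1 unit vector (length 3) or n x 3 matrix of unit vectors.
#' @param t_vec,f_vec matching circumferential / longitudinal frame vectors.
#' @return Angle(s) in degrees in [-90, 90].
#' @export
#' @examples
#' inclination_angle(c(0, 1, 0), t_vec = c(0, 1, 0), f_vec = c(0, 0, 1))  # 0
inclination_angle <- function(e1, t_vec, f_vec) {
  m <- rbind3(e1); tv <- rbind3(t_vec); fv <- rbind3(f_vec)
  et <- rowSums(m * tv)
  ef <- rowSums(m * fv)
  s <- ifelse(et < 0, -1, ifelse(et > 0, 1, ifelse(ef >= 0, 1, -1)))
  ang <- atan2(ef * s, et * s) * 180 / pi
  ang[abs(et) < 1e-12 & abs(ef) < 1e-12] <- NA_real_
  drop_if_vec(ang, e1)
}

#' Imbrication (transverse) angle of primary eigenvectors
#'
#' The out-of-tangent-plane tilt of the primary eigenvector, measured in the
#' plane spanned by the circumferential vector t and the wall normal n,
#' using the same sign-folded eigenvector as [inclination_angle()]. Positive
#' angles tilt toward the epicardium. For near-longitudinal fibers
#' (|e1.t| < 0.05) the angle is ill-conditioned; use the `low_confidence`
#' flag from [angle_maps()].
#'
#' @param e1 unit vector or n x 3 matrix.
#' @param t_vec,n_vec circumferential / normal frame vectors.
#' @return Angle(s) in degrees.
#' @export
imbrication_angle <- function(e1, t_vec, n_vec) {
  m <- rbind3(e1); tv <- rbind3(t_vec); nv <- rbind3(n_vec)
  et <- rowSums(m * tv)
  en <- rowSums(m * nv)
  s <- ifelse(et < 0, -1, ifelse(et > 0, 1, ifelse(en >= 0, 1, -1)))
  ang <- atan2(en * s, et * s) * 180 / pi
  ang[abs(et) < 1e-12 & abs(en) < 1e-12] <- NA_real_
  drop_if_vec(ang, e1)
}

rbind3 <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
drop_if_vec <- function(ang, x) if (is.matrix(x)) ang else ang[1]

#' Voxelwise fiber-angle maps
#'
#' Converts the primary eigenvectors of a tensor field into inclination and
#' imbrication angle maps in the local (n, t, f) frame, with quality flags:
#' `undefined` where the frame is undefined or e1 is parallel to n, and
#' `low_confidence` where |e1.t| < 0.05 (imbrication ill-conditioned for
#' near-longitudinal fibers). Both angles are invariant under e1 -> -e1.
#'
#' @param field a [new_tensor_field()] object.
#' @param frame a [compute_local_frame()] object on the same grid.
#' @return An `angle_maps` object: arrays `inclination_deg`,
#'   `imbrication_deg` (NA where undefined), logical arrays `undefined` and
#'   `low_confidence`.
#' @export
angle_maps <- function(field, frame) {
  mask <- field$mask
  stopifnot(all(dim(mask) == dim(frame$defined)))
  w <- which(mask)
  e1 <- primary_eigenvectors(field)
  pick <- function(a) cbind(a[, , , 1][w], a[, , , 2][w], a[, , , 3][w])
  nv <- pick(frame$n); tv <- pick(frame$t); fv <- pick(frame$f)
  ok <- frame$defined[w]
  inc <- imb <- rep(NA_real_, length(w))
  et <- rowSums(e1 * tv)
  inc[ok] <- inclination_angle(e1[ok, , drop = FALSE],
                               tv[ok, , drop = FALSE],
                               fv[ok, , drop = FALSE])
  imb[ok] <- imbrication_angle(e1[ok, , drop = FALSE],
                               tv[ok, , drop = FALSE],
                               nv[ok, , drop = FALSE])
  d <- dim(mask)
  undef <- array(FALSE, d); lowc <- array(FALSE, d)
  undef[w] <- !ok | is.na(inc)
  lowc[w] <- ok & abs(et) < 0.05
  structure(list(inclination_deg = field_to_array(inc, mask),
                 imbrication_deg = field_to_array(imb, mask),
                 undefined = undef, low_confidence = lowc),
            class = "angle_maps")
}
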