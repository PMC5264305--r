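# Internal 3-D array helpers shared by the phantom, frame and scar modules.
# Everything here works on plain numeric/logical arrays indexed (x, y, z).

# Euclidean distance (mm) from every voxel to the nearest TRUE voxel of
# `mask`, honouring anisotropic voxel spacing.
distance_to <- function(mask, voxel_size_mm) {
  stopifnot(length(dim(mask)) == 3L, any(mask))
  d2 <- .edt3d_cpp(as.logical(mask), as.integer(dim(mask)),
                   as.numeric(voxel_size_mm))
  array(sqrt(d2), dim = dim(mask))
}

# Distance to the continuous interface between `mask` and its complement:
# the voxel-centre transform overshoots by half a voxel for a flat boundary,
# so subtract it (floored at zero).
distance_to_surface <- function(mask, voxel_size_mm) {
  d <- distance_to(mask, voxel_size_mm)
  pmax(d - mean(voxel_size_mm) / 2, 0)
}

# Separable Gaussian smoothing with sigma in voxels (scalar), truncated at
# 3 sigma. Operates in-place dimension by dimension via matrix products.
gaussian_smooth3 <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    # band matrix applying the kernel with reflected edges
    K <- matrix(0, n, n)
    reflect <- function(idx) {
      # fold out-of-range indices back with mirror boundary (any depth)
      if (n == 1L) return(rep(1L, length(idx)))
      m <- (idx - 1L) %% (2L * (n - 1L))
      ifelse(m < n, m + 1L, 2L * n - 1L - m)
    }
    for (off in -r:r) {
      idx <- reflect(seq_len(n) + off)
      K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + k[off + r + 1L]
    }
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- K %*% matrix(m, nrow = n)
    dim(m) <- dm
    aperm(m, order(perm))
  }
  for (ax in 1:3) x <- smooth_axis(x, ax)
  x
}

# Central-difference gradient of a 3-D scalar field, mm^-1 units.
gradient3 <- function(x, voxel_size_mm) {
  d <- dim(x)
  g <- array(0, c(d, 3L))
  ix <- function(n) list(lo = c(1L, seq_len(n - 1L)), hi = c(seq_len(n - 1L) + 1L, n))
  sx <- ix(d[1]); sy <- ix(d[2]); sz <- ix(d[3])
  g[, , , 1] <- (x[sx$hi, , , drop = FALSE] - x[sx$lo, , , drop = FALSE]) /
    (voxel_size_mm[1] * outer_step(sx))
  g[, , , 2] <- aperm((aperm(x, c(2, 1, 3))[sy$hi, , , drop = FALSE] -
                         aperm(x, c(2, 1, 3))[sy$lo, , , drop = FALSE]) /
                        (voxel_size_mm[2] * outer_step(sy)), c(2, 1, 3))
  g[, , , 3] <- aperm((aperm(x, c(3, 2, 1))[sz$hi, , , drop = FALSE] -
                         aperm(x, c(3, 2, 1))[sz$lo, , , drop = FALSE]) /
                        (voxel_size_mm[3] * outer_step(sz)), c(3, 2, 1))
  g
}

outer_step <- function(s) {
  # one-sided at the ends, central elsewhere
  step <- s$hi - s$lo
  array(step, dim = c(length(step), 1, 1))[, 1, 1]
}

# Shift a 3-D array by one voxel along `axis` (+1 or -1), padding with `fill`.
shift3 <- function(x, axis, by, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) {
    src[[axis]] <- seq_len(d[axis] - by)
    dst[[axis]] <- seq_len(d[axis] - by) + by
  } else {
    src[[axis]] <- seq_len(d[axis] + by) - by
    dst[[axis]] <- seq_len(d[axis] + by)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary dilation/erosion with the 6-connected (face-neighbour) ball of
# radius 1, iterated `r` times.
dilate6 <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    out <- mask
    for (ax in 1:3) for (by in c(-1L, 1L))
      out <- out | shift3(mask, ax, by, FALSE)
    mask <- out
  }
  mask
}

erode6 <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    out <- mask
    for (ax in 1:3) for (by in c(-1L, 1L))
      out <- out & shift3(mask, ax, by, TRUE)
    mask <- out
  }
  mask
}

# Connected components (6-connectivity) via an adjacency graph; returns an
# integer label array, 0 outside the mask.
label_components6 <- function(mask) {
  d <- dim(mask)
  idx <- array(0L, d)
  idx[mask] <- seq_len(sum(mask))
  edges <- NULL
  for (ax in 1:3) {
    nb <- shift3(idx, ax, 1L, 0L)
    keep <- mask & nb > 0L & idx > 0L
    if (any(keep)) edges <- rbind(edges, cbind(idx[keep], nb[keep]))
  }
  n <- sum(mask)
  g <- igraph::make_graph(edges = if (is.null(edges)) integer(0) else t(edges),
                          n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- array(0L, d)
  lab[mask] <- as.integer(memb)
  lab
}

# Replicate the lowest/highest nonempty z-slice of a mask through the rest
# of the grid, so distance fields near the axial coverage boundary measure
# to the lateral surface rather than to the stack's end.
pad_axially <- function(mask) {
  has <- which(apply(mask, 3, any))
  if (length(has) == 0) return(mask)
  lo <- min(has); hi <- max(has)
  if (lo > 1) for (k in seq_len(lo - 1)) mask[, , k] <- mask[, , lo]
  nz <- dim(mask)[3]
  if (hi < nz) for (k in (hi + 1):nz) mask[, , k] <- mask[, , hi]
  mask
}

# Voxel-centre world coordinates (mm) relative to the grid centre.
voxel_coords <- function(grid_shape, voxel_size_mm) {
  axes <- lapply(1:3, function(k)
    (seq_len(grid_shape[k]) - (grid_shape[k] + 1) / 2) * voxel_size_mm[k])
  list(x = axes[[1]], y = axes[[2]], z = axes[[3]])
}

# n x 3 matrix of world coordinates for the TRUE voxels of a mask.
mask_coords <- function(mask, voxel_size_mm) {
  ax <- voxel_coords(dim(mask), voxel_size_mm)
  w <- which(mask, arr.ind = TRUE)
  cbind(ax$x[w[, 1]], ax$y[w[, 2]], ax$z[w[, 3]])
}
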