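# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / enumeration, never by calling the code paths
# they check.

# Exact two-sided Mann-Whitney p by enumerating all C(n+m, n) group labelings.
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  m <- length(y)
  u_all <- apply(utils::combn(n + m, n), 2, function(idx)
    sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# FA directly from the formula, no shared code.
fa_formula <- function(e) {
  m <- mean(e)
  sqrt(1.5 * sum((e - m)^2) / sum(e^2))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Nearest-neighbour rotation of a 3-D mask about the grid-centre z axis.
rotate_mask_z <- function(mask, deg) {
  d <- dim(mask)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  th <- -deg * pi / 180            # pull-back rotation
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  si <- round(cx + cos(th) * (g$i - cx) - sin(th) * (g$j - cy))
  sj <- round(cy + sin(th) * (g$i - cx) + cos(th) * (g$j - cy))
  ok <- si >= 1 & si <= d[1] & sj >= 1 & sj <= d[2]
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    vals <- rep(FALSE, nrow(g))
    vals[ok] <- sl[cbind(si[ok], sj[ok])]
    out[, , k] <- array(vals, d[1:2])
  }
  out
}

# Exact 90-degree counterclockwise rotation about z on an even square grid
# (voxel centres map onto voxel centres).
rot90z <- function(a) {
  d <- dim(a)
  stopifnot(d[1] == d[2])
  out <- array(a[1], d)
  for (k in seq_len(d[3]))
    out[, , k] <- t(a[, , k])[d[1]:1, ]   # out[65-j, i] = in[i, j]
  out
}

# Angle between two unit vectors modulo sign, degrees (rows recycled if one
# argument is a single vector).
axial_angle <- function(u, v) {
  u <- rbind3m(u); v <- rbind3m(v)
  if (nrow(u) == 1 && nrow(v) > 1) u <- u[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(u) > 1) v <- v[rep(1, nrow(u)), , drop = FALSE]
  acos(pmin(1, abs(rowSums(u * v)))) * 180 / pi
}
rbind3m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
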