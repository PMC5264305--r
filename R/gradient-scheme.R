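#' Diffusion gradient schemes
#'
#' Builds an approximately uniform set of unit diffusion-encoding directions
#' on the hemisphere by electrostatic repulsion with antipodal symmetry,
#' prepends one b = 0 entry, and checks that the resulting tensor design
#' matrix is well conditioned. `n_directions = 6` returns the classic
#' dual-gradient preset instead of an optimised set.
#'
#' @param n_directions number of nonzero-b directions (>= 6).
#' @param b_value diffusion weighting of the encoded volumes, s/mm^2.
#' @param seed integer seed for the repulsion start (determines the scheme).
#' @param n_iter repulsion iterations.
#' @return A `gradient_scheme`: list with `directions` ((n+1) x 3 unit rows,
#'   first row zero) and `b_values` (length n+1, first entry 0).
#' @export
#' @examples
#' sch <- make_gradient_scheme(15, seed = 1)
#' nrow(sch$directions)  # 16 entries including the b = 0 image
make_gradient_scheme <- function(n_directions = 15L, b_value = 800,
                                 seed = 1L, n_iter = 300L) {
  if (n_directions < 6L)
    stop("at least 6 directions are required to determine the tensor")
  if (n_directions == 6L) {
    g <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
               c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)) / sqrt(2)
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    g <- matrix(rnorm(3 * n_directions), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    step <- 0.05
    for (it in seq_len(n_iter)) {
      frc <- matrix(0, n_directions, 3)
      for (i in seq_len(n_directions)) {
        dif1 <- sweep(-g[-i, , drop = FALSE], 2, g[i, ], "+")   # g_i - g_j
        dif2 <- sweep(g[-i, , drop = FALSE], 2, g[i, ], "+")    # g_i + g_j
        r1 <- pmax(sqrt(rowSums(dif1^2)), 1e-6)
        r2 <- pmax(sqrt(rowSums(dif2^2)), 1e-6)
        frc[i, ] <- colSums(dif1 / r1^3) + colSums(dif2 / r2^3)
      }
      g <- g + step * frc
      g <- g / sqrt(rowSums(g^2))
      step <- step * 0.99
    }
    # hemisphere convention: fold to z >= 0 (sign is irrelevant to the fit)
    flip <- g[, 3] < 0
    g[flip, ] <- -g[flip, ]
  }
  scheme <- new_gradient_scheme(rbind(c(0, 0, 0), g),
                                c(0, rep(b_value, n_directions)))
  kap <- design_condition(scheme)
  if (!is.finite(kap) || kap >= 10)
    stop(sprintf("gradient scheme is poorly conditioned (kappa = %.2f)", kap))
  scheme
}

new_gradient_scheme <- function(directions, b_values) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3L, nrow(directions) == length(b_values))
  nz <- b_values > 0
  nrm <- sqrt(rowSums(directions[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("all nonzero-b directions must be unit vectors")
  if (sum(nz) < 6L || sum(!nz) < 1L)
    stop("need >= 6 diffusion-weighted entries and >= 1 b = 0 entry")
  structure(list(directions = directions, b_values = as.numeric(b_values)),
            class = "gradient_scheme")
}

# Design matrix of the log-linear tensor fit: one row per volume,
# columns (1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz);
# the first column absorbs ln S0.
tensor_design <- function(scheme) {
  g <- scheme$directions
  b <- scheme$b_values
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

# Condition number of the direction part of the design (b-scale removed).
design_condition <- function(scheme) {
  nz <- scheme$b_values > 0
  X <- tensor_design(scheme)[nz, -1, drop = FALSE] / max(scheme$b_values)
  sv <- svd(X)$d
  sv[1] / sv[length(sv)]
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d entries (%d diffusion-weighted, b = %g), kappa = %.2f\n",
              length(x$b_values), sum(x$b_values > 0), max(x$b_values),
              design_condition(x)))
  invisible(x)
}

#' Read and write FSL-dialect gradient tables
#'
#' `write_bvals_bvecs()` writes a `.bval` file (one row of b-values) and a
#' `.bvec` file (three rows of x, y, z components, one column per volume);
#' `read_bvals_bvecs()` reads them back into a `gradient_scheme`.
#'
#' @param scheme a `gradient_scheme`.
#' @param prefix file path prefix; `.bval`/`.bvec` are appended.
#' @return `read_bvals_bvecs()` returns a `gradient_scheme`;
#'   `write_bvals_bvecs()` returns the two paths invisibly.
#' @export
write_bvals_bvecs <- function(scheme, prefix) {
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(scheme$b_values, trim = TRUE), collapse = " "), bval)
  writeLines(apply(t(scheme$directions), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec)
  invisible(c(bval = bval, bvec = bvec))
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(prefix) {
  b <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  v <- unname(as.matrix(utils::read.table(paste0(prefix, ".bvec"))))
  new_gradient_scheme(t(v), b)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
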