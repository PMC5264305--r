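test_that("geometry: uniform wall without scar, thinned wall inside the sector", {
  # no-scar identity: thickness equals epi - endo radius everywhere
  p0 <- control_params(grid_shape = c(64L, 64L, 12L), long_axis_extent_mm = 4)
  g0 <- build_geometry(p0)
  seg0 <- partition_lv_segments(g0$lv_mask, g0$blood_mask, p0$voxel_size_mm,
                                apical_fraction = 0)
  th0 <- segment_wall_thickness(seg0, g0$lv_mask)
  expect_true(all(abs(th0$thickness_mm - 7.0) < 0.35))

  # thinning 5.1/7: ray-cast thickness ~5.1 inside the sector, ~7 outside
  p1 <- phantom_params(grid_shape = c(64L, 64L, 12L), long_axis_extent_mm = 4)
  g1 <- build_geometry(p1)
  seg1 <- partition_lv_segments(g1$lv_mask, g1$blood_mask, p1$voxel_size_mm,
                                apical_fraction = 0)
  th1 <- segment_wall_thickness(seg1, g1$lv_mask)
  bin <- th1$segment_id %% 36L
  in_sector <- bin <= 5L           # scar sector [0, 60) deg
  expect_lt(abs(mean(th1$thickness_mm[in_sector]) - 5.1), 0.35)
  expect_lt(abs(mean(th1$thickness_mm[!in_sector & bin >= 8]) - 7.0), 0.35)

  # endocardial-half transmural span: scar occupies half the depth span,
  # i.e. (r_mid^2 - r_endo^2) / (r_epi^2 - r_endo^2) of the sector voxels
  # once the annular area weighting is accounted for
  sector_wall <- g1$lv_mask & myofiber:::phantom_fields(p1)$in_sector
  r_mid <- (8 + 13.1) / 2
  expected <- (r_mid^2 - 8^2) / (13.1^2 - 8^2)
  expect_lt(abs(sum(g1$scar_mask) / sum(sector_wall) - expected), 0.03)

  expect_true(all(g1$lv_mask[g1$scar_mask]))          # scar inside wall
  expect_error(build_geometry(phantom_params(grid_shape = c(32L, 32L, 8L))),
               "grid too small")
})

test_that("ground-truth fibers follow the linear epi-to-endo inclination law", {
  p <- phantom_params(grid_shape = c(64L, 64L, 12L), long_axis_extent_mm = 4,
                      scar_sector_deg = NULL, scar_thinning_factor = 1)
  g <- build_geometry(p)
  gt <- ground_truth_fibers(g, p)
  d <- g$depth_norm
  w <- which(!is.na(d))
  expect_equal(gt$inclination_deg[w], -60 + 112.5 * d[w], tolerance = 1e-10)
  # endpoint and midpoint of the rotation
  expect_equal(unname(gt$inclination_deg[w][which.min(abs(d[w]))][1]),
               -60 + 112.5 * min(d[w]), tolerance = 1e-9)
  mid <- w[abs(d[w] - 0.5) < 1e-9]
  if (length(mid) > 0)
    expect_equal(gt$inclination_deg[mid], rep(-3.75, length(mid)),
                 tolerance = 1e-9)
  # zero imbrication: fibers orthogonal to the local radial direction
  f <- myofiber:::phantom_fields(p)
  th <- f$theta[w] * pi / 180
  radial_dot <- gt$fibers[, , , 1][w] * cos(th) + gt$fibers[, , , 2][w] * sin(th)
  expect_lt(max(abs(radial_dot)), 1e-9)
  expect_equal(max(abs(gt$imbrication_deg[w])), 0)
})

test_that("prolate tensors reproduce the prescribed MD and FA", {
  # fa = 0 collapses to md * identity
  ev0 <- myofiber:::prolate_eigenvalues(6.33e-4, 0)
  expect_equal(unname(ev0[1, ]), rep(6.33e-4, 3))

  # round trip at the normal-tissue values
  ev <- myofiber:::prolate_eigenvalues(6.33e-4, 0.37)
  expect_lt(abs(mean(ev) - 6.33e-4), 1e-10)
  expect_lt(abs(fa_formula(as.numeric(ev)) - 0.37), 1e-10)

  # fibrotic values: closed-form lambda1 against a 1-D root search
  ev_f <- myofiber:::prolate_eigenvalues(9.08e-4, 0.24)
  md <- 9.08e-4
  root <- uniroot(function(l1) {
    l23 <- (3 * md - l1) / 2
    fa_formula(c(l1, l23, l23)) - 0.24
  }, c(md, 3 * md * 0.999), tol = 1e-14)$root
  expect_equal(unname(ev_f[1, 1]), root, tolerance = 1e-8)

  expect_error(myofiber:::prolate_eigenvalues(6e-4, 1), "FA must lie")
})

test_that("DWI simulation follows the monoexponential model with Rician noise", {
  p <- phantom_params(grid_shape = c(24L, 24L, 8L), endo_radius_mm = 2,
                      epi_radius_mm = 5, long_axis_extent_mm = 3,
                      scar_sector_deg = NULL, scar_thinning_factor = 1)
  g <- build_geometry(p)
  gt <- ground_truth_fibers(g, p)
  sch <- make_gradient_scheme(15, seed = 2)

  # isotropic tensor: S/s0 = exp(-b MD) identically across directions
  iso <- assemble_tensors(gt$fibers, 9.08e-4, 0, mask = g$lv_mask,
                          voxel_size_mm = p$voxel_size_mm)
  dwi <- simulate_dwi(iso, sch, s0 = 1000, snr = Inf)
  w <- which(g$lv_mask)
  b0 <- dwi$signals[, , , 1]
  expect_equal(b0[w], rep(1000, length(w)))          # b = 0 volume is s0
  for (v in 2:16) {
    sv <- dwi$signals[, , , v]
    expect_equal(sv[w] / 1000, rep(exp(-0.7264), length(w)),
                 tolerance = 1e-6)
  }

  # anisotropic: attenuation is monotone in |g . e1|
  ani <- assemble_tensors(gt$fibers, 9.08e-4, 0.24, mask = g$lv_mask,
                          voxel_size_mm = p$voxel_size_mm)
  dwi2 <- simulate_dwi(ani, sch, s0 = 1000, snr = Inf)
  vox <- w[1]
  e1 <- c(gt$fibers[, , , 1][vox], gt$fibers[, , , 2][vox],
          gt$fibers[, , , 3][vox])
  gdir <- sch$directions[-1, ]
  align <- abs(gdir %*% e1)
  s_v <- vapply(2:16, function(v) dwi2$signals[, , , v][vox], 0)
  expect_true(all(diff(s_v[order(align)]) <= 1e-9))  # decreasing with alignment
  l1 <- myofiber:::prolate_eigenvalues(9.08e-4, 0.24)[1, 1]
  expect_gte(min(s_v) / 1000, exp(-800 * l1) - 1e-9) # bound at max attenuation

  # reproducibility under a fixed seed
  n1 <- simulate_dwi(ani, sch, s0 = 1000, snr = 120, seed = 9L)
  n2 <- simulate_dwi(ani, sch, s0 = 1000, snr = 120, seed = 9L)
  expect_identical(n1$signals, n2$signals)
  expect_error(simulate_dwi(ani, sch, s0 = -1), "s0")
})

test_that("LGE simulation separates fibrotic and normal intensities", {
  b <- small_noiseless()
  lge0 <- simulate_lge(b$lv_mask, b$scar_mask, sigma = 0)
  expect_setequal(unique(lge0[b$lv_mask]), c(100, 200))
  # empty scar: unimodal wall histogram
  empty <- array(FALSE, dim(b$lv_mask))
  lge1 <- simulate_lge(b$lv_mask, empty, sigma = 0)
  expect_equal(unique(lge1[b$lv_mask]), 100)
  expect_error(simulate_lge(b$lv_mask, b$scar_mask, sigma = -1), "sigma")
  expect_error(simulate_lge(b$lv_mask, b$scar_mask, mu_fibrotic = 50),
               "mu_fibrotic")
})

test_that("gradient schemes are unit-norm, well conditioned and reproducible", {
  sch <- make_gradient_scheme(15, seed = 1)
  expect_equal(length(sch$b_values), 16L)
  expect_equal(sum(sch$b_values == 0), 1L)
  nz <- sch$b_values > 0
  expect_lt(max(abs(sqrt(rowSums(sch$directions[nz, ]^2)) - 1)), 1e-9)
  expect_lt(myofiber:::design_condition(sch), 10)
  expect_identical(sch$directions, make_gradient_scheme(15, seed = 1)$directions)
  expect_false(identical(sch$directions,
                         make_gradient_scheme(15, seed = 2)$directions))
  # n = 6 preset solvable
  sch6 <- make_gradient_scheme(6)
  expect_true(is.finite(myofiber:::design_condition(sch6)))
  expect_error(make_gradient_scheme(5), "at least 6")
})

test_that("phantom bundles are reproducible bit for bit under a fixed seed", {
  p <- phantom_params(grid_shape = c(32L, 32L, 8L), endo_radius_mm = 3,
                      epi_radius_mm = 6, long_axis_extent_mm = 3, seed = 42L)
  b1 <- build_phantom(p)
  b2 <- build_phantom(p)
  expect_identical(b1$dwi$signals, b2$dwi$signals)
  expect_identical(b1$lge, b2$lge)
  expect_true(all(b1$lv_mask[b1$scar_mask]))
})
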