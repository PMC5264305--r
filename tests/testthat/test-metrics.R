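test_that("scar transmurality is the fibrotic voxel fraction", {
  expect_equal(scar_transmurality(40, 100), 0.4)
  expect_equal(scar_transmurality(0, 50), 0)
  expect_true(is.na(scar_transmurality(0, 0)))
  # sigma = 0 phantom with endocardial-half span: transmurality ~0.5
  b <- small_noiseless()
  lge0 <- simulate_lge(b$lv_mask, b$scar_mask, sigma = 0)
  fib <- otsu_fibrosis_mask(lge0, b$lv_mask)
  seg <- partition_lv_segments(b$lv_mask, b$blood_mask,
                               voxel_size_mm = b$params$voxel_size_mm)
  rec <- classify_segments(seg, fib, "infarcted")
  tm <- scar_transmurality(rec$n_fibrotic_voxels, rec$n_voxels)
  core <- rec$angular_bin %in% 1:4       # fully inside the 0-60 deg sector
  # half the depth span, area-weighted over the annular segment
  r_mid <- (8 + 13.1) / 2
  expected <- (r_mid^2 - 8^2) / (13.1^2 - 8^2)
  expect_lt(abs(mean(tm[core]) - expected), 0.03)
})

test_that("transmural profile fit recovers exact lines", {
  d <- seq(0, 7, by = 0.25)
  fit <- transmural_profile_fit(-60 + 16.07 * d, d)
  expect_equal(fit$slope, 16.07, tolerance = 1e-10)
  expect_equal(fit$intercept, -60, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # thinned wall, same endpoints: slope = 112.5 / 5.1
  d2 <- seq(0, 5.1, length.out = 20)
  fit2 <- transmural_profile_fit(-60 + (112.5 / 5.1) * d2, d2)
  expect_equal(fit2$slope, 22.06, tolerance = 1e-3)
  # constant profile: zero slope, zero r2
  fit3 <- transmural_profile_fit(rep(10, 10), seq(0, 7, length.out = 10))
  expect_equal(fit3$slope, 0)
  expect_equal(fit3$r2, 0)
  # degenerate: all depths equal
  fit4 <- transmural_profile_fit(c(1, 2, 3, 4), rep(2, 4))
  expect_true(is.na(fit4$slope))
  # under the reliability bound
  expect_true(is.na(transmural_profile_fit(1:3, 1:3)$slope))
  # tidiers
  td <- tidy(fit)
  expect_equal(td$estimate, c(-60, 16.07), tolerance = 1e-9)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-12)
})

test_that("inclination range uses interpolated 1-99 percentiles", {
  set.seed(8)
  v <- runif(20000, -60, 52.5)
  expect_lt(abs(inclination_range(v) - 0.98 * 112.5), 0.5)
  expect_equal(inclination_range(rep(5, 10)), 0)
  expect_true(is.na(inclination_range(c(1, 2, 3))))
})

test_that("handedness ratios partition the segment", {
  expect_equal(handedness_ratios(rep(0, 10)), c(lh = 0, circ = 1, rh = 0))
  expect_equal(handedness_ratios(c(-20, -16, 0, 16, 20)),
               c(lh = 0.4, circ = 0.2, rh = 0.4))
  # boundary +/-15 goes to the circumferential class
  expect_equal(handedness_ratios(c(-15, 15)), c(lh = 0, circ = 1, rh = 0))
  # uniform [-56.25, 56.25]: lh = (56.25 - 15) / 112.5
  set.seed(9)
  v <- runif(50000, -56.25, 56.25)
  hr <- handedness_ratios(v)
  expect_lt(abs(hr["lh"] - 0.3667), 0.01)
  # partition property over random segments
  for (i in 1:20) {
    hr <- handedness_ratios(runif(sample(5:50, 1), -90, 90))
    expect_equal(unname(sum(hr)), 1, tolerance = 1e-9)
  }
})

test_that("imbrication mean is the signed average", {
  expect_equal(imbrication_mean(rep(0, 5)), 0)
  expect_equal(imbrication_mean(c(-10, 10)), 0)
  expect_equal(imbrication_mean(c(2, 4, 9)), 5)
  # phantom with an injected +5 degree tilt recovers it
  p <- phantom_params(grid_shape = c(64L, 64L, 12L), long_axis_extent_mm = 4,
                      imbrication_deg = 5, snr = Inf,
                      scar_sector_deg = NULL, scar_thinning_factor = 1)
  b <- build_phantom(p)
  tf <- fit_tensor(b$dwi)
  fr <- compute_local_frame(b$lv_mask, b$blood_mask,
                            voxel_size_mm = p$voxel_size_mm)
  am <- angle_maps(tf, fr)
  interior <- myofiber:::erode6(b$lv_mask)
  expect_lt(abs(imbrication_mean(am$imbrication_deg[interior]) - 5), 1)
})

test_that("incoherency is the mean acute neighbour-pair difference", {
  d <- c(6, 6, 4)
  lab <- array(1L, d)
  # constant field: zero incoherency
  expect_equal(angle_incoherency(array(30, d), lab)$incoherency_deg, 0)
  # alternating +/-10 checkerboard: every pair differs by 20
  idx <- array(seq_len(prod(d)), d)
  parity <- (slice.index(idx, 1) + slice.index(idx, 2) +
               slice.index(idx, 3)) %% 2
  field <- ifelse(parity == 0, 10, -10)
  expect_equal(angle_incoherency(field, lab)$incoherency_deg, 20)
  # axial wrap: +80 vs -80 differ by 20, not 160
  field2 <- ifelse(parity == 0, 80, -80)
  expect_equal(angle_incoherency(field2, lab)$incoherency_deg, 20)
  # isolated voxels: undefined (absent from the table)
  lab2 <- array(NA_integer_, d); lab2[1, 1, 1] <- 1L
  expect_equal(nrow(angle_incoherency(field, lab2)), 0L)
})

test_that("incoherency grows as SNR falls, at fixed ground truth", {
  p <- phantom_params(grid_shape = c(64L, 64L, 10L), long_axis_extent_mm = 3)
  vals <- vapply(c(120, 60, 30), function(s) {
    out <- 0
    for (sd_ in 1:2) {
      b <- build_phantom(phantom_params(grid_shape = c(64L, 64L, 10L),
                                        long_axis_extent_mm = 3, snr = s,
                                        seed = sd_))
      tf <- fit_tensor(b$dwi)
      fr <- compute_local_frame(b$lv_mask, b$blood_mask,
                                voxel_size_mm = b$params$voxel_size_mm)
      am <- angle_maps(tf, fr)
      lab <- array(1L, dim(b$lv_mask)); lab[!b$lv_mask] <- NA_integer_
      out <- out + angle_incoherency(am$inclination_deg, lab)$incoherency_deg
    }
    out / 2
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("segment metrics integrate the analytic ground truth", {
  ha <- small_analysis()
  m <- ha$metrics[!ha$metrics$excluded, ]
  # away from the scar sector and from the wall-thickness step at its rim
  # (the step genuinely shortens epicardial distances nearby)
  ctrl <- m[m$status == "other" & m$angular_bin >= 10 & m$angular_bin <= 30, ]
  expect_lt(abs(mean(ctrl$slope_deg_per_mm) - 112.5 / 7) / (112.5 / 7), 0.05)
  expect_lt(abs(mean(ctrl$intercept_deg) - (-60)), 3)
  expect_true(all(ctrl$r2 > 0.97))
  expect_gt(mean(ctrl$inclination_range_deg), 100)
  expect_lt(mean(ctrl$inclination_range_deg), 112.5)
  expect_lt(abs(mean(ctrl$lh_ratio) - 0.47), 0.04)  # radius-weighted 0.4 law
  inf <- m[m$status == "infarcted" & m$angular_bin %in% 1:4, ]
  expect_lt(abs(mean(inf$slope_deg_per_mm) - 112.5 / 5.1) / (112.5 / 5.1),
            0.05)
  # endocardial-half scar span, area-weighted on the annulus (~0.44)
  expect_lt(abs(mean(inf$transmurality) -
                  (10.55^2 - 8^2) / (13.1^2 - 8^2)), 0.03)
  # ratio partition on every computed segment
  s <- m$lh_ratio + m$circ_ratio + m$rh_ratio
  expect_true(all(abs(s[!is.na(s)] - 1) < 1e-9))
  # internal consistency: slope x thickness ~ full angle span
  expect_lt(abs(mean(ctrl$slope_deg_per_mm * ctrl$thickness_mm) - 112.5) /
              112.5, 0.05)
})

test_that("slope varies with inverse thickness when the range is preserved", {
  ha <- small_analysis()
  m <- ha$metrics[!ha$metrics$excluded, ]
  r <- pearson_r(m$slope_deg_per_mm, 1 / m$thickness_mm)
  expect_gt(r, 0.5)   # sign/mechanism check; the magnitude is data-specific
})
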