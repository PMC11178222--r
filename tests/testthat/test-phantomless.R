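test_that("reference point is the head/knee midpoint", {
  expect_equal(compute_rp(c(0, 0, 0), c(0, 0, -400)), c(0, 0, -200))
  p <- c(12, -3, 77)
  expect_equal(compute_rp(p, p), p)
  expect_equal(compute_rp(c(10, 20, 100), c(30, -20, -300)), c(20, 0, -100))
})

test_that("VOI spans the slice nearest RP plus caudal slices, inclusive", {
  # caudal = increasing index here (axis label I)
  vol <- ct_volume(array(0, dim = c(12, 12, 40)), spacing = c(2, 2, 3),
                   orientation = c("L", "P", "I"))
  # slice k is at patient z = -(k - 1) * 3; RP at z of slice 20
  rp <- c(6, 6, -(20 - 1) * 3)
  mask <- build_voi_cut(vol, rp, n_slices = 9, posterior_offset = 1e6)
  expect_equal(attr(mask, "slices"), 20:28)
  used <- which(apply(mask, 3, any))
  expect_equal(used, 20:28)
  expect_equal(attr(mask, "height_mm"), 27)

  # caudal = decreasing index for an S-oriented axis
  vol2 <- ct_volume(array(0, dim = c(12, 12, 40)), spacing = c(2, 2, 3),
                    orientation = c("L", "P", "S"))
  rp2 <- c(6, 6, (20 - 1) * 3)
  mask2 <- build_voi_cut(vol2, rp2, n_slices = 9, posterior_offset = 1e6)
  expect_equal(attr(mask2, "slices"), 12:20)
})

test_that("the posterior cut removes voxels beyond the OP plane", {
  vol <- ct_volume(array(0, dim = c(12, 80, 20)), spacing = c(2, 2, 3))
  rp <- c(10, 40, 30)  # posterior coordinate y = 40; OP at y = 90
  mask <- build_voi_cut(vol, rp, n_slices = 3, posterior_offset = 50)
  yy <- (seq_len(80) - 1) * 2
  kept_rows <- which(apply(mask, 2, any))
  expect_true(all(yy[kept_rows] <= 90 + 1e-9))
  # a voxel 60 mm posterior of RP (y = 100) is excluded, 40 mm is kept
  expect_false(any(mask[, which(yy == 100), ]))
  expect_true(any(mask[, which(yy == 80), ]))
})

test_that("VOI construction fails cleanly at the volume edge", {
  vol <- ct_volume(array(0, dim = c(8, 8, 12)), spacing = c(2, 2, 3))
  # RP in the most caudal slice (z = 0 for an S axis)
  expect_error(build_voi_cut(vol, c(4, 4, 0), n_slices = 9), "fewer than 9")
  expect_error(build_voi_cut(vol, c(4, 4, 500)), "outside")
  expect_error(build_voi_cut(vol, c(4, 4, 15), n_slices = 0), ">= 1")
})

test_that("VOI voxel count scales linearly with slice count", {
  vol <- ct_volume(array(0, dim = c(10, 10, 30)), spacing = c(1, 1, 1))
  rp <- c(5, 3, 25)
  n1 <- sum(build_voi_cut(vol, rp, n_slices = 1, posterior_offset = 4))
  for (k in c(3, 6, 9)) {
    nk <- sum(build_voi_cut(vol, rp, n_slices = k, posterior_offset = 4))
    expect_equal(nk, k * n1)
  }
  # and is non-increasing as the posterior cut tightens
  counts <- vapply(c(8, 6, 4, 2, 0), function(off)
    sum(build_voi_cut(vol, rp, n_slices = 9, posterior_offset = off)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("kernel density matches the direct-summation oracle", {
  set.seed(31)
  # two well separated equal-mass clusters
  x <- c(rnorm(600, -1000, 2), rnorm(600, 40, 2))
  d <- fit_kde(x, bandwidth = 5, grid_step = 1, min_samples = 1000)
  expect_true(all(d$density >= 0))
  oracle <- kde_oracle(x, d$grid, 5)
  expect_equal(d$density, oracle, tolerance = 1e-12)
  # the numerical integral is ~1
  expect_equal(sum(d$density) * d$grid_step, 1, tolerance = 0.01)
  # the grid covers the sample range plus 3 bandwidths
  expect_equal(min(d$grid), min(x) - 15)
  expect_lte(max(d$grid), max(x) + 15)
  expect_gt(max(d$grid), max(x) + 14)
  # local maxima within 1 grid step of the oracle modes
  m_air <- kde_mode_oracle(x, d$grid, 5, c(-1050, -950))
  m_mus <- kde_mode_oracle(x, d$grid, 5, c(0, 90))
  is_max <- which(diff(sign(diff(d$density))) == -2) + 1L
  expect_true(any(abs(d$grid[is_max] - m_air) <= 1))
  expect_true(any(abs(d$grid[is_max] - m_mus) <= 1))
})

test_that("a degenerate constant sample peaks at the sample value", {
  x <- rep(-153.4, 1500)
  d <- fit_kde(x)
  k <- which.max(d$density)
  expect_lte(abs(d$grid[k] - (-153.4)), 0.5 + 1e-9)
  expect_gt(d$density[k], max(d$density[-k]))
})

test_that("undersized or invalid HU samples are rejected", {
  expect_error(fit_kde(numeric(0)), "0 values")
  expect_error(fit_kde(rnorm(999)), "999")
  expect_error(fit_kde(rnorm(2000), bandwidth = 0), "bandwidth")
  expect_error(fit_kde(rnorm(2000), grid_step = -1), "grid_step")
})

test_that("tissue peaks resolve to the per-window oracle modes", {
  set.seed(77)
  x <- c(rnorm(5000, -1000, 12), rnorm(3000, -100, 10), rnorm(2000, 40, 8))
  d <- fit_kde(x)
  refs <- default_tissue_references()
  pk <- detect_tissue_peaks(d, refs)
  for (tissue in c("air", "adipose", "muscle")) {
    m <- kde_mode_oracle(x, d$grid, 5, refs[[tissue]]$hu_window)
    expect_lte(abs(pk[[tissue]] - m), 1)
  }
})

test_that("a missing tissue peak is an error naming the tissue", {
  set.seed(78)
  x <- c(rnorm(2000, -1000, 10), rnorm(2000, 40, 8))  # no adipose
  d <- fit_kde(x)
  expect_error(detect_tissue_peaks(d), "adipose")
})

test_that("with two candidate maxima the denser one wins", {
  set.seed(79)
  x <- c(rnorm(2000, -1000, 8), rnorm(2000, -100, 8),
         rnorm(700, 30, 3), rnorm(1400, 70, 3))  # bimodal muscle window
  d <- fit_kde(x)
  pk <- detect_tissue_peaks(d)
  m30 <- kde_oracle(x, 30, 5)
  m70 <- kde_oracle(x, 70, 5)
  expect_gt(m70, m30)  # sanity: the 70 HU mode really is denser
  expect_lt(abs(pk[["muscle"]] - 70), 2)
})

test_that("phantomless line fits the three (peak, reference) pairs by OLS", {
  refs <- default_tissue_references()
  ident <- fit_phantomless_calibration(
    c(air = -797, adipose = -95, muscle = 38), refs)
  expect_equal(ident$slope, 1, tolerance = 1e-9)
  expect_equal(ident$intercept, 0, tolerance = 1e-7)
  expect_equal(ident$r_squared, 1, tolerance = 1e-12)
  expect_identical(ident$method, "phantomless")

  peaks <- c(air = -1000, adipose = -100, muscle = 40)
  line <- fit_phantomless_calibration(peaks, refs)
  oracle <- ols_oracle(unname(peaks), c(-797, -95, 38))
  expect_equal(line$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(line$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(line$slope, 0.7947, tolerance = 1e-4)
  expect_equal(line$intercept, -3.88, tolerance = 1e-2)
})

test_that("phantomless fitting rejects degenerate peak sets", {
  refs <- default_tissue_references()
  expect_error(fit_phantomless_calibration(
    c(air = -1000, adipose = -100, muscle = -100), refs), "duplicated")
  expect_error(fit_phantomless_calibration(c(air = -1000, muscle = 40),
                                           refs), "three")
  expect_error(fit_phantomless_calibration(c(-1000, -100, 40), refs),
               "named")
})

test_that("tissue reference validation enforces order and disjoint windows", {
  expect_error(default_tissue_references(densities = c(-797, 38, -95)),
               "ordered")
  expect_error(default_tissue_references(
    windows = list(c(-1050, -850), c(-900, -30), c(10, 90))), "disjoint")
  expect_error(tissue_reference("air", -797, c(10, -10)), "increasing")
})

test_that("cohort reference densities average phantom-calibrated peaks", {
  ident <- identity_line()
  one <- list(s1 = list(peaks = c(air = -797, adipose = -95, muscle = 38),
                        line = ident))
  rd1 <- derive_reference_densities(one)
  expect_equal(rd1$summary$mean, c(-797, -95, 38))

  two <- list(
    a = list(peaks = c(air = -800, adipose = -96, muscle = 38), line = ident),
    b = list(peaks = c(air = -794, adipose = -94, muscle = 38), line = ident)
  )
  rd2 <- derive_reference_densities(two)
  expect_equal(rd2$summary$mean, c(-797, -95, 38))
  expect_equal(rd2$summary$sd,
               c(sd(c(-800, -794)), sd(c(-96, -94)), sd(c(38, 38))))

  # permutation invariance in subject order
  rd2r <- derive_reference_densities(rev(two))
  expect_equal(rd2r$summary$mean, rd2$summary$mean)
  expect_equal(rd2r$summary$sd, rd2$summary$sd)

  # a non-identity line calibrates the peaks before averaging
  line <- calibration_line(intercept = -12.5, slope = 0.625)
  rd3 <- derive_reference_densities(
    list(list(peaks = c(air = -1255.2, adipose = -132, muscle = 80.8),
              line = line)))
  expect_equal(rd3$summary$mean, c(-797, -95, 38), tolerance = 1e-9)
})

test_that("incomplete cohort subjects fail with the subject named", {
  ident <- identity_line()
  subs <- list(
    ok = list(peaks = c(air = -797, adipose = -95, muscle = 38),
              line = ident),
    bad = list(peaks = c(air = -797, muscle = 38), line = ident)
  )
  expect_error(derive_reference_densities(subs), "bad")
  subs2 <- list(noline = list(
    peaks = c(air = -797, adipose = -95, muscle = 38)))
  expect_error(derive_reference_densities(subs2), "noline")
  expect_error(derive_reference_densities(list()), "at least one")
})
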