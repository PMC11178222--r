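test_that("rmsre matches hand-evaluated cases and is zero on identity", {
  expect_equal(rmsre(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsre(100, 110), 10 / 105, tolerance = 1e-12)
  expect_equal(rmsre(c(2, 4), c(2, 2)), sqrt((0 + (2 / 3)^2) / 2),
               tolerance = 1e-12)
})

test_that("rmsre is symmetric and strictly positive off the diagonal", {
  set.seed(21)
  for (i in 1:20) {
    x <- runif(sample(1:30, 1), 10, 1000)
    y <- x * runif(length(x), 0.8, 1.2)
    expect_equal(rmsre(x, y), rmsre(y, x), tolerance = 1e-14)
    expect_gte(rmsre(x, y), 0)
    if (any(x != y)) expect_gt(rmsre(x, y), 0)
  }
})

test_that("relative differences use the pairwise mean normalizer", {
  expect_equal(relative_differences(100, 100), 0)
  expect_equal(relative_differences(100, 110), 100 * 10 / 105,
               tolerance = 1e-12)
  expect_error(relative_differences(0, 0), "index 1")
  expect_error(rmsre(c(5, 1), c(5, -1)), "index 2")
  expect_error(rmsre(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("rmsre equals the rms of the relative differences", {
  set.seed(22)
  for (i in 1:10) {
    x <- runif(50, 100, 2000)
    y <- x * runif(50, 0.9, 1.1)
    rd <- relative_differences(x, y) / 100
    expect_equal(rmsre(x, y), sqrt(mean(rd^2)), tolerance = 1e-13)
  }
})

test_that("the 1.5 IQR screen reproduces the worked example", {
  r <- iqr_filter(c(1:9, 100))
  # Q1 = 3.25, Q3 = 7.75 under linear interpolation; upper fence 14.5
  expect_equal(r$fences, c(3.25 - 1.5 * 4.5, 7.75 + 1.5 * 4.5))
  expect_equal(r$removed, 100)
  expect_equal(r$kept, 1:9)
})

test_that("the IQR screen partitions its input and keeps ties intact", {
  expect_equal(iqr_filter(rep(7, 10))$removed, numeric(0))
  set.seed(23)
  for (i in 1:20) {
    v <- rnorm(sample(4:200, 1))
    r <- iqr_filter(v)
    expect_equal(sort(c(r$kept, r$removed)), sort(v))
    o <- iqr_oracle(v)
    expect_equal(sort(r$kept), sort(o$kept), tolerance = 1e-12)
    expect_equal(r$fences, o$fences, tolerance = 1e-12)
  }
  expect_error(iqr_filter(1:3), "at least 4")
})

test_that("regression agreement matches the closed form", {
  r <- regression_agreement(c(1, 2, 3), 2 * c(1, 2, 3))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  r2 <- regression_agreement(c(1, 2, 3), c(1, 2, 3) + 5)
  expect_equal(r2$slope, 1, tolerance = 1e-12)
  expect_equal(r2$intercept, 5, tolerance = 1e-12)

  r3 <- regression_agreement(c(1, 2, 3), c(1, 2, 4))
  o <- ols_oracle(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r3$slope, 1.5, tolerance = 1e-12)
  expect_equal(r3$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(r3$intercept, -2 / 3, tolerance = 1e-12)
  expect_equal(r3$r_squared, 0.9643, tolerance = 1e-4)

  expect_error(regression_agreement(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(regression_agreement(c(1, 2), c(1, 2)), "at least 3")
})

make_field_pair <- function(x, y) {
  d <- c(length(x), 1L, 1L)
  vol_a <- ct_volume(array(x, dim = d))
  vol_b <- ct_volume(array(y, dim = d))
  mask <- array(TRUE, dim = d)
  law <- elasticity_law(coefficient = 1, exponent = 1, qct_to_ash = 1000,
                        ash_to_apparent = 1)
  list(a = calibrated_modulus_field(vol_a, identity_line(), mask, law),
       b = calibrated_modulus_field(vol_b, identity_line(), mask, law))
}

test_that("field comparison reports the closed form for uniform scaling", {
  set.seed(24)
  x <- runif(500, 1000, 15000)
  p <- make_field_pair(x, 1.02 * x)
  rep <- compare_fields(p$a, p$b)
  expect_equal(rep$rmsre, 0.02 / 1.01, tolerance = 1e-12)
  expect_equal(rep$rmsre_pct, 100 * 0.02 / 1.01, tolerance = 1e-10)
  expect_equal(rep$mean_rel_diff, 100 * 0.02 / 1.01, tolerance = 1e-10)
  expect_equal(rep$n_outliers_removed, 0L)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)
  expect_equal(rep$n_total, 500L)

  ident <- compare_fields(p$a, p$a)
  expect_equal(ident$rmsre, 0)
  expect_equal(ident$mean_rel_diff, 0)
  expect_equal(ident$r_squared, 1)
})

test_that("the outlier screen trims summaries but never the RMSRE", {
  set.seed(25)
  x <- runif(200, 5000, 6000)
  y <- x * (1 + rnorm(200, 0, 0.01))
  y[1] <- x[1] * 2  # gross outlier
  p <- make_field_pair(x, y)
  scr <- compare_fields(p$a, p$b, with_outlier_removal = TRUE)
  raw <- compare_fields(p$a, p$b, with_outlier_removal = FALSE)
  expect_equal(scr$rmsre, raw$rmsre, tolerance = 1e-14)
  expect_gt(scr$n_outliers_removed, 0)
  expect_lt(scr$max_rel_diff, raw$max_rel_diff)
  expect_equal(length(scr$per_item_diffs), 200L)
})

test_that("fields on different masks cannot be compared", {
  vol <- ct_volume(array(runif(27, 100, 200), dim = c(3, 3, 3)))
  m1 <- array(TRUE, dim = c(3, 3, 3))
  m2 <- m1; m2[1, 1, 1] <- FALSE
  f1 <- calibrated_modulus_field(vol, identity_line(), m1)
  f2 <- calibrated_modulus_field(vol, identity_line(), m2)
  expect_error(compare_fields(f1, f2), "different masks")
})
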