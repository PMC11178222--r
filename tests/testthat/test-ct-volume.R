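test_that("voxel/world mapping round-trips for arbitrary orientations", {
  set.seed(42)
  orients <- list(c("L", "P", "S"), c("R", "A", "I"), c("P", "S", "L"),
                  c("I", "L", "A"), c("S", "R", "P"))
  for (o in orients) {
    vol <- ct_volume(array(0, dim = c(5, 7, 6)),
                     spacing = runif(3, 0.5, 3),
                     origin = runif(3, -100, 100), orientation = o)
    idx <- cbind(sample(5, 20, TRUE), sample(7, 20, TRUE),
                 sample(6, 20, TRUE))
    back <- world_to_voxel(vol, voxel_to_world(vol, idx))
    expect_equal(back, idx * 1.0, tolerance = 1e-12)
  }
})

test_that("origin maps to the first voxel centre and bounds are ordered", {
  vol <- ct_volume(array(0, dim = c(4, 4, 3)), spacing = c(2, 2, 3),
                   origin = c(10, -5, 40))
  expect_equal(voxel_to_world(vol, c(1, 1, 1)), c(10, -5, 40))
  b <- volume_bounds(vol)
  expect_true(all(b["max", ] >= b["min", ]))
  expect_equal(unname(b["max", ] - b["min", ]), c(3 * 2, 3 * 2, 2 * 3))
})

test_that("volume construction rejects invalid geometry", {
  a <- array(0, dim = c(2, 2, 2))
  expect_error(ct_volume(a, spacing = c(1, 0, 1)), "positive")
  expect_error(ct_volume(a, orientation = c("L", "R", "S")), "distinct")
  expect_error(ct_volume(a, orientation = c("L", "P", "Q")), "labels")
  expect_error(ct_volume(matrix(0, 2, 2)), "3-D")
})

test_that("knee centre is the epicondyle midpoint", {
  expect_equal(knee_center(c(10, 0, 0), c(-10, 0, 0)), c(0, 0, 0))
  p <- c(3.5, -2, 88)
  expect_equal(knee_center(p, p), p)
  expect_equal(knee_center(c(40, 20, -380), c(-20, 30, -384)),
               c(10, 25, -382))
  expect_error(knee_center(c(1, 2), c(1, 2, 3)), "length-3")
})

test_that("landmark files round-trip, derive the knee centre, and convert RAS", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(convention = "LPS",
                            head_center = c(0, 10, 100),
                            medial_epicondyle = c(30, 12, -300),
                            lateral_epicondyle = c(-30, 8, -302)),
                       f, auto_unbox = TRUE, digits = NA)
  lm <- read_landmarks(f)
  expect_s3_class(lm, "landmarks")
  expect_equal(lm$knee_center, c(0, 10, -301))

  # explicit knee centre, no epicondyles
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(convention = "LPS", head_center = c(0, 0, 0),
                            knee_center = c(0, 0, -400)),
                       f2, auto_unbox = TRUE, digits = NA)
  expect_equal(read_landmarks(f2)$knee_center, c(0, 0, -400))

  # RAS coordinates are negated in x and y on load
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(convention = "RAS", head_center = c(1, 2, 3),
                            knee_center = c(-4, 5, -6)),
                       f3, auto_unbox = TRUE, digits = NA)
  lm3 <- read_landmarks(f3)
  expect_equal(lm3$head_center, c(-1, -2, 3))
  expect_equal(lm3$knee_center, c(4, -5, -6))

  # write/read round trip
  f4 <- tempfile(fileext = ".json")
  write_landmarks(lm, f4)
  expect_equal(read_landmarks(f4)$knee_center, lm$knee_center)
})

test_that("landmark files with missing or malformed content fail loudly", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(convention = "LPS",
                            medial_epicondyle = c(0, 0, 0)),
                       f, auto_unbox = TRUE, digits = NA)
  expect_error(read_landmarks(f), "head_center")
  expect_error(read_landmarks(f), "knee_center")

  f2 <- tempfile(fileext = ".json")
  writeLines("{not json", f2)
  expect_error(read_landmarks(f2), "parse")

  expect_error(read_landmarks(tempfile()), "no such")
})

test_that("landmarks outside the volume trigger a warning, not an error", {
  vol <- ct_volume(array(0, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
  lm_in <- landmarks(head_center = c(5, 5, 15), knee_center = c(5, 5, 2))
  expect_silent(check_landmarks(vol, lm_in))
  lm_out <- landmarks(head_center = c(500, 5, 5), knee_center = c(5, 5, 2))
  expect_warning(check_landmarks(vol, lm_out), "head_center")
})

test_that("NIfTI write/read round-trips voxels and geometry bit-exactly", {
  set.seed(7)
  vol <- ct_volume(array(rnorm(4 * 5 * 6, sd = 300), dim = c(4, 5, 6)),
                   spacing = c(0.8, 0.8, 2.5), origin = c(-60, -110, 40),
                   orientation = c("L", "P", "S"))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_identical(back$voxels, vol$voxels)
  # geometry is stored in float32 NIfTI header fields
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  expect_identical(back$orientation, vol$orientation)

  # a flipped orientation survives the round trip too
  vol2 <- ct_volume(vol$voxels, spacing = vol$spacing, origin = vol$origin,
                    orientation = c("R", "P", "I"))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(vol2, f2)
  expect_identical(read_volume(f2)$orientation, c("R", "P", "I"))
})

test_that("masks can be written through a template volume", {
  vol <- ct_volume(array(rnorm(60), dim = c(3, 4, 5)), spacing = c(1, 1, 2))
  mask <- array(FALSE, dim = c(3, 4, 5)); mask[1:2, 1, 1] <- TRUE
  f <- tempfile(fileext = ".nii.gz")
  write_volume(mask, f, template = vol)
  back <- read_volume(f)
  expect_equal(back$voxels > 0.5, mask)
  expect_error(write_volume(mask, f), "template")
})

test_that("oblique volumes are rejected on read", {
  img <- RNifti::asNifti(array(0, dim = c(4, 4, 4)))
  th <- 10 * pi / 180  # 10 degrees: beyond the 5-degree acceptance cone
  M <- diag(4)
  M[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  img <- RNifti::`sform<-`(img, structure(M, code = 2L))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "oblique")
})
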