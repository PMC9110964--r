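test_that("band_shift maps the published band endpoints and midpoint", {
  v <- make_volume(c(-548, 800, 126, -1000, 3000, 0, rep(0, 2)), c(2, 2, 2))
  s <- band_shift(v)
  vals <- as.vector(s$voxels)
  expect_identical(vals[1], 0)        # f(-548) = 0
  expect_identical(vals[2], 255)      # f(800) = 255
  expect_equal(vals[3], 127.5)        # band midpoint -> output midpoint
  expect_identical(vals[4], 0)        # clamp below
  expect_identical(vals[5], 255)      # clamp above
  expect_identical(s$intensity_domain, "shifted")
  expect_error(band_shift(s), "already")
})

test_that("band_shift is strictly monotone in band and invertible", {
  spec <- band_shift_spec()
  hu <- seq(-548, 800, length.out = 200)
  out <- band_shift_values(hu, spec)
  expect_true(all(diff(out) > 0))
  # inverse linear map round trip
  back <- spec$input_low + (out - spec$output_low) *
    (spec$input_high - spec$input_low) /
    (spec$output_high - spec$output_low)
  expect_equal(back, hu, tolerance = 1e-9)
})

test_that("band_shift_spec validates edges", {
  expect_error(band_shift_spec(input_low = 10, input_high = 10), "low < high")
})

test_that("median_denoise matches the brute-force oracle and its bounds", {
  # constant volume unchanged
  v <- make_volume(rep(7, 64), c(4, 4, 4))
  expect_identical(median_denoise(v)$voxels, v$voxels)
  # impulse removal
  imp <- array(0, c(5, 5, 5)); imp[3, 3, 3] <- 255
  expect_true(all(median_denoise(make_volume(imp))$voxels == 0))
  # oracle equivalence and order-statistic bounds on random volumes
  set.seed(42)
  for (d in list(c(6, 5, 4), c(10, 10, 10))) {
    vals <- array(sample.int(255, prod(d), replace = TRUE), dim = d)
    got <- median_denoise(make_volume(vals), radius = 1)$voxels
    expect_equal(got, median_oracle(vals, 1))
    expect_true(min(got) >= min(vals) && max(got) <= max(vals))
  }
  expect_error(median_denoise(v, radius = 0), ">= 1")
})

test_that("resample honours identity, exact shifts and constancy", {
  set.seed(5)
  v <- make_volume(rnorm(6 * 6 * 6), c(6, 6, 6))
  # identity
  r <- resample(v, rigid_transform(), reference = v)
  expect_equal(r$voxels, v$voxels, tolerance = 1e-12)
  # exact one-voxel shift along x: transform maps p -> p + (1,0,0), so the
  # output at index i equals the input at index i+1
  r1 <- resample(v, rigid_transform(translation = c(1, 0, 0)),
                 reference = v, default_value = -999)
  expect_equal(r1$voxels[1:5, , ], v$voxels[2:6, , ], tolerance = 1e-12)
  expect_true(all(r1$voxels[6, , ] == -999))
  # constant volume stays constant in the overlap under any transform
  cst <- make_volume(rep(3.25, 8^3), c(8, 8, 8))
  rc <- resample(cst, rigid_transform(rotation = c(0.1, -0.05, 0.2),
                                      translation = c(1.5, -2, 0.7),
                                      center = c(3.5, 3.5, 3.5)),
                 reference = cst, default_value = NA)
  inside <- !is.na(rc$voxels)
  expect_true(sum(inside) > 100)
  expect_true(all(abs(rc$voxels[inside] - 3.25) < 1e-9))
})

test_that("rigid transforms compose and invert to identity", {
  tr <- rigid_transform(rotation = c(0.03, -0.02, 0.05),
                        translation = c(3, -2, 1), center = c(10, 20, 30))
  pts <- matrix(rnorm(30, sd = 40), ncol = 3)
  back <- transform_points(transform_inverse(tr), transform_points(tr, pts))
  expect_equal(back, pts, tolerance = 1e-6)
  comp <- transform_compose(transform_inverse(tr), tr)
  moved <- transform_points(comp, pts)
  expect_equal(moved, pts, tolerance = 1e-6)
})
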