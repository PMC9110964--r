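test_that("phantom labels voxelize to their analytic volumes", {
  ph <- generate_phantom(phantom_spec())
  lab <- ph$truth$label_map
  # stone voxel count vs analytic ellipsoid volume (voxelization error)
  stone_count <- sum(lab == 4L)
  expect_lt(abs(stone_count - ph$truth$stone_mm3) / ph$truth$stone_mm3, 0.05)
  # collecting-system cavity (contrast + stone) vs analytic
  cs_count <- sum(lab %in% c(3L, 4L))
  expect_lt(abs(cs_count - ph$truth$collecting_system_mm3) /
              ph$truth$collecting_system_mm3, 0.10)
  # labels exhaustive and exclusive by construction
  expect_true(all(lab %in% 0:4))
  expect_identical(dim(lab), dim(ph$native$voxels))
})

test_that("noise-free identity phantom differs only in the contrast region", {
  spec <- phantom_spec(noise_sd = 0, misalignment = rigid_transform())
  ph <- generate_phantom(spec)
  diff <- ph$delayed$voxels != ph$native$voxels
  cs <- ph$truth$label_map == 3L  # stone (4) keeps its value in both phases
  expect_identical(unname(which(diff)), unname(which(cs)))
  # contrast sits at its stated mean
  expect_true(all(ph$delayed$voxels[cs] == spec$hu$contrast))
})

test_that("phantom generation is bitwise deterministic in the seed", {
  a <- generate_phantom(phantom_spec(seed = 5L))
  b <- generate_phantom(phantom_spec(seed = 5L))
  expect_identical(a$native$voxels, b$native$voxels)
  expect_identical(a$delayed$voxels, b$delayed$voxels)
  c_ <- generate_phantom(phantom_spec(seed = 6L))
  expect_false(identical(a$native$voxels, c_$native$voxels))
})

test_that("verify_bands audits tissue placements", {
  audit <- verify_bands(phantom_spec())
  expect_true(attr(audit, "pass"))
  # shifted means land where the thresholds expect them
  bone <- audit[audit$tissue == "bone" & audit$band == "skeleton_native", ]
  expect_equal(bone$shifted_mean, 255 * (300 + 548) / 1348, tolerance = 1e-9)
  # a 500 HU stone misses the calculus band: f(500) ~ 198.2 < 250
  bad <- phantom_spec(hu = list(background = -80, soft_tissue = 40,
                                bone = 300, contrast = 450, stone = 500))
  audit2 <- verify_bands(bad)
  expect_false(attr(audit2, "pass"))
  stone_row <- audit2[audit2$tissue == "stone", ]
  expect_false(stone_row$pass)
  expect_equal(stone_row$shifted_mean, 255 * 1048 / 1348, tolerance = 1e-9)
  expect_error(generate_phantom(bad), "spec error")
  # zero noise: probability masses collapse to 0 or 1
  masses <- verify_bands(phantom_spec(noise_sd = 0))$band_mass
  expect_true(all(masses %in% c(0, 1)))
})

test_that("truth masks and dice behave", {
  ph <- generate_phantom(phantom_spec())
  bone <- truth_mask(ph$truth, "bone")
  expect_identical(sum(bone$bits), sum(ph$truth$label_map == 2L))
  both <- truth_mask(ph$truth, c("collecting_system", "stone"))
  expect_identical(sum(both$bits), sum(ph$truth$label_map %in% 3:4))
  expect_equal(dice_coefficient(bone, bone), 1)
  expect_error(truth_mask(ph$truth, "vessel"), "unknown")
})

test_that("halving the voxel size reduces stone voxelization error", {
  # same physical anatomy sampled at 1 mm and 0.5 mm
  base <- function(spacing, shape) phantom_spec(
    grid_shape = shape, spacing = spacing,
    stone_ellipsoids = list(list(center = c(24, 24, 24),
                                 semi_axes = c(8, 6, 5))),
    pelvis = list(center = c(24, 24, 24), semi_axes = c(16, 12, 10)),
    calyces = list(list(direction = c(0.894, 0.447, 0), radius = 4,
                        length = 8)),
    bone_cylinders = list(list(center_xy = c(8, 24), radius = 6),
                          list(center_xy = c(40, 24), radius = 6)),
    body = list(center_xy = c(24, 24), semi_axes_xy = c(23, 20)),
    misalignment = rigid_transform(), noise_sd = 0)
  coarse <- generate_phantom(base(c(1, 1, 1), c(48L, 48L, 48L)))
  fine <- generate_phantom(base(c(0.5, 0.5, 0.5), c(96L, 96L, 96L)))
  true_vol <- coarse$truth$stone_mm3
  err_c <- abs(sum(coarse$truth$label_map == 4L) * 1 - true_vol)
  err_f <- abs(sum(fine$truth$label_map == 4L) * 0.125 - true_vol)
  expect_lt(err_f, err_c)
})
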