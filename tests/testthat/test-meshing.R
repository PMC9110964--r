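# hand-built unit cube: 8 vertices, 12 triangles, outward winding
unit_cube_mesh <- function(offset = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  v <- sweep(v, 2, offset, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 face (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = 1 (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = 1 (+x)
  surface_mesh(v, f, label = "cube")
}

test_that("mesh_measures returns closed-form cube volume and area", {
  cube <- unit_cube_mesh()
  mm <- mesh_measures(cube)
  expect_equal(mm$volume_mm3, 1, tolerance = 1e-12)
  expect_equal(mm$area_mm2, 6, tolerance = 1e-12)
  expect_true(mm$watertight)
  # inverted winding keeps the absolute volume
  inv <- surface_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_equal(mesh_measures(inv)$volume_mm3, 1, tolerance = 1e-12)
  # two disjoint cubes add up
  two <- surface_mesh(rbind(cube$vertices, unit_cube_mesh(c(5, 0, 0))$vertices),
                      rbind(cube$faces, unit_cube_mesh()$faces + 8L))
  expect_equal(mesh_measures(two)$volume_mm3, 2, tolerance = 1e-12)
})

test_that("extract_surface recovers sphere volume and area within 5%", {
  sph <- voxel_sphere_mask(r = 10)
  mesh <- extract_surface(sph)
  mm <- mesh_measures(mesh)
  expect_true(mm$watertight)
  expect_lt(abs(mm$volume_mm3 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
  expect_lt(abs(mm$area_mm2 - 4 * pi * 100) / (4 * pi * 100), 0.05)
  # no degenerate faces
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  expect_true(all(rowSums(cr^2) > 0))
})

test_that("single-voxel mask gives a watertight mesh with volume in (0, 1]", {
  bits <- array(FALSE, c(5, 5, 5)); bits[3, 3, 3] <- TRUE
  m1 <- extract_surface(make_mask(bits), smooth_sigma = 0)
  mm <- mesh_measures(m1)
  expect_true(mm$watertight)
  expect_gt(mm$volume_mm3, 0)
  expect_lte(mm$volume_mm3, 1)
  # anisotropic spacing scales enclosed volume linearly per axis
  m2 <- extract_surface(make_mask(bits, spacing = c(1, 1, 2)),
                        smooth_sigma = 0)
  expect_equal(mesh_measures(m2)$volume_mm3, 2 * mm$volume_mm3,
               tolerance = 1e-9)
  expect_error(extract_surface(make_mask(array(FALSE, c(4, 4, 4)))),
               "empty-mesh")
})

test_that("objects touching the grid boundary still close", {
  bits <- array(FALSE, c(6, 6, 6)); bits[, , 1:6] <- FALSE
  bits[2:5, 2:5, 1:6] <- TRUE  # column spans the whole z range
  mesh <- extract_surface(make_mask(bits), smooth_sigma = 0)
  expect_true(is_watertight(mesh))
})

test_that("binary STL is byte-exact and round trips", {
  cube <- unit_cube_mesh()
  p <- file.path(tempdir(), "cube.stl")
  write_stl(cube, p)
  expect_identical(file.size(p), 80 + 4 + 12 * 50)
  back <- read_stl(p)
  expect_identical(nrow(back$faces), 12L)
  # coordinates survive at float32 precision; triangle soup order preserved
  orig_tris <- unname(cube$vertices[t(cube$faces), ])
  expect_equal(back$vertices, orig_tris, tolerance = 1e-6)
  mm <- mesh_measures(back)
  expect_equal(mm$volume_mm3, 1, tolerance = 1e-5)
  # empty mesh -> 0 triangles, minimal file
  empty <- surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  p0 <- file.path(tempdir(), "empty.stl")
  write_stl(empty, p0)
  expect_identical(file.size(p0), 84)
  expect_identical(nrow(read_stl(p0)$faces), 0L)
})

test_that("ascii STL dialect writes a parseable solid", {
  cube <- unit_cube_mesh()
  p <- file.path(tempdir(), "cube_ascii.stl")
  write_stl(cube, p, dialect = "ascii")
  txt <- readLines(p)
  expect_identical(sum(grepl("^  facet normal", txt)), 12L)
  expect_identical(txt[1], "solid cube")
})

test_that("mesh volume approaches mask volume as resolution doubles", {
  coarse <- voxel_sphere_mask(r = 6)
  fine <- voxel_sphere_mask(r = 12, spacing = c(0.5, 0.5, 0.5))
  true_vol <- 4 / 3 * pi * 6^3
  err_c <- abs(mesh_measures(extract_surface(coarse))$volume_mm3 - true_vol)
  err_f <- abs(mesh_measures(extract_surface(fine))$volume_mm3 - true_vol)
  expect_lt(err_f, err_c)
})
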