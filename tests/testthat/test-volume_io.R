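test_that("ct_volume validates geometry and shifted-domain range", {
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "spacing")
  expect_error(ct_volume(array(0, c(2, 2, 2)),
                         direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(ct_volume(array(300, c(2, 2, 2)),
                         intensity_domain = "shifted"), "\\[0, 255\\]")
  v <- make_volume(rep(100, 8), c(2, 2, 2))
  expect_s3_class(v, "ct_volume")
  expect_identical(v$intensity_domain, "hounsfield")
})

test_that("voxel_to_physical applies origin, spacing and direction", {
  v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(2, 3, 4),
                 origin = c(10, 20, 30))
  expect_equal(as.numeric(voxel_to_physical(v, c(0, 0, 0))), c(10, 20, 30))
  expect_equal(as.numeric(voxel_to_physical(v, c(1, 1, 1))), c(12, 23, 34))
  # axis-swapped direction
  dirm <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3)
  v2 <- ct_volume(array(0, c(4, 4, 4)), direction = dirm)
  expect_equal(as.numeric(voxel_to_physical(v2, c(1, 0, 0))), c(0, 1, 0))
})

test_that("MetaImage round trip preserves voxels and geometry", {
  set.seed(11)
  for (ext in c("mha", "mhd")) {
    v <- ct_volume(array(rnorm(60), c(3, 4, 5)), spacing = c(0.7, 0.8, 0.9),
                   origin = c(-1, 2, 3.5), phase = "delayed")
    p <- file.path(tempdir(), paste0("rt.", ext))
    write_metaimage(v, p)
    r <- read_metaimage(p, phase = "delayed")
    expect_identical(r$voxels, v$voxels)  # MET_DOUBLE: bitwise
    expect_equal(r$spacing, v$spacing, tolerance = 1e-12)
    expect_equal(r$origin, v$origin, tolerance = 1e-12)
    expect_equal(r$direction, v$direction)
    expect_identical(r$intensity_domain, "hounsfield")
  }
})

test_that("MetaImage reader rejects unsupported content", {
  p <- file.path(tempdir(), "bad2d.mha")
  writeLines(c("ObjectType = Image", "NDims = 2", "DimSize = 4 4",
               "ElementType = MET_UCHAR", "ElementDataFile = LOCAL"), p)
  expect_error(read_metaimage(p), "NDims")
  p2 <- file.path(tempdir(), "missingraw.mhd")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 2 2 2",
               "ElementType = MET_UCHAR",
               "ElementDataFile = nothere.raw"), p2)
  expect_error(read_metaimage(p2), "nothere.raw")
  expect_error(read_metaimage(file.path(tempdir(), "absent.mha")),
               "not found")
})

test_that("mask write/read round trips bits, geometry and label", {
  set.seed(7)
  m <- make_mask(runif(5 * 4 * 3) > 0.6, c(5, 4, 3), spacing = c(1, 2, 3),
                 label = "calculus")
  p <- file.path(tempdir(), "mask.mha")
  write_mask(m, p)
  r <- read_mask(p)
  expect_identical(r$bits, m$bits)
  expect_equal(r$geometry$spacing, m$geometry$spacing)
  expect_identical(r$label, "calculus")
  # empty and counted masks
  m0 <- make_mask(rep(FALSE, 27), c(3, 3, 3))
  write_mask(m0, p)
  expect_identical(mask_voxel_count(read_mask(p)), 0L)
  m100 <- make_mask(c(rep(TRUE, 100), rep(FALSE, 116)), c(6, 6, 6))
  write_mask(m100, p)
  expect_identical(mask_voxel_count(read_mask(p)), 100L)
})

test_that("DICOM series reads with geometric slice ordering and rescale", {
  dir <- file.path(tempdir(), "dcm_series")
  stored <- write_test_dicom_series(dir, n_slices = 4L)
  v <- read_dicom_series(dir)
  expect_equal(dim(v$voxels), dim(stored))
  # slope 1, intercept -1024 applied; slices in spatial order despite
  # shuffled files and reversed instance numbers
  expect_equal(unname(v$voxels), unname(stored - 1024), ignore_attr = TRUE)
  expect_equal(v$spacing, c(0.7, 0.7, 0.625), tolerance = 1e-9)
  expect_equal(v$origin, c(-10, 20, 0))
  expect_identical(v$intensity_domain, "hounsfield")
  # stored value 1024 must become exactly 0 HU
  idx <- which(stored == 1024)[1]
  if (!is.na(idx)) expect_identical(as.vector(v$voxels)[idx], 0)
})

test_that("DICOM reader rejects inconsistent series", {
  dir <- file.path(tempdir(), "dcm_badorient")
  write_test_dicom_series(dir, n_slices = 3L)
  write_test_dicom_slice(file.path(dir, "slice99.dcm"),
                         matrix(0L, 5, 6), position = c(-10, 20, 9),
                         series_uid = "1.2.826.0.1.999999.1",
                         orientation = c(0, 1, 0, 1, 0, 0))
  expect_error(read_dicom_series(dir), "orientation")

  dir2 <- file.path(tempdir(), "dcm_mixed")
  write_test_dicom_series(dir2, n_slices = 3L)
  write_test_dicom_slice(file.path(dir2, "slice99.dcm"),
                         matrix(0L, 5, 6), position = c(-10, 20, 9),
                         series_uid = "1.2.826.0.1.888888.2")
  expect_error(read_dicom_series(dir2), "mixed series")

  dir3 <- file.path(tempdir(), "dcm_gap")
  write_test_dicom_series(dir3, n_slices = 4L)
  # move one slice far off: non-uniform spacing
  write_test_dicom_slice(file.path(dir3, "slice01.dcm"),
                         matrix(0L, 5, 6), position = c(-10, 20, 7.5),
                         series_uid = "1.2.826.0.1.999999.1")
  expect_error(read_dicom_series(dir3), "non-uniform")
})

test_that("metrics report round trips and validates its config snapshot", {
  ca <- make_mask(c(rep(TRUE, 100), rep(FALSE, 900)), c(10, 10, 10),
                  label = "calculus")
  cs <- make_mask(rep(TRUE, 1000), c(10, 10, 10),
                  label = "collecting_system")
  m <- compute_metrics(list(calculus = ca, collecting_system = cs))
  expect_error(metrics_report(m, list(a = 1)), "config snapshot")
  rep_ <- metrics_report(m, segmentation_config(),
                         provenance = list(native = "phantom"))
  p <- file.path(tempdir(), "metrics.json")
  write_metrics(rep_, p)
  back <- read_metrics(p)
  expect_equal(back$metrics$SV_mm3, 100)
  expect_equal(back$metrics$PSV_mm3, 1000)
  expect_equal(back$metrics$ratio, 0.1, tolerance = 1e-12)
  expect_equal(back$config_used$calculus_lower, 250)
  expect_error(write_metrics(list(), p), "metrics_report")
})
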