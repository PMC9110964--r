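shifted_volume <- function(values, d = dim(values), spacing = c(1, 1, 1)) {
  make_volume(values, d, spacing, domain = "shifted")
}

test_that("compute_histogram counts conservatively over [0, 255]", {
  v <- shifted_volume(rep(100, 3 * 3 * 3), c(3, 3, 3))
  h <- compute_histogram(v)
  expect_length(h$counts, 256)
  expect_identical(sum(h$counts > 0), 1L)
  expect_identical(sum(h$counts), 27L)
  expect_true(all(diff(h$bin_edges) > 0))
  # two-value volume in equal halves -> two equal-count bins
  v2 <- shifted_volume(rep(c(50, 200), each = 32), c(4, 4, 4))
  h2 <- compute_histogram(v2)
  expect_identical(sort(h2$counts[h2$counts > 0]), c(32L, 32L))
  set.seed(3)
  v3 <- shifted_volume(runif(1000, 0, 255), c(10, 10, 10))
  expect_identical(sum(compute_histogram(v3, 37)$counts), 1000L)
  expect_error(compute_histogram(v3, 0), ">= 1")
  expect_error(compute_histogram(make_volume(rep(0, 8), c(2, 2, 2))),
               "shifted")
})

test_that("binarize uses inclusive bounds on the shifted scale", {
  v <- shifted_volume(c(116, 117, 180, 181, rep(0, 4)), c(2, 2, 2))
  m <- binarize(v, 117, 180)
  expect_identical(as.vector(m$bits)[1:4], c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(binarize(v, 0, 255)$bits))
  expect_identical(which(as.vector(binarize(v, 181, 181)$bits)), 4L)
  expect_error(binarize(v, 10, 5), "lower > upper")
})

test_that("binarize is monotone when the band widens", {
  set.seed(9)
  v <- shifted_volume(runif(343, 0, 255), c(7, 7, 7))
  inner <- binarize(v, 100, 150)$bits
  outer <- binarize(v, 80, 200)$bits
  expect_true(all(outer[inner]))
})

test_that("morphology matches the brute-force oracle on directed cases", {
  # isolated voxel is removed by particle removal with a cube of 3
  a <- array(FALSE, c(7, 7, 7)); a[4, 4, 4] <- TRUE
  expect_identical(sum(particle_removal(make_mask(a), 3)$bits), 0L)
  # a solid 5^3 block survives
  b <- array(FALSE, c(9, 9, 9)); b[3:7, 3:7, 3:7] <- TRUE
  expect_identical(particle_removal(make_mask(b), 3)$bits,
                   particle_removal_oracle(b, 3L))
  expect_true(all(particle_removal(make_mask(b), 3)$bits[3:7, 3:7, 3:7]))
  # unit element is the identity
  set.seed(21)
  r <- array(runif(125) > 0.5, c(5, 5, 5))
  expect_identical(particle_removal(make_mask(r), 1)$bits, r)
  expect_identical(dilate(make_mask(r), 1)$bits, r)
  # single voxel dilates to a 3^3 block
  s <- array(FALSE, c(5, 5, 5)); s[3, 3, 3] <- TRUE
  ds <- dilate(make_mask(s), 3)$bits
  expect_identical(sum(ds), 27L)
  expect_true(all(ds[2:4, 2:4, 2:4]))
  # empty stays empty; dilation is extensive
  expect_identical(sum(dilate(make_mask(array(FALSE, c(4, 4, 4))), 3)$bits), 0L)
})

test_that("morphology equals the oracle on random masks (property)", {
  set.seed(1001)
  for (i in 1:25) {
    d <- sample(4:10, 3, replace = TRUE)
    a <- array(runif(prod(d)) > runif(1, 0.3, 0.7), dim = d)
    m <- make_mask(a, d)
    for (cd in 1:3) {
      expect_identical(particle_removal(m, cd)$bits,
                       particle_removal_oracle(a, cd),
                       info = sprintf("particle dim %d iter %d", cd, i))
      expect_identical(dilate(m, cd)$bits, dilation_oracle_cube(a, cd),
                       info = sprintf("dilate dim %d iter %d", cd, i))
    }
    # opening is anti-extensive, closing extensive
    w <- cube_windows(3L)
    open3 <- dilate_oracle(erode_oracle(a, w$lo, w$hi), w$rlo, w$rhi)
    expect_true(all(a[open3]))
  }
})

test_that("mask set algebra obeys its identities", {
  set.seed(13)
  d <- c(6, 6, 6)
  a <- make_mask(runif(216) > 0.5, d)
  b <- make_mask(runif(216) > 0.5, d)
  empty <- make_mask(rep(FALSE, 216), d)
  expect_identical(intersect_masks(a, a)$bits, a$bits)
  expect_identical(sum(intersect_masks(a, empty)$bits), 0L)
  expect_identical(sum(subtract_masks(a, a)$bits), 0L)
  expect_identical(subtract_masks(a, empty)$bits, a$bits)
  expect_identical(sum(intersect_masks(subtract_masks(a, b), b)$bits), 0L)
  bad <- make_mask(rep(TRUE, 216), d, spacing = c(2, 1, 1))
  expect_error(intersect_masks(a, bad), "alignment")
  expect_error(subtract_masks(a, bad), "alignment")
})

test_that("segment_skeleton follows the six-step contract", {
  # all-bone grid: every voxel in both bands -> skeleton is the full grid
  # minus border erosion effects; compare against the oracle pipeline
  d <- c(8, 8, 8)
  nat <- shifted_volume(rep(150, prod(d)), d)
  del <- shifted_volume(rep(150, prod(d)), d)
  sk <- segment_skeleton(nat, del)
  full <- array(TRUE, d)
  step2 <- particle_removal_oracle(full, 3L)
  step3 <- dilation_oracle_cube(step2, 3L)
  step5 <- particle_removal_oracle(full, 3L)
  expect_identical(sk$skeleton$bits, step3 & step5)
  expect_identical(sk$skeleton$bits, sk$intermediates$step6$bits)
  # no voxel in the native bone band -> empty skeleton
  nat2 <- shifted_volume(rep(100, prod(d)), d)
  expect_identical(sum(segment_skeleton(nat2, del)$skeleton$bits), 0L)
  # collecting system is step5 minus step6 and disjoint from the skeleton
  cs <- segment_collecting_system(sk$intermediates$step5, sk$skeleton)
  expect_identical(sum(cs$bits & sk$skeleton$bits), 0L)
  expect_identical(sum(segment_collecting_system(sk$intermediates$step5,
                                                 sk$intermediates$step5)$bits),
                   0L)
})

test_that("segment_calculus extracts the saturated band and splits stones", {
  d <- c(16, 16, 8)
  vals <- array(100, d)
  vals[3:6, 3:6, 3:6] <- 252
  vals[11:14, 11:14, 3:6] <- 252
  m <- segment_calculus(shifted_volume(vals, d))
  expect_identical(count_components(m$bits), 2L)
  expect_identical(sum(m$bits), 2L * 64L)
  # nothing above 200 -> empty
  expect_identical(sum(segment_calculus(shifted_volume(array(200, d), d))$bits),
                   0L)
})

test_that("run_full_pipeline demands Hounsfield inputs and labels stages", {
  v <- shifted_volume(rep(100, 27), c(3, 3, 3))
  expect_error(run_full_pipeline(v, v), "Hounsfield")
  # aligned tiny volumes, registration skipped
  set.seed(2)
  nat <- make_volume(rnorm(1000, 40, 10), c(10, 10, 10))
  del <- make_volume(rnorm(1000, 40, 10), c(10, 10, 10), phase = "delayed")
  res <- run_full_pipeline(nat, del, register_settings = NULL)
  expect_s3_class(res, "segmentation_result")
  expect_named(res$intermediates,
               paste0("step", 1:6))
  expect_true(all(c("band_shift", "median_denoise", "segment_calculus") %in%
                    names(res$stage_log)))
  # grid mismatch without registration is a stage error
  del2 <- make_volume(rnorm(512, 40, 10), c(8, 8, 8), phase = "delayed")
  expect_error(run_full_pipeline(nat, del2, register_settings = NULL),
               "coregister")
})
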