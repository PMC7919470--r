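test_that("thresholding selects exactly the in-range voxels", {
  vol0 <- volume_image(array(0, c(8, 8, 8)))
  expect_equal(sum(threshold_mask(vol0, 300, 3000)$voxels), 0L)

  a <- array(-1000, c(20, 20, 20))
  a[6:15, 6:15, 6:15] <- 1000
  vol <- volume_image(a, spacing = c(0.9, 0.9, 1.2))
  mk <- threshold_mask(vol, 300)
  expect_equal(sum(mk$voxels), 1000L)               # exhaustive-scan count
  expect_equal(mk$spacing, vol$spacing)
  # re-thresholding the binary mask is idempotent
  mk2 <- threshold_mask(mk, 1, 1)
  expect_identical(mk2$voxels, mk$voxels)
  expect_error(threshold_mask(vol, 10, 5), "low > high")
})

test_that("island removal keeps the largest 26-connected components", {
  a <- array(0L, c(30, 30, 12))
  a[2:11, 2:11, 2:11] <- 1L                          # 1000-voxel block
  a[20:22, 20:22, 4:6] <- 1L                         # 27-voxel block
  mk <- label_mask(a)
  kept <- keep_largest_components(mk, 1)
  expect_equal(sum(kept$voxels), 1000L)
  expect_equal(sum(kept$voxels[20:22, 20:22, 4:6]), 0L)
  # n_keep >= number of components is the identity
  expect_identical(keep_largest_components(mk, 5)$voxels, mk$voxels)
  # single component: identity
  one <- label_mask(array(c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), c(2, 2, 2)))
  expect_identical(keep_largest_components(one, 1)$voxels, one$voxels)
  expect_warning(keep_largest_components(label_mask(array(0L, c(3, 3, 3)))),
                 "empty")
})

test_that("a disconnected flat slab (scanner bed) is removed from a bone mask", {
  a <- array(0L, c(40, 30, 20))
  a[5:20, 10:20, 8:14] <- 1L       # "bone", 1232 voxels
  a[, 1:2, 3] <- 1L                # thin flat slab, disjoint (80 voxels)
  cleaned <- keep_largest_components(label_mask(a), 1)
  expect_equal(sum(cleaned$voxels[, 1:2, ]), 0L)
  expect_equal(sum(cleaned$voxels), 16L * 11L * 7L)
})

test_that("hole filling closes cavities and matches a brute-force closing oracle", {
  a <- array(0L, c(16, 16, 10))
  a[4:13, 4:13, 3:8] <- 1L
  a[8:10, 8:10, 5] <- 0L                  # internal 3x3x1 cavity
  mk <- label_mask(a)
  filled <- fill_holes(mk, c(7, 7, 3))
  expect_equal(sum(filled$voxels[8:10, 8:10, 5]), 9L)
  expect_identical(filled$voxels, closing_oracle(a, c(7L, 7L, 3L)))
  # extensive and idempotent
  expect_true(all(filled$voxels >= a))
  expect_identical(fill_holes(filled, c(7, 7, 3))$voxels, filled$voxels)
  # solid block unchanged
  b <- array(0L, c(12, 12, 12)); b[3:10, 3:10, 3:10] <- 1L
  expect_identical(fill_holes(label_mask(b))$voxels, b)
  expect_error(fill_holes(mk, c(4, 7, 3)), "odd")
})

test_that("speckled masks have no interior cavities after closing", {
  set.seed(21)
  a <- array(0L, c(24, 24, 16))
  a[4:21, 4:21, 4:13] <- 1L
  holes <- cbind(sample(6:19, 30, TRUE), sample(6:19, 30, TRUE),
                 sample(6:11, 30, TRUE))
  a[holes] <- 0L
  filled <- fill_holes(label_mask(a), c(7, 7, 3))$voxels
  interior <- filled[5:20, 5:20, 5:12]
  expect_true(all(interior == 1L))
})

test_that("extracted surfaces are watertight with near-analytic volumes", {
  expect_error(extract_surface(label_mask(array(0L, c(4, 4, 4)))), "empty")
  # 10 mm cube at 1 mm spacing
  a <- array(0L, c(14, 14, 14)); a[3:12, 3:12, 3:12] <- 1L
  mc <- extract_surface(label_mask(a))
  expect_true(is_watertight(mc))
  expect_lt(abs(mesh_volume(mc) - 1000) / 1000, 0.15)
  # r = 10 mm sphere
  idx <- expand.grid(i = 0:24, j = 0:24, k = 0:24)
  inside <- (idx$i - 12)^2 + (idx$j - 12)^2 + (idx$k - 12)^2 <= 100
  ms <- extract_surface(label_mask(array(as.integer(inside), c(25, 25, 25))))
  expect_true(is_watertight(ms))
  expect_lt(abs(mesh_volume(ms) - 4189) / 4189, 0.10)
})

test_that("surface volume converges to the analytic volume as spacing shrinks", {
  vol_at <- function(h) {
    n <- ceiling(24 / h)
    ctr <- (n - 1) / 2
    idx <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
    inside <- ((idx$i - ctr)^2 + (idx$j - ctr)^2 + (idx$k - ctr)^2) * h^2 <= 100
    mesh_volume(extract_surface(
      label_mask(array(as.integer(inside), c(n, n, n)), spacing = rep(h, 3))))
  }
  true_v <- 4 / 3 * pi * 1000
  err <- abs(c(vol_at(2), vol_at(1)) - true_v) / true_v
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("NRRD and NIfTI volumes round-trip with geometry intact", {
  set.seed(22)
  vol <- volume_image(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                      spacing = c(0.78, 0.78, 0.8), origin = c(-10, 5, 2.5))
  for (ext in c(".nrrd", ".nii")) {
    f <- tempfile(fileext = ext)
    write_volume(vol, f)
    v2 <- read_volume(f)
    expect_equal(v2$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(v2$origin, vol$origin, tolerance = 1e-4)
    expect_equal(v2$voxels, vol$voxels, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("LPS-space NRRD volumes are converted to RAS on read", {
  f <- tempfile(fileext = ".nrrd")
  d <- c(3L, 2L, 2L)
  vals <- array(seq_len(prod(d)), d)
  con <- file(f, "wb")
  writeLines(c("NRRD0004", "type: float", "dimension: 3",
               "space: left-posterior-superior",
               paste("sizes:", paste(d, collapse = " ")),
               "space directions: (1,0,0) (0,1,0) (0,0,1)",
               "endian: little", "encoding: raw",
               "space origin: (10,20,5)", ""), con)
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  close(con)
  expect_warning(v <- read_volume(f), "LPS")
  # LPS +x becomes RAS -x: origin flips sign and the axis reverses
  expect_equal(v$origin, c(-10 - 2, -20 - 1, 5))
  expect_equal(v$voxels[, , 1], vals[rev(1:3), rev(1:2), 1],
               ignore_attr = TRUE)
})
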