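test_that("NIfTI round-trip preserves voxels, spacing and origin", {
  v <- new_volume(array(rnorm(8^3), rep(8, 3)),
                  spacing = c(1, 1, 2.5), origin = c(10, -5, 2))
  f <- tempfile(fileext = ".nii.gz")
  save_volume(v, f)
  v2 <- load_volume(f)
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-4)

  zero <- new_volume(array(0, rep(8, 3)))
  f2 <- tempfile(fileext = ".nii.gz")
  save_volume(zero, f2)
  expect_identical(as.numeric(load_volume(f2)$voxels),
                   as.numeric(zero$voxels))
})

test_that("non-3D input is rejected", {
  expect_error(new_volume(matrix(0, 4, 4)), "3D")
  expect_error(new_volume(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("intensity windowing maps the lung window onto [0,1]", {
  v <- new_volume(array(c(-1000, 600, -200, 2000, -3000,
                          rep(0, 8^3 - 5)), rep(8, 3)))
  n <- normalize_intensity(v, c(-1000, 600))
  expect_equal(n$voxels[1], 0)
  expect_equal(n$voxels[2], 1)
  expect_equal(n$voxels[3], 0.5)
  expect_equal(n$voxels[4], 1)  # clipped above
  expect_equal(n$voxels[5], 0)  # clipped below
  # idempotent on already-normalized volumes with window (0,1)
  expect_equal(normalize_intensity(n, c(0, 1))$voxels, n$voxels)
  expect_error(normalize_intensity(v, c(5, 5)), "degenerate")
})

test_that("voxel/normalized coordinate conversion is exact and invertible", {
  shape <- c(9L, 17L, 33L)
  expect_equal(as.numeric(voxel_to_norm(rbind(c(0, 0, 0)), shape)),
               c(-1, -1, -1))
  expect_equal(as.numeric(voxel_to_norm(rbind(shape - 1L), shape)),
               c(1, 1, 1))
  expect_equal(as.numeric(voxel_to_norm(rbind(c(4, 8, 16)), shape)),
               c(0, 0, 0))
  set.seed(1)
  idx <- cbind(sample(0:8, 20, TRUE), sample(0:16, 20, TRUE),
               sample(0:32, 20, TRUE))
  cn <- voxel_to_norm(idx, shape)
  expect_true(all(cn >= -1 & cn <= 1))
  expect_equal(norm_to_voxel(cn, shape), idx)
  expect_error(voxel_to_norm(rbind(c(9, 0, 0)), shape), "range")
})

test_that("patch features flatten the 5x5x5 neighborhood x-fastest", {
  # constant field
  v <- new_volume(array(0.37, rep(10, 3)))
  f <- extract_patch_features(v, rbind(c(5, 5, 5)))
  expect_equal(dim(f), c(1L, 125L))
  expect_true(all(f == 0.37))
  # linear ramp along x: rows reproduce the 5 ramp values per (y, z)
  ramp <- array(rep((0:9) / 10, 100), rep(10, 3))
  vr <- new_volume(ramp)
  fr <- extract_patch_features(vr, rbind(c(5, 5, 5)))
  expect_equal(as.numeric(fr), rep((3:7) / 10, times = 25))
  # corner voxel: compare against an explicitly padded-array oracle
  set.seed(2)
  a <- array(runif(6^3), rep(6, 3))
  va <- new_volume(a)
  fc <- extract_patch_features(va, rbind(c(0, 0, 0)))
  pad_idx <- function(i) pmin(pmax(i, 1L), 6L)
  oracle <- numeric(125)
  t <- 1
  for (dz in -2:2) for (dy in -2:2) for (dx in -2:2) {
    oracle[t] <- a[pad_idx(1 + dx), pad_idx(1 + dy), pad_idx(1 + dz)]
    t <- t + 1
  }
  expect_equal(as.numeric(fc), oracle)
  # shuffling input indices permutes feature rows identically
  idx <- rbind(c(1, 2, 3), c(4, 4, 4), c(0, 5, 2))
  f1 <- extract_patch_features(va, idx)
  p <- c(3, 1, 2)
  expect_equal(extract_patch_features(va, idx[p, ]), f1[p, ])
})
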