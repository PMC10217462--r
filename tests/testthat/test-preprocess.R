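test_that("NIfTI round trip preserves data and geometry", {
  v <- rand_volume(c(12, 10, 8), seed = 1)
  v@spacing <- c(2, 2, 2)
  path <- tempfile(fileext = ".nii.gz")
  writeVolume(v, path)
  v2 <- readVolume(path)
  expect_identical(v2@data, v@data)
  expect_lt(max(abs(v2@spacing - c(2, 2, 2))), 1e-6)
  file.remove(path)
})

test_that("readVolume rejects missing files and non-3D images", {
  expect_error(readVolume(tempfile()), "not found")
  path <- tempfile(fileext = ".nii.gz")
  arr4 <- array(runif(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  RNifti::writeNifti(RNifti::asNifti(arr4), path)
  expect_error(readVolume(path), "non-3D")
  file.remove(path)
})

test_that("resampling onto the source grid is the identity", {
  v <- rand_volume(c(10, 10, 10), seed = 2)
  r <- resampleToGrid(v, v)
  expect_equal(max(abs(r@data - v@data)), 0)
})

test_that("trilinear resampling matches the closed-form cell interpolation", {
  # 2x2x2 volume, upsample 2x: check an interior point against the direct
  # trilinear formula
  v <- RadVolume(array(c(0, 8, 0, 8, 0, 8, 0, 8), c(2, 2, 2)),
                 spacing = c(2, 2, 2))
  ref <- RadVolume(array(0, c(3, 3, 3)), spacing = c(1, 1, 1),
                   origin = c(0, 0, 0))
  out <- resampleToGrid(v, ref, "trilinear")
  # reference voxel (2,1,1) sits at physical x=1 -> halfway along axis 1
  expect_equal(out@data[2, 1, 1], (0 + 8) / 2)
  # oracle: direct interpolation at fractional source index
  frac <- 0.5
  expect_equal(out@data[2, 1, 1], (1 - frac) * 0 + frac * 8)
})

test_that("nearest-neighbour resampling keeps masks binary", {
  set.seed(3)
  m <- RadMask(array(rbinom(8^3, 1, 0.5) + 0, c(8, 8, 8)) |
                 array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
  ref <- RadVolume(array(0, c(16, 16, 16)), spacing = c(1, 1, 1))
  r <- resampleToGrid(m, ref)
  expect_true(all(r@data %in% c(0, 1)))
  expect_error(resampleToGrid(m, RadVolume(array(0, c(4, 4, 4)),
                                           origin = c(500, 0, 0))),
               "overlap")
})

test_that("min-max normalization maps the range onto [0,1]", {
  v <- rand_volume(c(8, 8, 8), seed = 4, lo = -1000, hi = 3000)
  n <- normalizeIntensity(v, preprocessConfig())
  expect_equal(min(n@data), 0)
  expect_equal(max(n@data), 1)
  # constant volume degenerates to all zeros
  cst <- RadVolume(array(7, c(4, 4, 4)))
  expect_true(all(normalizeIntensity(cst)@data == 0))
})

test_that("HU windowing clips before scaling", {
  v <- RadVolume(array(c(-500, 0, 1000, 300), c(4, 1, 1)))
  cfg <- preprocessConfig(normalize_mode = "hu_window",
                          hu_window = c(-200, 400))
  n <- normalizeIntensity(v, cfg)
  oracle <- (pmin(pmax(c(-500, 0, 1000, 300), -200), 400) + 200) / 600
  expect_equal(as.numeric(n@data), oracle)
  expect_error(preprocessConfig(normalize_mode = "hu_window",
                                hu_window = c(5, 5)))
})

test_that("enhancement is bounded, identity-able, and rejects raw input", {
  v <- rand_volume(c(24, 24, 4), seed = 5)
  cfgN <- preprocessConfig(enhance = "none")
  expect_identical(enhanceVolume(v, cfgN)@data, v@data)
  e <- enhanceVolume(v, preprocessConfig())
  expect_gte(min(e@data), 0)
  expect_lte(max(e@data), 1)
  # constant slices stay constant
  cst <- RadVolume(array(0.4, c(24, 24, 2)))
  expect_true(all(enhanceVolume(cst, preprocessConfig())@data == 0.4))
  raw <- RadVolume(array(c(-5, 10), c(2, 1, 1)))
  expect_error(enhanceVolume(raw, preprocessConfig()), "normalize")
})

test_that("adaptive equalization flattens a two-level histogram", {
  set.seed(6)
  sl <- matrix(0.25, 32, 32)
  sl[, seq(1, 32, 2)] <- 0.3  # low-contrast checkerboard stripes
  sl <- sl + matrix(runif(32 * 32, 0, 0.02), 32)
  v <- RadVolume(array(rep(sl, 2), c(32, 32, 2)))
  e <- enhanceVolume(v, preprocessConfig())
  ks_to_unif <- function(x) {
    x <- sort((x - min(x)) / (max(x) - min(x) + 1e-12))
    max(abs(x - seq_along(x) / length(x)))
  }
  expect_lt(ks_to_unif(as.numeric(e@data[, , 1])),
            ks_to_unif(as.numeric(v@data[, , 1])))
})

test_that("bounding-box crop has config-determined shape and padding", {
  v <- rand_volume(c(40, 40, 40), seed = 7)
  m <- array(0, c(40, 40, 40)); m[18:24, 18:24, 18:24] <- 1
  mask <- RadMask(m)
  cfg <- preprocessConfig(crop_size_mm = c(16, 16, 16),
                          target_spacing = c(1, 1, 1))
  cr <- cropBoundingBox(v, mask, cfg)
  expect_identical(dim(cr$volume@data), c(16L, 16L, 16L))
  # centroid at 21, box start round(21 - 7.5) = 14: sub-block oracle
  expect_equal(cr$volume@data, v@data[14:29, 14:29, 14:29])
  expect_equal(sum(cr$mask@data), sum(m))
  # crop larger than the volume pads with the minimum
  big <- preprocessConfig(crop_size_mm = c(60, 60, 60))
  crb <- cropBoundingBox(v, mask, big)
  expect_identical(dim(crb$volume@data), c(60L, 60L, 60L))
  expect_equal(crb$volume@data[1, 1, 1], min(v@data))
  # shape depends only on config and spacing, not on the tumor
  m2 <- array(0, c(40, 40, 40)); m2[5:6, 5:6, 5:6] <- 1
  expect_identical(dim(cropBoundingBox(v, RadMask(m2), cfg)$volume@data),
                   c(16L, 16L, 16L))
  expect_error(cropBoundingBox(v, mask, preprocessConfig(crop_size_mm = -1)))
})

test_that("default 1 x 1 x 1 mm grid yields the 224-voxel reference box", {
  v <- rand_volume(c(30, 30, 30), seed = 8)
  v@spacing <- c(1, 1, 1)
  m <- array(0, c(30, 30, 30)); m[14:16, 14:16, 14:16] <- 1
  cr <- cropBoundingBox(v, RadMask(m), preprocessConfig())
  expect_identical(dim(cr$volume@data), c(224L, 224L, 224L))
})

test_that("outcome labels are validated", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,label", "a,0", "b,1"), p)
  df <- readOutcomeLabels(p)
  expect_identical(df$label, c(0L, 1L))
  writeLines(c("patient_id,label", "a,0", "a,1"), p)
  expect_error(readOutcomeLabels(p), "duplicate")
  writeLines(c("patient_id,label", "a,2"), p)
  expect_error(readOutcomeLabels(p), "0/1")
  file.remove(p)
})
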