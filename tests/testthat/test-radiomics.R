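test_that("fixed-bin-number discretization follows the closed form", {
  v <- RadVolume(array(c(0, 0.5, 1), c(3, 1, 1)))
  m <- RadMask(array(1, c(3, 1, 1)))
  expect_identical(as.integer(discretizeFBN(v, m, 2)$levels), c(1L, 2L, 2L))
  cst <- RadVolume(array(4, c(2, 2, 2)))
  d <- discretizeFBN(cst, RadMask(array(1, c(2, 2, 2))), 8)
  expect_true(all(d$levels == 1L))
  set.seed(51)
  rv <- rand_volume(c(6, 6, 6), seed = 51)
  dd <- discretizeFBN(rv, RadMask(array(1, c(6, 6, 6))), 5)
  expect_true(all(dd$levels %in% 1:5))
  expect_error(discretizeFBN(rv, RadMask(array(1, c(6, 6, 6))), 1))
})

test_that("morphology matches analytic solids", {
  geo <- maskGeometry(ball_mask(8))$static
  expect_lt(abs(geo["morph_sphericity"] - 1), 0.05)
  expect_lt(abs(geo["morph_volume_mesh"] / (4 / 3 * pi * 512) - 1), 0.05)
  # voxel-count volume of a 10^3 cube at 1 mm spacing
  m <- array(0, c(14, 14, 14)); m[3:12, 3:12, 3:12] <- 1
  expect_equal(maskGeometry(RadMask(m))$static["morph_volume_voxel"],
               c(morph_volume_voxel = 1000))
  # 20 x 10 x 5 box: closed-form uniform-box inertia ratios
  b <- array(0, c(24, 16, 9)); b[2:21, 2:11, 2:6] <- 1
  s <- maskGeometry(RadMask(b))$static
  expect_lt(abs(s["morph_elongation"] - 0.5), 0.05 * 0.5)
  expect_lt(abs(s["morph_flatness"] - 0.25), 0.05 * 0.25)
  expect_lt(abs(s["morph_max_3d_diameter"] -
                  sqrt(19^2 + 9^2 + 4^2)) / sqrt(19^2 + 9^2 + 4^2), 0.1)
})

test_that("single-voxel masks flag mesh features undefined", {
  m <- array(0, c(5, 5, 5)); m[3, 3, 3] <- 1
  f <- morphologyFeatures(RadMask(m), rand_volume(c(5, 5, 5), 52))
  expect_true(is.na(f["morph_sphericity"]))
  expect_equal(f[["morph_volume_voxel"]], 1)
})

test_that("intensity statistics match hand computation", {
  v <- RadVolume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  m <- RadMask(array(1, c(4, 1, 1)))
  s <- intensityStats(v, m)
  expect_equal(s[["stat_mean"]], 2.5)
  expect_equal(s[["stat_variance"]], 1.25)  # population variance
  expect_equal(s[["stat_energy"]], 30)
  expect_equal(s[["stat_rms"]], sqrt(7.5))
  v2 <- RadVolume(array(c(1, 2), c(2, 1, 1)))
  expect_equal(intensityStats(v2, RadMask(array(1, c(2, 1, 1))))[["stat_energy"]], 5)
  cst <- intensityStats(RadVolume(array(3, c(3, 1, 1))),
                        RadMask(array(1, c(3, 1, 1))))
  expect_equal(cst[["stat_mean"]], 3)
  expect_equal(cst[["stat_variance"]], 0)
  expect_true(is.na(cst[["stat_skewness"]]))
})

test_that("histogram features: entropy and uniformity closed forms", {
  lev <- array(rep(1:4, each = 4), c(16, 1, 1))
  d <- structure(list(levels = lev, ng = 4L, scheme = "fixed_bin_number",
                      spacing = c(1, 1, 1)), class = "DiscretizedVolume")
  h <- histogramFeatures(d)
  expect_equal(h[["ih_entropy"]], 2)
  expect_equal(h[["ih_uniformity"]], 0.25)
  one <- structure(list(levels = array(1L, c(4, 1, 1)), ng = 4L,
                        scheme = "fixed_bin_number", spacing = c(1, 1, 1)),
                   class = "DiscretizedVolume")
  h1 <- histogramFeatures(one)
  expect_equal(h1[["ih_entropy"]], 0)
  expect_equal(h1[["ih_uniformity"]], 1)
  # entropy is maximal exactly when levels are equifrequent
  set.seed(53)
  skewed <- structure(list(levels = array(c(rep(1L, 10), rep(2:4, 2)),
                                          c(16, 1, 1)), ng = 4L,
                           scheme = "fixed_bin_number",
                           spacing = c(1, 1, 1)),
                      class = "DiscretizedVolume")
  expect_lt(histogramFeatures(skewed)[["ih_entropy"]], 2)
})

test_that("IVH of a two-value region matches direct counting", {
  vals <- c(rep(0.2, 6), rep(0.8, 2))
  v <- RadVolume(array(vals, c(8, 1, 1)))
  m <- RadMask(array(1, c(8, 1, 1)))
  iv <- ivhFeatures(v, m)
  # at the midpoint threshold only the high voxels remain: 2/8
  expect_equal(iv[["ivh_v10"]], 2 / 8)  # threshold 0.26 -> high fraction
  expect_equal(iv[["ivh_v90"]], 2 / 8)
  expect_equal(iv[["ivh_i10"]], 0.8)
})

test_that("GLCM of a 1D strip matches hand enumeration", {
  v <- RadVolume(array(c(0, 1, 0, 1), c(4, 1, 1)))
  m <- RadMask(array(1, c(4, 1, 1)))
  d <- discretizeFBN(v, m, 2)
  M <- glcm3d(d, matrix(c(1L, 0L, 0L), 1))[, , 1]
  expect_equal(M, matrix(c(0, 3, 3, 0), 2))
  # constant region: single diagonal entry, zero contrast, NA correlation
  dc <- discretizeFBN(RadVolume(array(5, c(3, 3, 3))),
                      RadMask(array(1, c(3, 3, 3))), 4)
  f <- textureFeatures("GLCM", dc, "merged")
  expect_equal(f[["glcm_merged_contrast"]], 0)
  expect_true(is.na(f[["glcm_merged_correlation"]]))
})

test_that("texture matrices equal brute-force enumeration on random volumes", {
  offs <- tensorRad:::.offsets13()
  for (seed in 1:10) {
    d <- rand_disc(seed, dim = c(4, 4, 5), ng = 3)
    lev <- d$levels
    G <- glcm3d(d)
    R <- glrlm3d(d)
    for (o in seq_len(nrow(offs))) {
      expect_equal(G[, , o], bf_glcm(lev, 3, offs[o, ]), label = "GLCM")
      expect_equal(R[, , o], bf_glrlm(lev, 3, offs[o, ], dim(R)[2]),
                   label = "GLRLM")
    }
    z <- greyLevelZones(d)
    bz <- bf_zones(lev)
    expect_equal(sort(paste(z[, 1], z[, 2])), sort(paste(bz[, 1], bz[, 2])))
    expect_equal(tensorRad:::cpp_ngtdm(as.integer(lev), dim(lev), 3L),
                 bf_ngtdm(lev, 3))
    expect_equal(tensorRad:::cpp_ngldm(as.integer(lev), dim(lev), 3L, 0L),
                 bf_ngldm(lev, 3))
  }
})

test_that("Chebyshev distance map matches the exhaustive oracle", {
  for (seed in 1:5) {
    set.seed(seed + 60)
    m <- array(rbinom(5^3, 1, 0.7), c(5, 5, 5))
    if (sum(m) == 0) m[3, 3, 3] <- 1
    dmap <- tensorRad:::cpp_cheb_dist(as.integer(m), dim(m))
    oracle <- bf_cheb_dist(m)
    got <- array(dmap, dim(m))[oracle$idx]
    expect_equal(got, oracle$dist)
  }
})

test_that("GLSZM of isolated single-voxel zones is concentrated in column 1", {
  lev <- array(0L, c(5, 5, 5))
  lev[1, 1, 1] <- 1L; lev[5, 5, 5] <- 2L; lev[1, 5, 1] <- 3L
  d <- structure(list(levels = lev, ng = 3L, scheme = "fixed_bin_number",
                      spacing = c(1, 1, 1)), class = "DiscretizedVolume")
  f <- textureFeatures("GLSZM", d)
  expect_equal(f[["glszm_sze"]], 1)
  expect_equal(f[["glszm_zone_pct"]], 1)
})

test_that("NGTDM coarseness of a constant region is undefined", {
  dc <- discretizeFBN(RadVolume(array(2, c(4, 4, 4))),
                      RadMask(array(1, c(4, 4, 4))), 8)
  f <- textureFeatures("NGTDM", dc)
  expect_true(is.na(f[["ngtdm_coarseness"]]))
})

test_that("the full feature vector is 215-long, ordered and deterministic", {
  pp <- tiny_pair()
  f1 <- extractFeatures(pp$ct, pp$mask)
  f2 <- extractFeatures(pp$ct, pp$mask)
  expect_length(f1, 215L)
  expect_identical(names(f1), featureNames())
  expect_identical(f1, f2)
  # block sizes: 79 first-order, 136 texture
  fo <- grep("^(morph|loc|stat|ih|ivh)_", names(f1))
  expect_length(fo, 79L)
  expect_length(setdiff(seq_along(f1), fo), 136L)
  expect_length(grep("^glcm_", names(f1)), 50L)
  expect_length(grep("^glrlm_", names(f1)), 32L)
  expect_length(grep("^ngldm_", names(f1)), 17L)
})

test_that("features ignore intensities outside the mask", {
  pp <- tiny_pair()
  f1 <- extractFeatures(pp$ct, pp$mask)
  v2 <- pp$ct
  v2@data[pp$mask@data == 0] <- pmin(v2@data[pp$mask@data == 0] + 0.3, 1)
  f2 <- extractFeatures(v2, pp$mask)
  keep <- setdiff(names(f1), c("loc_peak_local", "loc_peak_global"))
  expect_equal(f1[keep], f2[keep])
})

test_that("axis-aligned 90-degree rotation leaves aggregated features alone", {
  pp <- tiny_pair()
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3))
  v2 <- RadVolume(rot(pp$ct@data), pp$ct@spacing)
  m2 <- RadMask(rot(pp$mask@data), pp$mask@spacing)
  d1 <- discretizeFBN(pp$ct, pp$mask, 16)
  d2 <- discretizeFBN(v2, m2, 16)
  for (kind in c("GLCM", "GLRLM"))
    for (agg in c("averaged", "merged"))
      expect_equal(textureFeatures(kind, d1, agg),
                   textureFeatures(kind, d2, agg), tolerance = 1e-9)
})
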