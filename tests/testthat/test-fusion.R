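test_that("the registry yields 15 fused flavours plus CT and PET", {
  expect_length(fusionRegistry(), 15L)
  pp <- tiny_pair()
  fs <- buildFlavourSet(pp$ct, pp$pet, seed = 1)
  expect_length(flavourNames(fs), 17L)
  expect_identical(flavourNames(fs)[1:2], c("CT", "PET"))
  d <- dim(pp$ct@data)
  for (nm in flavourNames(fs)) {
    v <- getFlavour(fs, nm)
    expect_identical(dim(v@data), d)
    expect_true(all(is.finite(v@data)))
    expect_gte(min(v@data), 0)
    expect_lte(max(v@data), 1)
  }
  expect_error(getFlavour(fs, "nope"), "unknown")
  expect_error(fusionRegistry("XXX"), "unknown")
})

test_that("a restricted registry gives 2 + length(registry) flavours", {
  pp <- tiny_pair()
  fs <- buildFlavourSet(pp$ct, pp$pet, fusionRegistry("WEIGHTED"))
  expect_length(flavourNames(fs), 3L)
})

test_that("flavour building is deterministic under a fixed seed", {
  pp <- tiny_pair()
  reg <- fusionRegistry(c("SR", "DWT", "PCA"))
  f1 <- buildFlavourSet(pp$ct, pp$pet, reg, seed = 7)
  f2 <- buildFlavourSet(pp$ct, pp$pet, reg, seed = 7)
  for (nm in flavourNames(f1))
    expect_identical(getFlavour(f1, nm)@data, getFlavour(f2, nm)@data)
})

test_that("every fusion method is idempotent on identical inputs", {
  pp <- tiny_pair()
  ct <- pp$ct
  dict <- tensorRad:::.train_pair_dictionary(ct, ct, seed = 2)
  for (m in fusionRegistry()) {
    fused <- fusePair(ct, ct, m, dict = dict)
    tol <- if (m$name == "WEIGHTED") 1e-9 else 1e-3
    expect_lt(max(abs(fused@data - ct@data)), tol)
  }
})

test_that("symmetric-rule methods are order-symmetric", {
  pp <- tiny_pair()
  for (nm in c("LP", "DWT", "WAVELET", "CVT", "NSCT", "WEIGHTED")) {
    ab <- fusePair(pp$ct, pp$pet, nm)
    ba <- fusePair(pp$pet, pp$ct, nm)
    expect_lt(max(abs(ab@data - ba@data)), 1e-9)
  }
})

test_that("weighted fusion endpoints and PCA weights behave analytically", {
  pp <- tiny_pair()
  w1 <- fuseSimple(pp$ct, pp$pet, "WEIGHTED", w = 1)
  expect_equal(w1@data, pp$ct@data)
  # PCA of identical columns gives equal weights
  x <- rnorm(500)
  expect_equal(pcaFusionWeights(x, x), c(0.5, 0.5))
  # known covariance oracle: weights proportional to leading eigenvector
  set.seed(31)
  a <- rnorm(2000); b <- 0.5 * a + rnorm(2000, sd = 0.1)
  e <- eigen(cov(cbind(a, b)), symmetric = TRUE)$vectors[, 1]
  expect_lt(max(abs(pcaFusionWeights(a, b) - e / sum(e))), 1e-8)
})

test_that("DWT fusion with a zero image matches the coefficient oracle", {
  pp <- tiny_pair()
  zero <- RadVolume(array(0, dim(pp$ct@data)), pp$ct@spacing,
                    pp$ct@origin)
  f <- fusePair(pp$ct, zero, "DWT")
  # oracle: per slice, low-pass halved, details kept (max-abs vs 0)
  z <- 3L
  p <- decomposeSlice(pp$ct@data[, , z], "DWT")
  p$dec$low <- p$dec$low / 2
  oracle <- pmin(pmax(reconstructSlice(p), 0), 1)
  expect_lt(max(abs(f@data[, , z] - oracle)), 1e-9)
})

test_that("HSI keeps intensity where modalities agree", {
  pp <- tiny_pair()
  f <- fuseSimple(pp$ct, pp$ct, "HSI")
  expect_lt(max(abs(f@data - pp$ct@data)), 1e-9)
})

test_that("fusion rejects unnormalized or mismatched inputs", {
  pp <- tiny_pair()
  raw <- RadVolume(pp$ct@data * 2000 - 1000, pp$ct@spacing)
  expect_error(fusePair(raw, pp$pet, "DWT"), "normalized")
  small <- RadVolume(array(0.5, c(8, 8, 8)), pp$ct@spacing)
  expect_error(fusePair(small, pp$pet, "DWT"), "grids")
})
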