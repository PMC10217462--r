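test_that("K-SVD recovers a planted two-atom dictionary", {
  set.seed(41)
  a1 <- sin(seq(0, 4 * pi, length.out = 64)); a1 <- a1 / sqrt(sum(a1^2))
  a2 <- rep(c(1, -1), 32); a2 <- a2 / sqrt(sum(a2^2))
  # sparse generative codes: each patch uses exactly one atom
  pick <- sample(1:2, 400, replace = TRUE)
  codes <- matrix(0, 2, 400)
  codes[cbind(pick, 1:400)] <- runif(400, 0.5, 2) * sample(c(-1, 1), 400,
                                                           replace = TRUE)
  X <- cbind(a1, a2) %*% codes + matrix(rnorm(64 * 400, sd = 1e-3), 64)
  d <- learnDictionary(X, n_atoms = 2, sparsity = 1, seed = 1, iters = 10)
  expect_equal(colSums(d$atoms^2), c(1, 1), tolerance = 1e-9)
  cosim <- abs(crossprod(d$atoms, cbind(a1, a2)))
  # each generator matched by some atom up to sign/permutation
  expect_gt(max(cosim[, 1]), 0.99)
  expect_gt(max(cosim[, 2]), 0.99)
})

test_that("dictionary training error trace is non-increasing", {
  set.seed(42)
  X <- matrix(rnorm(64 * 300), 64)
  d <- learnDictionary(X, n_atoms = 16, sparsity = 3, seed = 2, iters = 6)
  expect_true(all(diff(d$err_trace) <= 1e-12))
})

test_that("degenerate one-atom data is reconstructed exactly", {
  atom <- rnorm(64); atom <- atom / sqrt(sum(atom^2))
  X <- atom %o% runif(50, 1, 2)
  d <- learnDictionary(X, n_atoms = 4, sparsity = 1, seed = 3, iters = 3)
  C <- tensorRad:::cpp_omp(d$atoms, X - matrix(colMeans(X), 64, 50,
                                               byrow = TRUE), 1, 1e-9)
  R <- (X - matrix(colMeans(X), 64, 50, byrow = TRUE)) - d$atoms %*% C
  expect_lt(max(abs(R)), 1e-8)
})

test_that("dictionary learning is deterministic and validates input", {
  set.seed(43)
  X <- matrix(rnorm(64 * 100), 64)
  d1 <- learnDictionary(X, n_atoms = 8, seed = 5)
  d2 <- learnDictionary(X, n_atoms = 8, seed = 5)
  expect_identical(d1$atoms, d2$atoms)
  expect_error(learnDictionary(X[, 1:4], n_atoms = 8), "too few")
})

test_that("OMP solves to the requested residual tolerance", {
  set.seed(44)
  D <- qr.Q(qr(matrix(rnorm(64 * 64), 64)))  # orthonormal basis
  x <- rnorm(64)
  C <- tensorRad:::cpp_omp(D, matrix(x), 64L, 1e-6)
  expect_lt(sqrt(sum((x - D %*% C)^2)), 1e-6)
})

test_that("SR fusion keeps the stronger-activity patch and the zero-code
           contract", {
  set.seed(45)
  base <- matrix(runif(32 * 32, 0.2, 0.4), 32)
  dict <- learnDictionary(cbind(tensorRad:::.extract_patches(base, 8, 4)$patches,
                                matrix(rnorm(64 * 80, sd = 0.3), 64)),
                          n_atoms = 32, seed = 6)
  # identical inputs: fused equals the input
  f <- fuseSR(base, base, dict)
  expect_lt(max(abs(f - base)), 1e-9)
  # zero PET: zero codes are never selected, CT content survives exactly
  f0 <- fuseSR(base, matrix(0, 32, 32), dict)
  expect_lt(max(abs(f0 - base)), 1e-9)
})

test_that("disjoint bright blobs both survive SR fusion", {
  set.seed(46)
  a <- matrix(0.1, 32, 32); a[6:10, 6:10] <- 0.9
  b <- matrix(0.1, 32, 32); b[22:26, 22:26] <- 0.85
  dict <- learnDictionary(cbind(tensorRad:::.extract_patches(a, 8, 4)$patches,
                                tensorRad:::.extract_patches(b, 8, 4)$patches),
                          n_atoms = 32, seed = 7)
  f <- fuseSR(a, b, dict)
  expect_gt(max(f[6:10, 6:10]), 0.8 * 0.9)
  expect_gt(max(f[22:26, 22:26]), 0.8 * 0.85)
})

test_that("hybrid fusion: exact detail passthrough, SR low-pass", {
  pp <- tiny_pair()
  dict <- tensorRad:::.train_pair_dictionary(pp$ct, pp$pet, seed = 8)
  f <- fuseHybrid(pp$ct, pp$pet, "CVT", dict)
  expect_identical(dim(f@data), dim(pp$ct@data))
  # band-level oracle on one slice: details of the hybrid equal max-abs
  # selection, which reconstruct-with-zero-lowpass can isolate
  z <- 4L
  pa <- decomposeSlice(pp$ct@data[, , z], "CVT")
  pb <- decomposeSlice(pp$pet@data[, , z], "CVT")
  fused <- fuseCoefficients(pa, pb)
  for (j in seq_along(fused$dec$details))
    for (k in seq_along(fused$dec$details[[j]])) {
      da <- pa$dec$details[[j]][[k]]; db <- pb$dec$details[[j]][[k]]
      expect_equal(fused$dec$details[[j]][[k]],
                   ifelse(abs(db) > abs(da), db, da))
    }
  # identical inputs: hybrid is idempotent within the SR tolerance
  fid <- fuseHybrid(pp$ct, pp$ct, "CVT", dict)
  expect_lt(max(abs(fid@data - pp$ct@data)), 1e-3)
  # constant pair stays constant
  cst <- RadVolume(array(0.6, dim(pp$ct@data)), pp$ct@spacing)
  dc <- tensorRad:::.train_pair_dictionary(cst, cst, seed = 9)
  fc <- fuseHybrid(cst, cst, "NSCT", dc)
  expect_lt(max(abs(fc@data - 0.6)), 1e-3)
})
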