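test_that("autoencoder shape contract holds for /8-divisible grids", {
  for (g in list(c(16L, 16L, 16L), c(32L, 16L, 24L))) {
    sp <- autoencoderSpec(g, channels = c(4L, 4L), bottleneck_channels = 2L)
    expect_identical(sp$bottleneck_len, as.integer(prod(g / 8L) * 2L))
    m <- buildAutoencoder(sp, seed = 1)
    x <- array(runif(prod(g)), g)
    fw <- tensorRad:::.ae_forward(m, x)
    expect_identical(dim(fw$yhat)[1:3], g)
    expect_length(extractBottleneck(m, x), sp$bottleneck_len)
  }
  expect_error(autoencoderSpec(c(20, 16, 16)), "divisible")
  sp <- autoencoderSpec(c(32L, 32L, 32L), channels = c(4L, 4L),
                        bottleneck_channels = 4L)
  expect_identical(sp$bottleneck_len, 256L)
})

test_that("the reference configuration flattens to 15,680 bottleneck units", {
  sp <- autoencoderSpec(c(224L, 224L, 160L), bottleneck_channels = 1L)
  expect_identical(sp$bottleneck_len, 15680L)
  expect_identical(as.integer(prod(c(28, 28, 20))), 15680L)
})

test_that("weight init and extraction are deterministic", {
  sp <- autoencoderSpec(c(16L, 16L, 16L), channels = c(4L, 4L))
  m1 <- buildAutoencoder(sp, seed = 9)
  m2 <- buildAutoencoder(sp, seed = 9)
  expect_identical(m1$W, m2$W)
  x <- array(runif(16^3), c(16, 16, 16))
  expect_identical(extractBottleneck(m1, x), extractBottleneck(m1, x))
})

test_that("zero input through a zero-bias encoder gives a zero bottleneck", {
  sp <- autoencoderSpec(c(16L, 16L, 16L), channels = c(4L, 4L))
  m <- buildAutoencoder(sp, seed = 2)  # biases init to zero
  b <- extractBottleneck(m, array(0, c(16, 16, 16)))
  expect_true(all(b == 0))
})

test_that("conv/pool/upsample gradients match finite differences", {
  set.seed(71)
  g <- c(6L, 6L, 6L)
  x <- array(runif(prod(g) * 2), c(g, 2L))
  w <- array(rnorm(3 * 3 * 3 * 2 * 3, sd = 0.3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  y <- tensorRad:::cpp_conv3_fwd(x, g, w, 2L, 3L, b)
  gy <- array(rnorm(length(y)), dim(y))
  gr <- tensorRad:::cpp_conv3_bwd(x, g, w, 2L, 3L, gy)
  loss <- function(wv) sum(tensorRad:::cpp_conv3_fwd(x, g, wv, 2L, 3L, b) * gy)
  for (k in sample(length(w), 5)) {
    w2 <- w; w2[k] <- w2[k] + 1e-6
    expect_equal((loss(w2) - loss(w)) / 1e-6, as.numeric(gr$gw)[k],
                 tolerance = 1e-3)
  }
  lx <- function(xv) sum(tensorRad:::cpp_conv3_fwd(xv, g, w, 2L, 3L, b) * gy)
  for (k in sample(length(x), 5)) {
    x2 <- x; x2[k] <- x2[k] + 1e-6
    expect_equal((lx(x2) - lx(x)) / 1e-6, as.numeric(gr$gx)[k],
                 tolerance = 1e-3)
  }
})

test_that("training reduces the reconstruction loss", {
  set.seed(72)
  co <- .fixture_env$cohort2
  if (is.null(co)) { tiny_pair(); co <- .fixture_env$cohort2 }
  vols <- lapply(1:8, function(i) {
    pp <- processPhantom(co[[1 + (i %% 2)]])
    (pp$ct@data + array(runif(32^3, 0, 0.02), c(32, 32, 32))) /
      1.02  # small jitter keeps copies distinct, values in [0,1]
  })
  sp <- autoencoderSpec(c(32L, 32L, 32L), channels = c(4L, 4L),
                        bottleneck_channels = 2L)
  m <- buildAutoencoder(sp, seed = 3)
  tr <- trainAutoencoder(m, vols, trainingConfig(epochs = 6, batch = 4,
                                                 seed = 4))
  expect_lt(tr$loss_trace[6], tr$loss_trace[1])
  # determinism of the loss trace
  tr2 <- trainAutoencoder(m, vols, trainingConfig(epochs = 6, batch = 4,
                                                  seed = 4))
  expect_identical(tr$loss_trace, tr2$loss_trace)
  # overfit-one sanity: training on copies of one volume beats the
  # untrained model by a wide margin
  one <- vols[1]
  sp2 <- autoencoderSpec(c(32L, 32L, 32L), channels = c(8L, 8L),
                         bottleneck_channels = 4L)
  m0 <- buildAutoencoder(sp2, seed = 5)
  mse0 <- mean((reconstructVolume(m0, one[[1]]) - one[[1]])^2)
  mtr <- trainAutoencoder(m0, rep(one, 4),
                          trainingConfig(epochs = 40, batch = 2, seed = 6,
                                         lr = 5e-3))
  mse1 <- mean((reconstructVolume(mtr, one[[1]]) - one[[1]])^2)
  expect_lt(mse1, 0.1 * mse0)
})

test_that("training rejects values outside [0,1] and mismatched grids", {
  sp <- autoencoderSpec(c(16L, 16L, 16L), channels = c(4L, 4L))
  m <- buildAutoencoder(sp, seed = 1)
  bad <- array(2, c(16, 16, 16))
  expect_error(trainAutoencoder(m, list(bad)), "\\[0,1\\]")
  wrong <- array(0.5, c(8, 8, 8))
  expect_error(trainAutoencoder(m, list(wrong)), "grid")
  expect_error(extractBottleneck(m, wrong), "grid")
})

test_that("deep features of two texture classes are linearly separable", {
  set.seed(73)
  n <- 20
  vols <- vector("list", n)
  lab <- rep(0:1, each = n / 2)
  for (i in seq_len(n)) {
    ell <- if (lab[i] == 1) 4 else 1
    f <- gaussianRandomField(c(16, 16, 16), ell, seed = 100 + i)
    vols[[i]] <- (f - min(f)) / (max(f) - min(f))
  }
  sp <- autoencoderSpec(c(16L, 16L, 16L), channels = c(4L, 4L),
                        bottleneck_channels = 4L)
  m <- buildAutoencoder(sp, seed = 7)
  m <- trainAutoencoder(m, vols[seq(1, n, 2)],
                        trainingConfig(epochs = 5, batch = 4, seed = 8))
  X <- t(vapply(vols, function(v) extractBottleneck(m, v),
                numeric(sp$bottleneck_len)))
  # logistic probe on principal components: train on half, test on half
  tr <- seq(1, n, 2); te <- seq(2, n, 2)
  pc <- prcomp(X[tr, ], center = TRUE)
  k <- min(3, sum(pc$sdev > 1e-8))
  Ztr <- pc$x[, 1:k, drop = FALSE]
  Zte <- scale(X[te, ], center = pc$center, scale = FALSE) %*%
    pc$rotation[, 1:k, drop = FALSE]
  fit <- suppressWarnings(glm.fit(cbind(1, Ztr), lab[tr],
                                  family = binomial()))
  cf <- fit$coefficients; cf[is.na(cf)] <- 0
  p <- 1 / (1 + exp(-cbind(1, Zte) %*% cf))
  expect_gt(mean((p > 0.5) == lab[te]), 0.6)
})
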