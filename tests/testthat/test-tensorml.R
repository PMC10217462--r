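# small synthetic feature tensors for the ML stage
make_toy_tensor <- function(n = 60, nf = 10, nflav = 3, seed = 81,
                            signal = 1.5) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  tables <- lapply(seq_len(nflav), function(fl) {
    M <- matrix(rnorm(nf * n), nf, n)
    M[1, ] <- M[1, ] + signal * y  # informative base feature
    rownames(M) <- sprintf("f%02d", seq_len(nf))
    colnames(M) <- sprintf("P%03d", seq_len(n))
    M
  })
  names(tables) <- paste0("FL", seq_len(nflav))
  assembleTensor(tables, y)
}

test_that("tensor assembly enforces the patient x feature x flavour contract", {
  ft <- make_toy_tensor(n = 10, nf = 215, nflav = 17)
  expect_s4_class(ft, "FlavourTensor")
  expect_identical(dim(ft), c(215L, 10L))
  expect_length(flavourNames(ft), 17L)
  fl <- tensorRad:::.flatten_tensor(ft)
  expect_identical(dim(fl$X), c(10L, 215L * 17L))
  # missing flavour for one patient -> hard error naming both
  tb <- lapply(1:2, function(i) matrix(1, 3, 4))
  names(tb) <- c("A", "B")
  tb$B[, 2] <- NA
  expect_error(assembleTensor(tb, rep(0:1, 2)), "flavour B.*patient")
})

test_that("imputation uses training-fold medians only", {
  X <- matrix(c(1, 2, 3, 100, NA, 2, 4, 6, 8, 10), ncol = 2)
  imp <- fitImputer(X, rows = 1:3)
  Xi <- applyImputer(imp, X)
  expect_equal(Xi[5, 1], 2)  # median of rows 1:3, not influenced by 100
  expect_identical(imp$fitRows, 1:3)
})

test_that("variance filter drops exactly the low-variance columns", {
  set.seed(82)
  X <- cbind(rep(5, 20), rnorm(20, sd = sqrt(0.5)), rnorm(20, sd = sqrt(2)))
  vf <- varianceFilter(X, threshold = 0.1)
  expect_identical(vf$keep, 2:3)
  expect_identical(varianceFilter(X, threshold = 0)$keep, 2:3)
  vf2 <- varianceFilter(X[, 2:3], threshold = 1e-12)
  expect_identical(vf2$keep, 1:2)  # below-min threshold keeps everything
  expect_error(varianceFilter(matrix(1, 5, 2), 0.1), "all columns")
})

test_that("correlation filter keeps one of a duplicated column", {
  set.seed(83)
  n <- 40
  y <- rep(0:1, n / 2)
  x1 <- rnorm(n) + y
  X <- cbind(x1, x1, rnorm(n), rnorm(n))
  cf <- correlationFilter(X, y, threshold = 0.95)
  expect_length(intersect(cf$keep, 1:2), 1L)
  # orthogonal columns all survive
  Xo <- qr.Q(qr(matrix(rnorm(n * 4), n)))
  expect_length(correlationFilter(Xo, y, 0.95)$keep, 4L)
  # greedy replay oracle on a constructed 4-column matrix
  base <- rnorm(n)
  Xc <- cbind(a = base + 0.01 * rnorm(n), b = base + 0.01 * rnorm(n),
              c = rnorm(n), d = rnorm(n))
  f <- anovaF(Xc, y)
  ordc <- order(-f, seq_len(4))
  keep <- integer(0)
  for (j in ordc) {
    if (!length(keep) ||
        all(abs(cor(Xc[, j], Xc[, keep, drop = FALSE])) < 0.95))
      keep <- c(keep, j)
  }
  expect_setequal(correlationFilter(Xc, y, 0.95)$keep, keep)
})

test_that("ANOVA F matches the closed form and selection is order-stable", {
  X <- cbind(c(1, 2, 3, 4, 5, 6), c(7, 7, 7, 7, 7, 7), rnorm(6))
  y <- c(0, 0, 0, 1, 1, 1)
  f <- anovaF(X, y)
  expect_equal(f[1], 13.5)
  expect_equal(f[2], 0)
  sel <- anovaSelect(X, y, k = 1)
  expect_identical(sel$keep, 1L)
  expect_error(anovaF(X, rep(0, 6)), "class")
  # stats::aov cross-check on a random column
  set.seed(84)
  x <- rnorm(20); yy <- rep(0:1, 10)
  f2 <- anovaF(matrix(x), yy)
  ref <- summary(stats::aov(x ~ factor(yy)))[[1]]$`F value`[1]
  expect_equal(f2, ref, tolerance = 1e-10)
})

test_that("label permutation breaks ANOVA selection overlap", {
  set.seed(85)
  n <- 40; p <- 50; k <- 5
  X <- matrix(rnorm(n * p), n)
  y <- rep(0:1, n / 2)
  base <- anovaSelect(X, y, k)$keep
  overlaps <- vapply(1:60, function(i) {
    yp <- sample(y)
    length(intersect(anovaSelect(X, yp, k)$keep, base))
  }, 0)
  # expected overlap ~ k^2/p = 0.5 under the permutation null
  expect_lt(mean(overlaps), 3 * k^2 / p + 0.5)
})

test_that("PCA fusion: explained variance and eigen oracle", {
  set.seed(86)
  X <- matrix(rnorm(40 * 5), 40)
  p <- pcaFlavourFusion(X, 5)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  ev <- eigen(cov(X))$vectors
  for (k in 1:3)
    expect_lt(min(max(abs(p$loadings[, k] - ev[, k])),
                  max(abs(p$loadings[, k] + ev[, k]))), 1e-8)
  # collinear data: one component explains everything
  line <- cbind(1:40, 2 * (1:40) + rnorm(40, sd = 1e-9))
  pl <- pcaFlavourFusion(scale(line, scale = FALSE), 1)
  expect_gt(pl$explained[1], 1 - 1e-9)
  expect_error(pcaFlavourFusion(line, 3), "rank")
})

test_that("polynomial flavour fusion counts and values follow the formula", {
  X <- matrix(1:12, 4, 3)
  pe <- polynomialFlavourFusion(X, feat = c(1, 1, 1))
  expect_identical(ncol(pe$X), 9L)  # 3 linear + 3 squares + C(3,2) pairs
  expect_error(polynomialFlavourFusion(X, c(1, 1, 1), degree = 3), "degree")
  ones <- matrix(1, 2, 3)
  expect_true(all(polynomialFlavourFusion(ones, c(1, 1, 1))$X == 1))
  # 215 features x 17 flavours -> 215 * (17 + 17 + 136) columns
  feat <- rep(seq_len(215), times = 17)
  Xb <- matrix(0, 1, 215 * 17)
  expect_equal(ncol(polynomialFlavourFusion(Xb, feat)$X),
               215 * (17 + 17 + choose(17, 2)))
  # cross-base terms are never formed
  X2 <- cbind(2, 3)
  pe2 <- polynomialFlavourFusion(X2, feat = c(1, 2))
  expect_identical(sort(as.numeric(pe2$X)), c(2, 3, 4, 9))
})

test_that("classifiers separate a separable toy problem; permutation is at
           chance", {
  set.seed(87)
  n <- 120
  y <- rep(0:1, n / 2)
  X <- matrix(rnorm(n * 3), n); X[, 1] <- X[, 1] + 6 * y
  tr <- seq_len(80); val <- 81:120
  for (fam in c("mlp", "rf", "lr")) {
    ms <- trainClassifier(X[tr, ], y[tr], X[val, ], y[val], fam, seed = 1)
    expect_length(ms, 3L)
    expect_gte(max(vapply(ms, function(m) m$val_acc, 0)), 0.95)
  }
  # permuted labels: mean validation accuracy near 0.5 over seeds
  accs <- vapply(1:10, function(s) {
    set.seed(200 + s)
    yp <- sample(y)
    ms <- trainClassifier(X[tr, ], yp[tr], X[val, ], yp[val], "lr", seed = s)
    mean(vapply(ms, function(m) m$val_acc, 0))
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 3 * max(sd(accs), 0.05))
  expect_error(trainClassifier(X[1:5, ], rep(1, 5), X[val, ], y[val], "lr"),
               "single-class")
})

test_that("classifier grid results are reproducible under a fixed seed", {
  set.seed(88)
  X <- matrix(rnorm(40 * 3), 40); y <- rep(0:1, 20)
  a <- trainClassifier(X[1:30, ], y[1:30], X[31:40, ], y[31:40], "mlp",
                       seed = 5)
  b <- trainClassifier(X[1:30, ], y[1:30], X[31:40, ], y[31:40], "mlp",
                       seed = 5)
  expect_identical(vapply(a, function(m) m$val_acc, 0),
                   vapply(b, function(m) m$val_acc, 0))
})

test_that("ensemble voting: unanimity, majority and the tie rule", {
  mk <- function(p) structure(list(family = "fixed", p = p), class = "fx")
  # use the internal vote math through a direct probability matrix
  P <- matrix(0.9, nrow = 2, ncol = 9)
  hard <- P >= 0.5
  expect_true(all(rowSums(hard) > 4))
  # construct member stubs via lr fits on trivial data for the API path
  set.seed(89)
  X <- matrix(rnorm(40), 20, 2); y <- rep(0:1, 10)
  ms <- trainClassifier(X[1:16, ], y[1:16], X[17:20, ], y[17:20], "lr",
                        seed = 2)
  expect_error(ensembleVote(ms, X), "9 members")
  # direct tie-rule replay: 4 vs 4 with mean probability 0.6 -> class 1
  Pt <- cbind(matrix(0.9, 1, 4), matrix(0.45, 1, 4))
  v1 <- sum(Pt >= 0.5); v0 <- 8 - v1
  expect_equal(v1, v0)
  expect_identical(as.integer(mean(Pt) > 0.5), 1L)
})

test_that("fold split is a stratified partition with a nested 80/20 split", {
  y <- rep(c(0, 1), c(35, 25))
  fs <- foldSplit(y, seed = 4)
  expect_identical(sort(unlist(fs$outer)), seq_along(y))
  for (f in 1:5) {
    tr <- setdiff(seq_along(y), fs$outer[[f]])
    expect_setequal(c(fs$inner[[f]]$train, fs$inner[[f]]$val), tr)
    expect_length(intersect(fs$inner[[f]]$train, fs$outer[[f]]), 0L)
    # roughly stratified outer folds
    expect_lt(abs(mean(y[fs$outer[[f]]]) - mean(y)), 0.15)
  }
})

test_that("nested CV reports five external accuracies and guards leakage", {
  ft <- make_toy_tensor(n = 60, nf = 10, nflav = 3, signal = 2)
  cfg <- hmlsConfig("tensor_RF", anova_k = c(4L), pca_k = 4L)
  rep <- runNestedCV(ft, cfg, seed = 3)
  expect_length(rep$test_acc, 5L)
  expect_true(all(rep$test_acc >= 0 & rep$test_acc <= 1))
  for (f in 1:5) {
    test <- rep$folds$outer[[f]]
    for (rec in rep$leakage[[f]])
      for (rows in rec)
        expect_length(intersect(rows, test), 0L)
  }
  # strong signal should be learnable
  expect_gt(rep$test_mean, 0.7)
  # determinism of the whole report
  rep2 <- runNestedCV(ft, cfg, seed = 3)
  expect_identical(rep$test_acc, rep2$test_acc)
})

test_that("conventional frameworks run on a single named flavour", {
  ft <- make_toy_tensor(n = 50, nf = 8, nflav = 3, signal = 2)
  cfg <- hmlsConfig("conventional_DF", flavour = "FL1", pca_k = 4L,
                    anova_k = 4L)
  rep <- runNestedCV(ft, cfg, seed = 2)
  expect_length(rep$val_acc, 5L)
  expect_error(runNestedCV(ft, hmlsConfig("conventional_DF"), seed = 2),
               "flavour")
  expect_error(runNestedCV(ft, hmlsConfig("conventional_DF",
                                          flavour = "nope"), seed = 2),
               "unknown flavour")
})

test_that("a majority-class dummy scores the majority prevalence", {
  # replace the decision by a constant: emulate via a tensor whose labels
  # are imbalanced and signal-free, LR with huge regularization acts as a
  # near-dummy baseline
  set.seed(90)
  n <- 60
  y <- rep(c(0, 1), c(40, 20))
  tables <- list(FL1 = matrix(rnorm(5 * n, sd = 1e-6), 5, n,
                              dimnames = list(NULL, sprintf("P%02d", 1:n))))
  ft <- assembleTensor(tables, y)
  cfg <- hmlsConfig("conventional_RF", flavour = "FL1", anova_k = 2L,
                    grids = list(mlp = data.frame(size = 2L, decay = 10),
                                 rf = data.frame(mtry_frac = 1, ntree = 50L),
                                 lr = data.frame(lambda = 1e6)),
                    ensemble_size = 3L)
  rep <- runNestedCV(ft, cfg, seed = 6)
  expect_lt(abs(rep$test_mean - 2 / 3), 0.15)
})
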