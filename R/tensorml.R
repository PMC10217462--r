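# Conventional (per-flavour) and tensor (cross-flavour) prediction
# frameworks under leakage-free 5-fold nested cross-validation with
# nine-member ensemble voting.

#' Assemble per-flavour feature tables into a FlavourTensor
#'
#' @param tables named list (flavour -> features x patients matrix, all
#'   with identical feature rows and patient columns).
#' @param labels integer 0/1 vector, one per patient.
#' @param patient_ids optional ids (default from the first table's
#'   colnames).
#' @param latents optional patients x k matrix stored in colData.
#' @return A \linkS4class{FlavourTensor}.
#' @export
assembleTensor <- function(tables, labels, patient_ids = NULL,
                           latents = NULL) {
  if (!length(tables) || is.null(names(tables)))
    stop("tables must be a named list of flavour matrices")
  ref <- tables[[1]]
  if (is.null(patient_ids))
    patient_ids <- colnames(ref)
  if (is.null(patient_ids))
    patient_ids <- sprintf("P%03d", seq_len(ncol(ref)))
  for (fl in names(tables)) {
    tb <- tables[[fl]]
    if (!identical(dim(tb), dim(ref)))
      stop("flavour ", fl, " has mismatched dimensions")
    miss <- which(colSums(!is.na(tb)) == 0)
    if (length(miss))
      stop("flavour ", fl, " missing for patient ", patient_ids[miss[1]])
  }
  if (length(labels) != ncol(ref)) stop("labels length mismatch")
  cd <- S4Vectors::DataFrame(label = as.integer(labels),
                             row.names = patient_ids)
  if (!is.null(latents)) cd <- cbind(cd, S4Vectors::DataFrame(latents))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = lapply(tables, function(tb) {
      colnames(tb) <- patient_ids
      tb
    }),
    colData = cd)
  new("FlavourTensor", se)
}

# flatten a FlavourTensor to patients x (features * flavours), with column
# metadata linking each column to its base feature and flavour
.flatten_tensor <- function(ft) {
  flavs <- SummarizedExperiment::assayNames(ft)
  mats <- lapply(flavs, function(fl)
    t(SummarizedExperiment::assay(ft, fl)))
  X <- do.call(cbind, mats)
  nf <- nrow(ft)
  featnames <- rownames(ft)
  if (is.null(featnames)) featnames <- sprintf("f%04d", seq_len(nf))
  colnames(X) <- paste(rep(flavs, each = nf), rep(featnames, length(flavs)),
                       sep = ".")
  list(X = X, feat = rep(seq_len(nf), length(flavs)),
       flav = rep(seq_along(flavs), each = nf))
}

#' Stratified 5-fold outer split with an inner 80/20 split
#'
#' @param labels 0/1 outcome vector.
#' @param k outer folds (default 5).
#' @param inner_frac fraction of the outer-training patients used for
#'   inner training (rest validates model selection).
#' @param seed RNG seed.
#' @return a \code{FoldSplit}: \code{outer} (test index sets partitioning
#'   all patients) and per-fold \code{inner} train/validation indices, all
#'   stratified by label.
#' @export
foldSplit <- function(labels, k = 5L, inner_frac = 0.8, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(labels)
  folds <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  outer <- lapply(seq_len(k), function(f) which(folds == f))
  inner <- lapply(seq_len(k), function(f) {
    tr <- which(folds != f)
    itr <- unlist(lapply(unique(labels[tr]), function(cl) {
      cand <- sample(tr[labels[tr] == cl])
      cand[seq_len(max(1L, round(inner_frac * length(cand))))]
    }))
    list(train = sort(itr), val = sort(setdiff(tr, itr)))
  })
  structure(list(outer = outer, inner = inner, k = k, seed = seed,
                 labels = labels),
            class = "FoldSplit")
}

# ---- fitted transforms (each records the rows it was fit on) -------------

fitImputer <- function(X, rows) {
  med <- apply(X[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  structure(list(medians = med, fitRows = rows), class = "radImputer")
}

applyImputer <- function(fit, X) {
  for (j in which(colSums(is.na(X)) > 0))
    X[is.na(X[, j]), j] <- fit$medians[j]
  X
}

#' Variance filter (fit on training rows only)
#' @param X numeric matrix (patients x features).
#' @param threshold columns with training variance <= threshold are
#'   dropped.
#' @param rows training row indices the filter is fit on.
#' @return list with \code{keep} (column indices) and \code{fitRows}.
#' @export
varianceFilter <- function(X, threshold = 1e-8, rows = seq_len(nrow(X))) {
  v <- apply(X[rows, , drop = FALSE], 2, stats::var)
  v[!is.finite(v)] <- 0
  keep <- which(v > threshold)
  if (!length(keep)) stop("variance filter dropped all columns")
  structure(list(keep = keep, fitRows = rows, variances = v),
            class = "radVarFilter")
}

#' One-way ANOVA F statistics for binary labels
#' @param X patients x features matrix.
#' @param y 0/1 labels (same rows as X).
#' @return numeric vector of F values (0 when within-variance is 0 and
#'   between-variance is 0; Inf when only within is 0).
#' @export
anovaF <- function(X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("a class is absent in the training rows")
  n <- nrow(X)
  g1 <- y == 1
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  mt <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - mt)^2 + n0 * (m0 - mt)^2
  ssw <- colSums((X[g1, , drop = FALSE] -
                    matrix(m1, n1, ncol(X), byrow = TRUE))^2) +
         colSums((X[!g1, , drop = FALSE] -
                    matrix(m0, n0, ncol(X), byrow = TRUE))^2)
  dfb <- 1; dfw <- n - 2
  f <- (ssb / dfb) / (ssw / dfw)
  f[ssw == 0 & ssb == 0] <- 0
  f
}

#' Correlation filter (greedy, ordered by ANOVA F)
#'
#' Passes over columns in decreasing training-F order and drops any column
#' whose absolute Pearson correlation with an already-kept column reaches
#' the threshold. To keep the greedy pass tractable on wide tensors only
#' the \code{max_candidates} columns with the highest F are considered.
#'
#' @param X patients x features matrix.
#' @param y binary labels.
#' @param threshold |r| at or above which a column is dropped.
#' @param rows training rows (filter fit uses only these).
#' @param max_candidates cap on the number of columns entering the pass.
#' @return list with \code{keep} and \code{fitRows}.
#' @export
correlationFilter <- function(X, y, threshold = 0.95,
                              rows = seq_len(nrow(X)),
                              max_candidates = 1200L) {
  Xtr <- X[rows, , drop = FALSE]
  f <- anovaF(Xtr, y[rows])
  ord <- order(-f, seq_along(f))
  if (length(ord) > max_candidates) ord <- ord[seq_len(max_candidates)]
  n <- nrow(Xtr)
  mu <- colMeans(Xtr); sdv <- sqrt(pmax(apply(Xtr, 2, stats::var), 0))
  keep <- integer(0)
  K <- NULL
  for (j in ord) {
    if (sdv[j] == 0) next
    xs <- (Xtr[, j] - mu[j]) / sdv[j]
    if (length(keep)) {
      r <- abs(crossprod(K, xs)) / (n - 1)
      if (any(r >= threshold)) next
    }
    keep <- c(keep, j)
    K <- cbind(K, xs)
  }
  if (!length(keep)) stop("correlation filter dropped all columns")
  structure(list(keep = sort(keep), fitRows = rows),
            class = "radCorFilter")
}

#' PCA flavour fusion (fit on training rows only)
#' @param X patients x features matrix (already filtered/imputed).
#' @param k number of components (<= rank of the training block).
#' @param rows training rows used for centering and loadings.
#' @return list: \code{center}, \code{loadings}, \code{explained}
#'   (variance fractions), \code{fitRows}; use \code{\link{applyPCA}}.
#' @export
pcaFlavourFusion <- function(X, k, rows = seq_len(nrow(X))) {
  Xtr <- X[rows, , drop = FALSE]
  cen <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, cen)
  sv <- svd(Xc)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (k > pos) stop("k exceeds the rank of the training data")
  expl <- sv$d^2 / sum(sv$d^2)
  structure(list(center = cen, loadings = sv$v[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)], fitRows = rows),
            class = "radPCA")
}

#' @rdname pcaFlavourFusion
#' @param fit a \code{pcaFlavourFusion} result.
#' @export
applyPCA <- function(fit, X) {
  sweep(X, 2, fit$center) %*% fit$loadings
}

#' Degree-2 polynomial flavour fusion
#'
#' For every base feature, the surviving flavour columns are expanded with
#' their squares and all pairwise cross-flavour products of the same base
#' feature; no cross-base-feature terms are formed. Stateless (applies
#' identically to any rows).
#'
#' @param X patients x columns matrix.
#' @param feat integer vector mapping each column to its base feature.
#' @param degree must be 2 (v1).
#' @return list \code{X} (expanded matrix) and \code{terms} (two-row index
#'   matrix; squares have both rows equal, linear terms have row 2 = 0).
#' @export
polynomialFlavourFusion <- function(X, feat, degree = 2L) {
  if (degree != 2L) stop("only degree 2 is supported")
  terms1 <- rbind(seq_len(ncol(X)), 0L)
  terms2 <- NULL
  for (f in unique(feat)) {
    cols <- which(feat == f)
    s <- length(cols)
    if (s == 0) next
    sq <- rbind(cols, cols)
    pr <- if (s >= 2) {
      cmb <- utils::combn(cols, 2)
      cmb
    } else NULL
    terms2 <- cbind(terms2, sq, pr)
  }
  terms <- cbind(terms1, terms2)
  out <- matrix(0, nrow(X), ncol(terms))
  lin <- terms[2, ] == 0L
  out[, lin] <- X[, terms[1, lin], drop = FALSE]
  nl <- which(!lin)
  if (length(nl))
    out[, nl] <- X[, terms[1, nl], drop = FALSE] *
      X[, terms[2, nl], drop = FALSE]
  list(X = out, terms = terms)
}

#' Select the top-k columns by ANOVA F (fit on training rows only)
#' @param X patients x features matrix.
#' @param y binary labels (all patients; only \code{rows} are used).
#' @param k columns to keep (ties broken by column order).
#' @param rows training rows.
#' @return list: \code{keep}, \code{F} (training F for kept columns),
#'   \code{fitRows}.
#' @export
anovaSelect <- function(X, y, k, rows = seq_len(nrow(X))) {
  f <- anovaF(X[rows, , drop = FALSE], y[rows])
  k <- min(k, ncol(X))
  keep <- order(-f, seq_along(f))[seq_len(k)]
  structure(list(keep = keep, F = f[keep], fitRows = rows),
            class = "radAnova")
}

fitScaler <- function(X, rows) {
  mu <- colMeans(X[rows, , drop = FALSE])
  sdv <- apply(X[rows, , drop = FALSE], 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  structure(list(mu = mu, sd = sdv, fitRows = rows), class = "radScaler")
}

applyScaler <- function(fit, X) {
  sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
}

# ---- classifiers ---------------------------------------------------------

#' Default hyperparameter grids (three configurations per family)
#' @return named list of data.frames for \code{mlp}, \code{rf}, \code{lr}.
#' @export
defaultGrids <- function() {
  list(mlp = data.frame(size = c(3L, 6L, 12L), decay = c(0.1, 0.1, 0.1)),
       rf = data.frame(mtry_frac = c(0.5, 1, 2), ntree = 300L),
       lr = data.frame(lambda = c(0.01, 0.1, 1)))
}

.fit_one_clf <- function(Xtr, ytr, family, par, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (family == "mlp") {
    fit <- nnet::nnet(Xtr, ytr, size = par$size, decay = par$decay,
                      maxit = 200, entropy = TRUE, trace = FALSE,
                      MaxNWts = 1e5)
    list(family = family, par = par, fit = fit)
  } else if (family == "rf") {
    mtry <- max(1L, min(ncol(Xtr),
                        round(par$mtry_frac * sqrt(ncol(Xtr)))))
    fit <- randomForest::randomForest(Xtr, factor(ytr, levels = c(0, 1)),
                                      ntree = par$ntree, mtry = mtry)
    list(family = family, par = par, fit = fit)
  } else {
    Xg <- if (ncol(Xtr) < 2) cbind(Xtr, 0) else Xtr
    fit <- glmnet::glmnet(Xg, ytr, family = "binomial", alpha = 0,
                          lambda = par$lambda)
    list(family = family, par = par, fit = fit, pad = ncol(Xtr) < 2)
  }
}

.predict_clf <- function(m, X) {
  if (m$family == "mlp") {
    as.numeric(stats::predict(m$fit, X))
  } else if (m$family == "rf") {
    stats::predict(m$fit, X, type = "prob")[, "1"]
  } else {
    Xg <- if (isTRUE(m$pad)) cbind(X, 0) else X
    as.numeric(stats::predict(m$fit, Xg, type = "response"))
  }
}

#' Train one classifier family over its hyperparameter grid
#'
#' @param Xtr,ytr standardized inner-training data.
#' @param Xval,yval inner-validation data (model selection only).
#' @param family "mlp", "rf" or "lr".
#' @param grid data.frame of hyperparameter rows (see
#'   \code{\link{defaultGrids}}).
#' @param seed RNG seed (classifier fits are seeded per grid row).
#' @return list of fitted grid points, each with \code{val_acc}.
#' @export
trainClassifier <- function(Xtr, ytr, Xval, yval, family,
                            grid = defaultGrids()[[family]], seed = 1L) {
  if (length(unique(ytr)) < 2) stop("single-class training set")
  lapply(seq_len(nrow(grid)), function(i) {
    m <- .fit_one_clf(Xtr, ytr, family, grid[i, , drop = FALSE],
                      seed + i)
    p <- .predict_clf(m, Xval)
    m$val_acc <- mean((p >= 0.5) == (yval == 1))
    m
  })
}

#' Ensemble majority vote
#'
#' @param members list of fitted classifiers (normally 9: the top three
#'   grid configurations from each of the three families).
#' @param X feature matrix to predict.
#' @param min_members required member count (default 9).
#' @return integer 0/1 predictions; ties are broken by the mean predicted
#'   probability, then class 0.
#' @export
ensembleVote <- function(members, X, min_members = 9L) {
  if (length(members) < min_members)
    stop("ensemble requires ", min_members, " members")
  P <- vapply(members, function(m) .predict_clf(m, X), numeric(nrow(X)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  hard <- P >= 0.5
  v1 <- rowSums(hard); v0 <- ncol(P) - v1
  out <- ifelse(v1 > v0, 1L, 0L)
  tie <- v1 == v0
  out[tie] <- as.integer(rowMeans(P)[tie] > 0.5)
  out
}

# ---- framework chains ----------------------------------------------------

#' Hybrid machine-learning system configuration
#'
#' @param framework one of \code{"conventional_RF"}, \code{"tensor_RF"},
#'   \code{"conventional_DF"}, \code{"tensor_DF"}, \code{"cnn"}.
#' @param flavour flavour name for the conventional frameworks and the CNN.
#' @param variance_threshold variance-filter threshold.
#' @param correlation_threshold correlation-filter threshold grid
#'   (searched on inner validation along with the other reducer params).
#' @param pca_k,anova_k reducer grids (searched on inner validation).
#' @param poly_degree polynomial flavour-fusion degree (2).
#' @param grids classifier grids, see \code{\link{defaultGrids}}.
#' @param ensemble_size voting members (9 = top 3 per family).
#' @param max_corr_candidates cap for the greedy correlation filter.
#' @param ae_spec,ae_config autoencoder settings for the DF frameworks
#'   (when deep features are computed per fold from flavour sets).
#' @param ae_train_max cap on autoencoder training volumes per fold
#'   (evenly spaced subsample of the inner-training patients).
#' @param cnn_channels,cnn_config CNN baseline settings.
#' @return an \code{HMLSConfig} list.
#' @export
hmlsConfig <- function(framework = c("tensor_DF", "tensor_RF",
                                     "conventional_RF", "conventional_DF",
                                     "cnn"),
                       flavour = NULL,
                       variance_threshold = 1e-8,
                       correlation_threshold = c(0.8, 0.95),
                       pca_k = c(8L, 16L, 32L), anova_k = c(10L, 20L, 50L),
                       poly_degree = 2L,
                       grids = defaultGrids(), ensemble_size = 9L,
                       max_corr_candidates = 1200L,
                       ae_spec = NULL, ae_config = NULL, ae_train_max = 12L,
                       cnn_channels = c(8L, 8L, 4L), cnn_config = NULL) {
  framework <- match.arg(framework)
  if (ensemble_size > sum(vapply(grids, nrow, 0L)) * 3L)
    stop("ensemble_size exceeds the available grid configurations")
  structure(list(framework = framework, flavour = flavour,
                 variance_threshold = variance_threshold,
                 correlation_threshold = correlation_threshold,
                 pca_k = as.integer(pca_k), anova_k = as.integer(anova_k),
                 poly_degree = as.integer(poly_degree), grids = grids,
                 ensemble_size = as.integer(ensemble_size),
                 max_corr_candidates = as.integer(max_corr_candidates),
                 ae_spec = ae_spec, ae_config = ae_config,
                 ae_train_max = as.integer(ae_train_max),
                 cnn_channels = as.integer(cnn_channels),
                 cnn_config = cnn_config),
            class = "HMLSConfig")
}

# fit the reduction chain on itrain rows, returning projected data for a
# given row set plus the leakage record
.fit_chain <- function(X, feat, y, cfg, itrain, pca_k, anova_k,
                       corr_thr = 0.95) {
  rec <- list()
  imp <- fitImputer(X, itrain); rec$imputer <- imp$fitRows
  X <- applyImputer(imp, X)
  if (cfg$framework %in% c("tensor_DF", "conventional_DF")) {
    vf <- varianceFilter(X, cfg$variance_threshold, itrain)
    rec$variance_filter <- vf$fitRows
    X <- X[, vf$keep, drop = FALSE]
    pc <- pcaFlavourFusion(X, min(pca_k, length(itrain) - 2L,
                                  ncol(X)), itrain)
    rec$pca <- pc$fitRows
    X <- applyPCA(pc, X)
  } else {
    cf <- correlationFilter(X, y, corr_thr, itrain,
                            cfg$max_corr_candidates)
    rec$correlation_filter <- cf$fitRows
    X <- X[, cf$keep, drop = FALSE]
    feat <- feat[cf$keep]
    if (cfg$framework == "tensor_RF") {
      pe <- polynomialFlavourFusion(X, feat, cfg$poly_degree)
      X <- pe$X
    }
  }
  an <- anovaSelect(X, y, anova_k, itrain); rec$anova <- an$fitRows
  X <- X[, an$keep, drop = FALSE]
  sc <- fitScaler(X, itrain); rec$scaler <- sc$fitRows
  X <- applyScaler(sc, X)
  list(X = X, rec = rec)
}

#' Run one framework under 5-fold nested cross-validation
#'
#' For each outer fold the full chain (imputer, filters, flavour fusion,
#' ANOVA, scaler, classifiers) is fit on the inner-training 80\% of the
#' four training folds; the nine ensemble members (top three grid
#' configurations per classifier family, chosen on the inner-validation
#' 20\%) vote on the untouched outer test fold. Every fitted transform's
#' fit-row set is recorded in the report for leakage auditing.
#'
#' @param inputs a \linkS4class{FlavourTensor} (feature frameworks), or for
#'   per-fold deep features a list \code{list(flavour_sets =, labels =)}
#'   where \code{flavour_sets} is a per-patient list of
#'   \linkS4class{FlavourSet}s.
#' @param config \code{\link{hmlsConfig}}.
#' @param seed seed driving the fold split and all classifier fits.
#' @param folds optional precomputed \code{\link{foldSplit}}.
#' @return a \code{MetricsReport} list: per-fold validation and external
#'   (outer-test) accuracies, their mean and sd, chosen members, the fold
#'   split, leakage records and the seed.
#' @export
runNestedCV <- function(inputs, config, seed = 1L, folds = NULL) {
  stopifnot(inherits(config, "HMLSConfig"))
  if (config$framework == "cnn")
    stop("use cnnBaseline() for the end-to-end CNN")
  perFoldDF <- is.list(inputs) && !is(inputs, "FlavourTensor") &&
    !is.null(inputs$flavour_sets)
  if (perFoldDF) {
    y <- as.integer(inputs$labels)
    nPat <- length(y)
  } else {
    ft <- inputs
    y <- SummarizedExperiment::colData(ft)$label
    nPat <- length(y)
    fl <- .flatten_tensor(ft)
    if (config$framework %in% c("conventional_RF", "conventional_DF")) {
      if (is.null(config$flavour))
        stop("conventional frameworks need config$flavour")
      fid <- match(config$flavour, flavourNames(ft))
      if (is.na(fid)) stop("unknown flavour: ", config$flavour)
      keep <- fl$flav == fid
      fl$X <- fl$X[, keep, drop = FALSE]
      fl$feat <- fl$feat[keep]
    }
  }
  if (is.null(folds)) folds <- foldSplit(y, seed = seed)
  k <- folds$k
  val_acc <- numeric(k); test_acc <- numeric(k)
  members_info <- vector("list", k)
  leakage <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds$outer[[f]]
    itr <- folds$inner[[f]]$train
    ival <- folds$inner[[f]]$val
    if (perFoldDF) {
      df <- .deep_features_fold(inputs$flavour_sets, itr, config, seed + f)
      Xall <- df$X; feat <- df$feat
      leak_extra <- list(autoencoder = itr)
    } else {
      Xall <- fl$X; feat <- fl$feat
      leak_extra <- NULL
    }
    best <- NULL
    rkgrid <- expand.grid(pca_k = config$pca_k, anova_k = config$anova_k,
                          corr_thr = config$correlation_threshold[1])
    if (config$framework %in% c("tensor_RF", "conventional_RF"))
      rkgrid <- expand.grid(pca_k = NA_integer_,
                            anova_k = unique(config$anova_k),
                            corr_thr = unique(config$correlation_threshold))
    cand <- list()
    for (g in seq_len(nrow(rkgrid))) {
      ch <- tryCatch(
        .fit_chain(Xall, feat, y, config, itr,
                   pca_k = rkgrid$pca_k[g], anova_k = rkgrid$anova_k[g],
                   corr_thr = rkgrid$corr_thr[g]),
        error = function(e) NULL)
      if (is.null(ch)) next
      for (fam in names(config$grids)) {
        ms <- trainClassifier(ch$X[itr, , drop = FALSE], y[itr],
                              ch$X[ival, , drop = FALSE], y[ival],
                              fam, config$grids[[fam]], seed + 17 * g)
        for (m in ms) {
          m$chain <- ch; m$reducer <- rkgrid[g, ]
          cand[[length(cand) + 1L]] <- m
        }
      }
    }
    if (!length(cand)) stop("no candidate models in fold ", f)
    fams <- vapply(cand, function(m) m$family, "")
    accs <- vapply(cand, function(m) m$val_acc, 0)
    mids <- integer(0)
    for (fam in names(config$grids)) {
      ids <- which(fams == fam)
      ids <- ids[order(-accs[ids])]
      mids <- c(mids, ids[seq_len(min(3L, length(ids)))])
    }
    if (length(mids) < config$ensemble_size) {
      spare <- setdiff(order(-accs), mids)
      mids <- c(mids, spare[seq_len(config$ensemble_size - length(mids))])
    }
    members <- cand[mids]
    # members may use different chains; vote member-wise on each row set
    predEV <- function(rows) {
      P <- vapply(members, function(m)
        .predict_clf(m, m$chain$X[rows, , drop = FALSE]),
        numeric(length(rows)))
      if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
      hard <- P >= 0.5
      v1 <- rowSums(hard); v0 <- ncol(P) - v1
      out <- ifelse(v1 > v0, 1L, 0L)
      tie <- v1 == v0
      out[tie] <- as.integer(rowMeans(P)[tie] > 0.5)
      out
    }
    val_acc[f] <- mean(predEV(ival) == y[ival])
    test_acc[f] <- mean(predEV(test) == y[test])
    members_info[[f]] <- lapply(members, function(m)
      list(family = m$family, par = m$par, reducer = m$reducer,
           val_acc = m$val_acc))
    recs <- lapply(members, function(m) m$chain$rec)
    if (!is.null(leak_extra)) recs <- c(recs, list(leak_extra))
    leakage[[f]] <- recs
  }
  structure(list(framework = config$framework, flavour = config$flavour,
                 val_acc = val_acc, test_acc = test_acc,
                 val_mean = mean(val_acc), val_sd = stats::sd(val_acc),
                 test_mean = mean(test_acc), test_sd = stats::sd(test_acc),
                 members = members_info, folds = folds,
                 leakage = leakage, seed = seed),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport [%s%s]\n", x$framework,
              if (!is.null(x$flavour)) paste0(" / ", x$flavour) else ""))
  cat(sprintf("  validation accuracy: %.3f +/- %.3f\n", x$val_mean,
              x$val_sd))
  cat(sprintf("  external test accuracy: %.3f +/- %.3f (folds: %s)\n",
              x$test_mean, x$test_sd,
              paste(sprintf("%.2f", x$test_acc), collapse = ", ")))
  invisible(x)
}

# per-fold deep features: one autoencoder per flavour trained on the
# inner-training patients of that fold only
.deep_features_fold <- function(flavour_sets, itrain, config, seed) {
  flavs <- flavourNames(flavour_sets[[1]])
  grid <- dim(flavour_sets[[1]]@volumes[[1]]@data)
  spec <- config$ae_spec
  if (is.null(spec))
    spec <- autoencoderSpec(grid, channels = c(2L, 2L),
                            bottleneck_channels = 2L)
  tc <- config$ae_config
  if (is.null(tc)) tc <- trainingConfig(epochs = 2L, lr = 2e-3, batch = 4L)
  sub <- itrain
  if (length(sub) > config$ae_train_max)
    sub <- sub[unique(round(seq(1, length(sub),
                                length.out = config$ae_train_max)))]
  mats <- vector("list", length(flavs))
  names(mats) <- flavs
  for (fi in seq_along(flavs)) {
    fl <- flavs[fi]
    vols <- lapply(flavour_sets, function(fs) fs@volumes[[fl]]@data)
    model <- buildAutoencoder(spec, seed = seed + fi)
    tc$seed <- seed + 1000L + fi
    model <- trainAutoencoder(model, vols[sub], tc)
    mats[[fi]] <- vapply(vols, function(v) extractBottleneck(model, v),
                         numeric(spec$bottleneck_len))
  }
  X <- do.call(cbind, lapply(mats, t))
  nf <- spec$bottleneck_len
  list(X = X, feat = rep(seq_len(nf), length(flavs)),
       flav = rep(seq_along(flavs), each = nf))
}

#' End-to-end CNN baseline under the same nested protocol
#'
#' Per outer fold one CNN is trained on the inner-training patients of a
#' single flavour; the nine ensemble members are three random restarts
#' crossed with three epoch checkpoints, voting as in the feature
#' frameworks.
#'
#' @param volumes per-patient list of volumes/arrays (one flavour) in
#'   [0,1], grids divisible by 8.
#' @param labels 0/1 vector.
#' @param config \code{\link{hmlsConfig}} (fields \code{cnn_channels},
#'   \code{cnn_config} used).
#' @param seed seed (fold split, restarts).
#' @param folds optional precomputed \code{\link{foldSplit}}.
#' @return a \code{MetricsReport} with the same shape as
#'   \code{\link{runNestedCV}}.
#' @export
cnnBaseline <- function(volumes, labels, config = hmlsConfig("cnn"),
                        seed = 1L, folds = NULL) {
  y <- as.integer(labels)
  vols <- lapply(volumes, function(v) if (is(v, "RadVolume")) v@data else v)
  if (is.null(folds)) folds <- foldSplit(y, seed = seed)
  k <- folds$k
  tc <- config$cnn_config
  if (is.null(tc)) tc <- trainingConfig(epochs = 6L, lr = 2e-3, batch = 8L)
  ckpts <- unique(pmax(1L, round(tc$epochs * c(1 / 3, 2 / 3, 1))))
  val_acc <- numeric(k); test_acc <- numeric(k)
  leakage <- vector("list", k)
  grid <- dim(vols[[1]])
  for (f in seq_len(k)) {
    test <- folds$outer[[f]]
    itr <- folds$inner[[f]]$train
    ival <- folds$inner[[f]]$val
    members <- list()
    restarts <- 0L
    while (length(members) < config$ensemble_size) {
      restarts <- restarts + 1L
      model <- buildCNN(grid, channels = config$cnn_channels,
                        seed = seed + 101L * f + restarts)
      tc$seed <- seed + 977L * f + restarts
      tr <- trainCNN(model, vols[itr], y[itr], tc,
                     checkpoint_epochs = ckpts)
      snaps <- tr$checkpoints
      if (!length(snaps)) snaps <- list(tr)
      members <- c(members, snaps)
    }
    members <- members[seq_len(config$ensemble_size)]
    predEV <- function(rows) {
      P <- vapply(members, function(m) predictCNN(m, vols[rows]),
                  numeric(length(rows)))
      if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
      hard <- P >= 0.5
      v1 <- rowSums(hard); v0 <- ncol(P) - v1
      out <- ifelse(v1 > v0, 1L, 0L)
      tie <- v1 == v0
      out[tie] <- as.integer(rowMeans(P)[tie] > 0.5)
      out
    }
    val_acc[f] <- mean(predEV(ival) == y[ival])
    test_acc[f] <- mean(predEV(test) == y[test])
    leakage[[f]] <- list(list(cnn = itr))
  }
  structure(list(framework = "cnn", flavour = config$flavour,
                 val_acc = val_acc, test_acc = test_acc,
                 val_mean = mean(val_acc), val_sd = stats::sd(val_acc),
                 test_mean = mean(test_acc), test_sd = stats::sd(test_acc),
                 members = NULL, folds = folds, leakage = leakage,
                 seed = seed),
            class = "MetricsReport")
}
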