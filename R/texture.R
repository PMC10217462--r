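# 3D texture feature families. Matrices come from the C++ accumulators;
# the feature formulas follow the IBSI reference definitions. Undefined
# features (degenerate denominators, single grey level) are NA.

.glcm_feature_names <- c(
  "joint_max", "joint_avg", "joint_var", "joint_entropy", "diff_avg",
  "diff_var", "diff_entropy", "sum_avg", "sum_var", "sum_entropy",
  "energy", "contrast", "dissimilarity", "inv_diff", "inv_diff_norm",
  "inv_diff_mom", "inv_diff_mom_norm", "inv_variance", "correlation",
  "autocorrelation", "cluster_tendency", "cluster_shade",
  "cluster_prominence", "info_corr1", "info_corr2")

# index matrices and diagonal groupings, cached per matrix size
.glcm_idx_cache <- new.env(parent = emptyenv())

.glcm_idx <- function(ng) {
  key <- as.character(ng)
  g <- .glcm_idx_cache[[key]]
  if (!is.null(g)) return(g)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  g <- list(i = i, j = j, dgrp = as.numeric(abs(i - j) + 1L),
            sgrp = as.numeric(i + j - 1L))
  .glcm_idx_cache[[key]] <- g
  g
}

# features of one ng x ng symmetric co-occurrence count matrix
.glcm_features_one <- function(M) {
  ng <- nrow(M)
  s <- sum(M)
  if (s == 0) return(stats::setNames(rep(NA_real_, 25), .glcm_feature_names))
  p <- M / s
  gidx <- .glcm_idx(ng)
  i <- gidx$i
  j <- gidx$j
  pi_ <- rowSums(p)
  mu <- sum(i * p)
  sg2 <- sum((i - mu)^2 * p)
  # difference |i-j| and sum i+j distributions (grouped sums over diagonals)
  dvals <- 0:(ng - 1)
  pd <- as.numeric(rowsum(as.numeric(p), gidx$dgrp))
  svals <- 2:(2 * ng)
  ps <- as.numeric(rowsum(as.numeric(p), gidx$sgrp))
  mu_d <- sum(dvals * pd)
  mu_s <- sum(svals * ps)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HXY <- ent(p)
  px_py <- outer(pi_, pi_)
  HXY1 <- -sum(p[px_py > 0] * log2(px_py[px_py > 0]))
  HXY2 <- ent(px_py)
  HX <- ent(pi_)
  off <- i != j
  out <- c(
    max(p),
    mu,
    sg2,
    HXY,
    mu_d,
    sum((dvals - mu_d)^2 * pd),
    ent(pd),
    mu_s,
    sum((svals - mu_s)^2 * ps),
    ent(ps),
    sum(p^2),
    sum((i - j)^2 * p),
    sum(abs(i - j) * p),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + abs(i - j) / ng)),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + (i - j)^2 / ng^2)),
    if (any(off & p > 0)) sum(p[off] / (i[off] - j[off])^2) else NA_real_,
    if (sg2 > 0) (sum(i * j * p) - mu^2) / sg2 else NA_real_,
    sum(i * j * p),
    sum((i + j - 2 * mu)^2 * p),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    if (HX > 0) (HXY - HXY1) / HX else NA_real_,
    if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else NA_real_)
  stats::setNames(out, .glcm_feature_names)
}

.rl_feature_names <- c(
  "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
  "glnu", "glnu_norm", "rlnu", "rlnu_norm", "run_pct", "gl_var",
  "rl_var", "run_entropy")

# run-length-style features of a level x size matrix (also used for zones
# and distance zones with the appropriate name prefixes)
.rl_features_one <- function(M, nvox) {
  ns <- sum(M)
  if (ns == 0) return(stats::setNames(rep(NA_real_, 16), .rl_feature_names))
  ng <- nrow(M); nr <- ncol(M)
  i <- matrix(seq_len(ng), ng, nr)
  jm <- matrix(seq_len(nr), ng, nr, byrow = TRUE)
  ri <- rowSums(M); rj <- colSums(M)
  p <- M / ns
  mu_i <- sum(i * p); mu_j <- sum(jm * p)
  pe <- p[p > 0]
  out <- c(
    sum(M / jm^2) / ns,
    sum(M * jm^2) / ns,
    sum(M / i^2) / ns,
    sum(M * i^2) / ns,
    sum(M / (i^2 * jm^2)) / ns,
    sum(M * i^2 / jm^2) / ns,
    sum(M * jm^2 / i^2) / ns,
    sum(M * i^2 * jm^2) / ns,
    sum(ri^2) / ns,
    sum(ri^2) / ns^2,
    sum(rj^2) / ns,
    sum(rj^2) / ns^2,
    ns / nvox,
    sum((i - mu_i)^2 * p),
    sum((jm - mu_j)^2 * p),
    -sum(pe * log2(pe)))
  stats::setNames(out, .rl_feature_names)
}

.ngtdm_names <- c("coarseness", "contrast", "busyness", "complexity",
                  "strength")

.ngtdm_features <- function(tab) {
  n_i <- tab[, 1]; s_i <- tab[, 2]
  N <- sum(n_i)
  if (N == 0) return(stats::setNames(rep(NA_real_, 5), .ngtdm_names))
  p <- n_i / N
  ii <- seq_along(p)
  pres <- p > 0
  Ngp <- sum(pres)
  den_coarse <- sum(p * s_i)
  ip <- ii[pres]; pp <- p[pres]; sp_ <- s_i[pres]
  pij_i <- rep(ip, each = length(ip)); pij_j <- rep(ip, length(ip))
  ppi <- rep(pp, each = length(pp)); ppj <- rep(pp, length(pp))
  ssi <- rep(sp_, each = length(sp_)); ssj <- rep(sp_, length(sp_))
  out <- c(
    if (den_coarse > 0) 1 / den_coarse else NA_real_,
    if (Ngp > 1)
      (sum(ppi * ppj * (pij_i - pij_j)^2) / (Ngp * (Ngp - 1))) *
        (sum(s_i) / N)
    else NA_real_,
    if (Ngp > 1 && sum(abs(pij_i * ppi - pij_j * ppj)) > 0)
      den_coarse / sum(abs(pij_i * ppi - pij_j * ppj))
    else NA_real_,
    sum(abs(pij_i - pij_j) * (ppi * ssi + ppj * ssj) / (ppi + ppj)) / N,
    if (sum(s_i) > 0)
      sum((ppi + ppj) * (pij_i - pij_j)^2) / sum(s_i)
    else NA_real_)
  stats::setNames(out, .ngtdm_names)
}

.ngldm_names <- c(
  "lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge", "hdhge",
  "glnu", "glnu_norm", "dcnu", "dcnu_norm", "dc_pct", "gl_var", "dc_var",
  "dc_entropy", "dc_energy")

.ngldm_features <- function(M, nvox) {
  ns <- sum(M)
  if (ns == 0) return(stats::setNames(rep(NA_real_, 17), .ngldm_names))
  ng <- nrow(M); nk <- ncol(M)
  i <- matrix(seq_len(ng), ng, nk)
  k <- matrix(seq_len(nk), ng, nk, byrow = TRUE)  # dependence count + 1
  ri <- rowSums(M); rk <- colSums(M)
  p <- M / ns
  mu_i <- sum(i * p); mu_k <- sum(k * p)
  pe <- p[p > 0]
  out <- c(
    sum(M / k^2) / ns,
    sum(M * k^2) / ns,
    sum(M / i^2) / ns,
    sum(M * i^2) / ns,
    sum(M / (i^2 * k^2)) / ns,
    sum(M * k^2 / i^2) / ns,
    sum(M * i^2 / k^2) / ns,
    sum(M * i^2 * k^2) / ns,
    sum(ri^2) / ns,
    sum(ri^2) / ns^2,
    sum(rk^2) / ns,
    sum(rk^2) / ns^2,
    ns / nvox,
    sum((i - mu_i)^2 * p),
    sum((k - mu_k)^2 * p),
    -sum(pe * log2(pe)),
    sum(p^2))
  stats::setNames(out, .ngldm_names)
}

#' Texture features for one family
#'
#' \code{GLCM} (25 features) and \code{GLRLM} (16) are emitted under both
#' the \code{averaged} (features per direction, then averaged over the 13
#' directions) and \code{merged} (matrices summed over directions, features
#' once) 3D aggregations. \code{GLSZM}/\code{GLDZM} (16 each),
#' \code{NGTDM} (5) and \code{NGLDM} (17) use a single 3D matrix with
#' 26-connectivity; GLDZM distances are Chebyshev distances to the mask
#' edge.
#'
#' @param kind one of "GLCM","GLRLM","GLSZM","GLDZM","NGTDM","NGLDM".
#' @param disc a \code{\link{discretizeFBN}} result.
#' @param aggregation "averaged" or "merged" (GLCM/GLRLM only).
#' @return named numeric vector.
#' @export
textureFeatures <- function(kind = c("GLCM", "GLRLM", "GLSZM", "GLDZM",
                                     "NGTDM", "NGLDM"),
                            disc, aggregation = c("averaged", "merged")) {
  kind <- match.arg(kind)
  nvox <- sum(disc$levels > 0L)
  if (kind %in% c("GLCM", "GLRLM")) {
    aggregation <- match.arg(aggregation)
    arr <- if (kind == "GLCM") glcm3d(disc) else glrlm3d(disc)
    fun <- if (kind == "GLCM") .glcm_features_one
           else function(M) .rl_features_one(M, nvox)
    if (aggregation == "merged") {
      f <- fun(apply(arr, c(1, 2), sum))
    } else {
      per <- vapply(seq_len(dim(arr)[3]), function(k) fun(arr[, , k]),
                    numeric(if (kind == "GLCM") 25 else 16))
      f <- rowMeans(per)
    }
    names(f) <- paste0(tolower(kind), "_", aggregation, "_", names(f))
    return(f)
  }
  if (kind %in% c("GLSZM", "GLDZM")) {
    z <- greyLevelZones(disc, with_distance = (kind == "GLDZM"))
    col <- if (kind == "GLDZM") z[, "mindist"] else z[, "size"]
    ncol_ <- max(col, 1L)
    M <- matrix(0, disc$ng, ncol_)
    for (r in seq_len(nrow(z))) M[z[r, "level"], col[r]] <- M[z[r, "level"], col[r]] + 1
    f <- .rl_features_one(M, nvox)
    pre <- tolower(kind)
    ren <- c(sre = "sze", lre = "lze", srlge = "szlge", srhge = "szhge",
             lrlge = "lzlge", lrhge = "lzhge", rlnu = "zsnu",
             rlnu_norm = "zsnu_norm", run_pct = "zone_pct",
             rl_var = "zs_var", run_entropy = "zs_entropy")
    if (kind == "GLDZM")
      ren <- c(sre = "sde", lre = "lde", srlge = "sdlge", srhge = "sdhge",
               lrlge = "ldlge", lrhge = "ldhge", rlnu = "zdnu",
               rlnu_norm = "zdnu_norm", run_pct = "zone_pct",
               rl_var = "zd_var", run_entropy = "zd_entropy")
    nm <- names(f)
    hit <- nm %in% names(ren)
    nm[hit] <- ren[nm[hit]]
    names(f) <- paste0(pre, "_", nm)
    return(f)
  }
  if (kind == "NGTDM") {
    f <- .ngtdm_features(cpp_ngtdm(as.integer(disc$levels),
                                   dim(disc$levels), disc$ng))
    names(f) <- paste0("ngtdm_", names(f))
    return(f)
  }
  M <- cpp_ngldm(as.integer(disc$levels), dim(disc$levels), disc$ng, 0L)
  f <- .ngldm_features(M, nvox)
  names(f) <- paste0("ngldm_", names(f))
  f
}
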