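# First-order feature blocks: intensity statistics, local intensity peaks,
# intensity histogram, intensity-volume histogram.

.is_names <- c(
  "stat_mean", "stat_variance", "stat_skewness", "stat_kurtosis",
  "stat_median", "stat_min", "stat_p10", "stat_p90", "stat_max",
  "stat_iqr", "stat_range", "stat_mad", "stat_rmad", "stat_medad",
  "stat_cov", "stat_qcod", "stat_energy", "stat_rms")

#' Intensity-based statistics (18 features)
#'
#' IBSI intensity statistics on the raw (continuous) in-mask values.
#' Moment ratios of a zero-variance region are \code{NA} (undefined).
#'
#' @param vol \linkS4class{RadVolume}.
#' @param mask \linkS4class{RadMask} on the same grid.
#' @return named numeric vector (18 features).
#' @export
intensityStats <- function(vol, mask) {
  x <- vol@data[mask@data == 1]
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)  # population variance
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  rx <- x[x >= q[1] & x <= q[5]]
  out <- c(
    stat_mean = mu,
    stat_variance = v,
    stat_skewness = if (v > 0) mean((x - mu)^3) / v^1.5 else NA_real_,
    stat_kurtosis = if (v > 0) mean((x - mu)^4) / v^2 - 3 else NA_real_,
    stat_median = q[3],
    stat_min = min(x),
    stat_p10 = q[1],
    stat_p90 = q[5],
    stat_max = max(x),
    stat_iqr = q[4] - q[2],
    stat_range = max(x) - min(x),
    stat_mad = mean(abs(x - mu)),
    stat_rmad = mean(abs(rx - mean(rx))),
    stat_medad = mean(abs(x - q[3])),
    stat_cov = if (mu != 0) sqrt(v) / mu else NA_real_,
    stat_qcod = if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2])
                else NA_real_,
    stat_energy = sum(x^2),
    stat_rms = sqrt(mean(x^2)))
  stats::setNames(out, .is_names)
}

#' Local and global intensity peaks (2 features)
#'
#' Mean intensity within a 1 cm^3 sphere (radius 6.2 mm) centred on (local)
#' the brightest voxel(s) of the region, and (global) any in-mask voxel,
#' maximized.
#'
#' @inheritParams intensityStats
#' @param cache optional precomputed neighborhood gather table (built
#'   internally when extracting many flavours of one patient).
#' @return named numeric vector: \code{loc_peak_local},
#'   \code{loc_peak_global}.
#' @export
localIntensityPeaks <- function(vol, mask, cache = NULL) {
  if (is.null(cache)) cache <- .peak_cache(mask)
  vals <- vol@data[mask@data == 1]
  G <- array(vol@data[cache$M], dim(cache$M))
  sphere_mean <- rowSums(G, na.rm = TRUE) / cache$cnt
  mx <- max(vals)
  c(loc_peak_local = max(sphere_mean[vals == mx]),
    loc_peak_global = max(sphere_mean))
}

# linear-index gather table for the 1 cm^3 sphere around each mask voxel
.peak_cache <- function(mask) {
  sp <- mask@spacing
  r <- 6.2
  d <- dim(mask@data)
  ranges <- lapply(1:3, function(k) seq(-floor(r / sp[k]), floor(r / sp[k])))
  off <- as.matrix(expand.grid(ranges[[1]], ranges[[2]], ranges[[3]]))
  keep <- sqrt((off[, 1] * sp[1])^2 + (off[, 2] * sp[2])^2 +
               (off[, 3] * sp[3])^2) <= r
  off <- off[keep, , drop = FALSE]
  inm <- which(mask@data == 1, arr.ind = TRUE)
  M <- matrix(NA_integer_, nrow(inm), nrow(off))
  for (k in seq_len(nrow(off))) {
    p <- sweep(inm, 2, off[k, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
          p[, 3] >= 1 & p[, 3] <= d[3]
    M[ok, k] <- p[ok, 1] + d[1] * (p[ok, 2] - 1L) +
      d[1] * d[2] * (p[ok, 3] - 1L)
  }
  list(M = M, cnt = rowSums(!is.na(M)))
}

.ih_names <- c(
  "ih_mean", "ih_variance", "ih_skewness", "ih_kurtosis", "ih_median",
  "ih_min", "ih_p10", "ih_p90", "ih_max", "ih_mode", "ih_iqr", "ih_range",
  "ih_mad", "ih_rmad", "ih_medad", "ih_cov", "ih_qcod", "ih_entropy",
  "ih_uniformity", "ih_max_gradient", "ih_max_gradient_level",
  "ih_min_gradient", "ih_min_gradient_level")

#' Intensity-histogram features (23)
#'
#' Computed on the discretized grey levels 1..Ng. The mode takes the lowest
#' level on ties; histogram gradients use central differences with
#' one-sided edges.
#'
#' @param disc a \code{\link{discretizeFBN}} result.
#' @return named numeric vector (23 features).
#' @export
histogramFeatures <- function(disc) {
  lev <- disc$levels[disc$levels > 0L]
  ng <- disc$ng
  H <- tabulate(lev, nbins = ng)
  n <- length(lev)
  p <- H / n
  i <- seq_len(ng)
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  q <- stats::quantile(lev, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  rx <- lev[lev >= q[1] & lev <= q[5]]
  grad <- numeric(ng)
  if (ng >= 2) {
    grad[1] <- H[2] - H[1]
    grad[ng] <- H[ng] - H[ng - 1]
    if (ng > 2) grad[2:(ng - 1)] <- (H[3:ng] - H[1:(ng - 2)]) / 2
  }
  pos <- p > 0
  out <- c(
    mu, v,
    if (v > 0) sum((i - mu)^3 * p) / v^1.5 else NA_real_,
    if (v > 0) sum((i - mu)^4 * p) / v^2 - 3 else NA_real_,
    q[3], min(lev), q[1], q[5], max(lev),
    which.max(H),
    q[4] - q[2], max(lev) - min(lev),
    sum(abs(lev - mu)) / n,
    mean(abs(rx - mean(rx))),
    mean(abs(lev - q[3])),
    if (mu != 0) sqrt(v) / mu else NA_real_,
    if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else NA_real_,
    -sum(p[pos] * log2(p[pos])),
    sum(p^2),
    max(grad), which.max(grad), min(grad), which.min(grad))
  stats::setNames(out, .ih_names)
}

.ivh_names <- c("ivh_v10", "ivh_v90", "ivh_i10", "ivh_i90",
                "ivh_v10_minus_v90", "ivh_i10_minus_i90", "ivh_auc")

#' Intensity-volume-histogram features (7)
#'
#' The IVH curve \eqn{\nu(\gamma)} is the fractional volume with intensity
#' at least \code{min + gamma * range}. \code{Vx} is \eqn{\nu} at intensity
#' fraction x/100; \code{Ix} is the smallest intensity at which no more
#' than x percent of the volume remains; the AUC is the exact integral
#' \code{mean((x - min) / range)}. All are \code{NA} for a constant region.
#'
#' @inheritParams intensityStats
#' @return named numeric vector (7 features).
#' @export
ivhFeatures <- function(vol, mask) {
  x <- vol@data[mask@data == 1]
  rng <- range(x)
  if (rng[2] <= rng[1])
    return(stats::setNames(c(1, 1, rng[1], rng[1], 0, 0, NA_real_),
                           .ivh_names))
  nu <- function(g) mean(x >= rng[1] + g * (rng[2] - rng[1]))
  ix <- function(frac) {
    xs <- sort(x, decreasing = TRUE)
    k <- max(1L, floor(frac * length(x)))
    xs[k]
  }
  v10 <- nu(0.10); v90 <- nu(0.90)
  i10 <- ix(0.10); i90 <- ix(0.90)
  stats::setNames(c(v10, v90, i10, i90, v10 - v90, i10 - i90,
                    mean((x - rng[1]) / (rng[2] - rng[1]))), .ivh_names)
}
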