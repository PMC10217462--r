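# IBSI morphology feature block: mesh-based volume/surface (marching
# tetrahedra on the 0.5 level set), axis lengths from the inertia tensor,
# bounding volumes (AABB, PCA-aligned box, enclosing/equivalent ellipsoids,
# convex hull) and spatial autocorrelation of intensities.


# light separable [1,2,1]/4 smoothing of the binary mask before meshing:
# the interpolated 0.5 level set of the smoothed field approximates the
# tumor boundary far better than the staircase surface of the raw mask
.smooth_mask <- function(m, passes = 1L) {
  f <- m
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      n <- dim(f)[ax]
      lo <- pmax(seq_len(n) - 1L, 1L)
      hi <- pmin(seq_len(n) + 1L, n)
      f <- switch(ax,
        0.25 * f[lo, , , drop = FALSE] + 0.5 * f + 0.25 * f[hi, , , drop = FALSE],
        0.25 * f[, lo, , drop = FALSE] + 0.5 * f + 0.25 * f[, hi, , drop = FALSE],
        0.25 * f[, , lo, drop = FALSE] + 0.5 * f + 0.25 * f[, , hi, drop = FALSE])
    }
  }
  f
}

# Thomsen approximation to the ellipsoid surface (semi-axes a >= b >= c)
.ellipsoid_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# minimum-volume enclosing ellipsoid (Khachiyan), points as rows
.mvee <- function(P, tol = 1e-3, maxit = 200L) {
  n <- nrow(P); d <- ncol(P)
  if (n <= d) return(NULL)
  Q <- t(cbind(P, 1))
  u <- rep(1 / n, n)
  for (it in seq_len(maxit)) {
    X <- Q %*% (u * t(Q))
    Xi <- tryCatch(solve(X), error = function(e) NULL)
    if (is.null(Xi)) return(NULL)
    m <- colSums(Q * (Xi %*% Q))
    j <- which.max(m)
    step <- (m[j] - d - 1) / ((d + 1) * (m[j] - 1))
    if (!is.finite(step) || step <= tol / n) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  cen <- colSums(P * u)
  A <- tryCatch(
    solve(t(P) %*% (u * P) - outer(cen, cen)) / d,
    error = function(e) NULL)
  if (is.null(A)) return(NULL)
  ev <- eigen(A, symmetric = TRUE)$values
  if (any(ev <= 0)) return(NULL)
  semi <- sort(1 / sqrt(ev), decreasing = TRUE)
  list(center = cen, semiaxes = semi)
}

.morph_names <- c(
  "morph_volume_mesh", "morph_volume_voxel", "morph_surface_area",
  "morph_surface_to_volume", "morph_compactness1", "morph_compactness2",
  "morph_spherical_disproportion", "morph_sphericity", "morph_asphericity",
  "morph_com_shift", "morph_max_3d_diameter", "morph_major_axis",
  "morph_minor_axis", "morph_least_axis", "morph_elongation",
  "morph_flatness", "morph_vol_density_aabb", "morph_area_density_aabb",
  "morph_vol_density_ombb", "morph_area_density_ombb",
  "morph_vol_density_aee", "morph_area_density_aee",
  "morph_vol_density_mvee", "morph_area_density_mvee",
  "morph_vol_density_chull", "morph_area_density_chull",
  "morph_integrated_intensity", "morph_moran_i", "morph_geary_c")

#' Precompute mask-only geometry shared across flavours
#'
#' All mesh/hull/ellipsoid/axis quantities depend only on the mask, so when
#' the 215-feature vector is extracted for many flavours of one patient the
#' geometry is computed once and reused; only the intensity-dependent
#' morphology entries are recomputed per flavour.
#'
#' @param mask \linkS4class{RadMask}.
#' @param autocorr_max_voxels subsample cap for Moran/Geary.
#' @return an opaque geometry cache for \code{\link{morphologyFeatures}}.
#' @export
maskGeometry <- function(mask, autocorr_max_voxels = 600L) {
  m <- mask@data
  sp <- mask@spacing
  nvox <- sum(m)
  out <- stats::setNames(rep(NA_real_, length(.morph_names)), .morph_names)
  out["morph_volume_voxel"] <- nvox * prod(sp)
  idx <- which(m == 1, arr.ind = TRUE)
  X <- sweep(idx, 2, sp, "*")
  if (nvox > 1) {
    S <- stats::cov(X) * (nvox - 1) / nvox
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    out["morph_major_axis"] <- 4 * sqrt(ev[1])
    out["morph_minor_axis"] <- 4 * sqrt(ev[2])
    out["morph_least_axis"] <- 4 * sqrt(ev[3])
    out["morph_elongation"] <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
    out["morph_flatness"] <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
  }
  geom <- list(static = out, X = X, nvox = nvox, com_geom = colMeans(X),
               V = NA_real_)
  if (nvox == 1) return(geom)
  mesh <- cpp_mesh(.smooth_mask(m), dim(m), sp, iso = 0.5)
  V <- mesh$volume; A <- mesh$area
  out["morph_volume_mesh"] <- V
  out["morph_surface_area"] <- A
  out["morph_surface_to_volume"] <- A / V
  out["morph_compactness1"] <- V / (sqrt(pi) * A^1.5)
  out["morph_compactness2"] <- 36 * pi * V^2 / A^3
  out["morph_spherical_disproportion"] <- A / (36 * pi * V^2)^(1 / 3)
  out["morph_sphericity"] <- (36 * pi * V^2)^(1 / 3) / A
  out["morph_asphericity"] <- (A^3 / (36 * pi * V^2))^(1 / 3) - 1
  verts <- mesh$vertices
  hull <- cpp_convhull(verts)
  if (length(hull$vertices) >= 4) {
    hv <- verts[hull$vertices, , drop = FALSE]
    out["morph_max_3d_diameter"] <- cpp_max_pairwise_dist(hv)
    if (hull$volume > 0) {
      out["morph_vol_density_chull"] <- V / hull$volume
      out["morph_area_density_chull"] <- A / hull$area
    }
    mv <- .mvee(hv)
    if (!is.null(mv)) {
      s <- mv$semiaxes
      vol_mvee <- 4 / 3 * pi * prod(s)
      if (vol_mvee > 0) {
        out["morph_vol_density_mvee"] <- V / vol_mvee
        out["morph_area_density_mvee"] <- A / .ellipsoid_area(s[1], s[2], s[3])
      }
    }
  }
  ext <- apply(verts, 2, function(v) diff(range(v)))
  if (all(ext > 0)) {
    out["morph_vol_density_aabb"] <- V / prod(ext)
    out["morph_area_density_aabb"] <-
      A / (2 * (ext[1] * ext[2] + ext[1] * ext[3] + ext[2] * ext[3]))
  }
  if (nvox > 3) {
    ec <- eigen(stats::cov(X), symmetric = TRUE)$vectors
    VR <- sweep(verts, 2, colMeans(verts)) %*% ec
    ext2 <- apply(VR, 2, function(v) diff(range(v)))
    if (all(ext2 > 0)) {
      out["morph_vol_density_ombb"] <- V / prod(ext2)
      out["morph_area_density_ombb"] <-
        A / (2 * (ext2[1] * ext2[2] + ext2[1] * ext2[3] + ext2[2] * ext2[3]))
    }
  }
  if (nvox > 1 && !is.na(out["morph_major_axis"]) &&
      out["morph_least_axis"] > 0) {
    a <- out["morph_major_axis"] / 2
    b <- out["morph_minor_axis"] / 2
    c <- out["morph_least_axis"] / 2
    out["morph_vol_density_aee"] <- V / (4 / 3 * pi * a * b * c)
    out["morph_area_density_aee"] <- A / .ellipsoid_area(a, b, c)
  }
  keep <- seq_len(nvox)
  if (nvox > autocorr_max_voxels)
    keep <- unique(round(seq(1, nvox, length.out = autocorr_max_voxels)))
  W <- 1 / as.matrix(stats::dist(X[keep, , drop = FALSE]))
  diag(W) <- 0
  geom$static <- out
  geom$V <- V
  geom$keep <- keep
  geom$W <- W
  geom$sw <- sum(W)
  geom
}

#' Morphology features (29, IBSI-style)
#'
#' Mesh volume and surface come from a marching-tetrahedra triangulation of
#' the 0.5 level set of the binary mask; the maximum 3D diameter is the
#' largest distance between convex-hull vertices of that mesh; axis lengths
#' derive from the eigenvalues of the voxel-position covariance.
#' For a single-voxel mask the mesh-based entries are returned as \code{NA}
#' and only voxel-counting features are kept.
#'
#' @param mask \linkS4class{RadMask}.
#' @param vol \linkS4class{RadVolume} on the same grid (intensities for the
#'   centre-of-mass shift, integrated intensity and autocorrelation).
#' @param autocorr_max_voxels subsample cap for Moran/Geary (O(n^2) pairs).
#' @param geom optional precomputed \code{\link{maskGeometry}} cache.
#' @return named numeric vector of 29 features (mm-based units).
#' @export
morphologyFeatures <- function(mask, vol, autocorr_max_voxels = 600L,
                               geom = NULL) {
  if (is.null(geom)) geom <- maskGeometry(mask, autocorr_max_voxels)
  out <- geom$static
  xv <- vol@data[mask@data == 1]
  if (sum(xv) > 0) {
    com_int <- colSums(geom$X * xv) / sum(xv)
    out["morph_com_shift"] <- sqrt(sum((geom$com_geom - com_int)^2))
  }
  if (geom$nvox == 1) return(out)
  out["morph_integrated_intensity"] <- mean(xv) * geom$V
  if (geom$nvox >= 4 && stats::var(xv) > 0 && !is.null(geom$W)) {
    v <- xv[geom$keep]
    n <- length(v)
    mu <- mean(v)
    dev <- v - mu
    out["morph_moran_i"] <-
      (n / geom$sw) * sum(geom$W * outer(dev, dev)) / sum(dev^2)
    out["morph_geary_c"] <-
      ((n - 1) / (2 * geom$sw)) *
      sum(geom$W * outer(v, v, function(a, b) (a - b)^2)) / sum(dev^2)
  }
  out
}
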