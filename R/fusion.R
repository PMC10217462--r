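# Image-level CT/PET fusion: the 15-method registry and volume-level API.

#' The fusion-method registry
#'
#' Returns the closed set of 15 fusion methods, in canonical order:
#' \code{LP} (Laplacian pyramid), \code{RP} (ratio of low-pass pyramid),
#' \code{DWT} (db4 wavelet), \code{DTCWT} (dual-tree complex wavelet),
#' \code{CVT} and \code{NSCT} (FFT-based directional decompositions),
#' \code{SR} (sparse representation), \code{DTCWT_SR}, \code{CVT_SR},
#' \code{NSCT_SR} (hybrids: SR on the low-pass band), \code{BCF}
#' (cross-bilateral filter), \code{WAVELET} (sym4 wavelet), \code{WEIGHTED}
#' (w = 0.5), \code{PCA} (eigenvector-weighted average) and \code{HSI}
#' (hue from PET, intensity from CT).
#'
#' @param names optional subset (and order) of method names.
#' @return named list of method descriptors (\code{name}, \code{type},
#'   \code{params}).
#' @export
fusionRegistry <- function(names = NULL) {
  mk <- function(name, type, ...) list(name = name, type = type,
                                       params = list(...))
  reg <- list(
    LP       = mk("LP", "pyramid", levels = 3L),
    RP       = mk("RP", "pyramid", levels = 3L),
    DWT      = mk("DWT", "pyramid", levels = 3L),
    DTCWT    = mk("DTCWT", "pyramid", levels = 3L),
    CVT      = mk("CVT", "pyramid", levels = 3L),
    NSCT     = mk("NSCT", "pyramid", levels = 3L),
    SR       = mk("SR", "sr"),
    DTCWT_SR = mk("DTCWT_SR", "hybrid", base = "DTCWT"),
    CVT_SR   = mk("CVT_SR", "hybrid", base = "CVT"),
    NSCT_SR  = mk("NSCT_SR", "hybrid", base = "NSCT"),
    BCF      = mk("BCF", "simple"),
    WAVELET  = mk("WAVELET", "pyramid", levels = 3L),
    WEIGHTED = mk("WEIGHTED", "simple", w = 0.5),
    PCA      = mk("PCA", "simple"),
    HSI      = mk("HSI", "simple"))
  if (is.null(names)) return(reg)
  unknown <- setdiff(names, names(reg))
  if (length(unknown)) stop("unknown fusion method(s): ",
                            paste(unknown, collapse = ", "))
  reg[names]
}

# vectorized hue (in [0,1]) to RGB on a 300-degree wheel
.hue_rgb <- function(h) {
  hh <- h * 5  # 0..5 sectors (stop short of wrapping red onto red)
  i <- pmin(floor(hh), 4)
  f <- hh - i
  R <- numeric(length(h)); G <- R; B <- R
  s0 <- i == 0; s1 <- i == 1; s2 <- i == 2; s3 <- i == 3; s4 <- i == 4
  R[s0] <- 1;        G[s0] <- f[s0];     B[s0] <- 0
  R[s1] <- 1 - f[s1]; G[s1] <- 1;        B[s1] <- 0
  R[s2] <- 0;        G[s2] <- 1;         B[s2] <- f[s2]
  R[s3] <- 0;        G[s3] <- 1 - f[s3]; B[s3] <- 1
  R[s4] <- f[s4];    G[s4] <- 0;         B[s4] <- 1
  list(R = R, G = G, B = B)
}

# cross-bilateral filter of x guided by g (5x5 window, edge-clamped)
.cross_bilateral <- function(x, g, sigma_s = 2, sigma_r = 0.1) {
  n1 <- nrow(x); n2 <- ncol(x)
  num <- matrix(0, n1, n2); den <- matrix(0, n1, n2)
  for (oi in -2:2) for (oj in -2:2) {
    ws <- exp(-(oi^2 + oj^2) / (2 * sigma_s^2))
    ri <- pmin(pmax(seq_len(n1) + oi, 1L), n1)
    cj <- pmin(pmax(seq_len(n2) + oj, 1L), n2)
    gs <- g[ri, cj, drop = FALSE]
    w <- ws * exp(-(gs - g)^2 / (2 * sigma_r^2))
    num <- num + w * x[ri, cj, drop = FALSE]
    den <- den + w
  }
  num / den
}

#' Intensity-domain fusion methods
#'
#' \code{WEIGHTED}: convex combination \code{w*ct + (1-w)*pet}.
#' \code{PCA}: weights are the first principal-component loadings of the
#' two-column voxel matrix, normalized to sum 1.
#' \code{HSI}: intensity from the modality average, chromatic modulation
#' with hue taken from PET and saturation from the CT-PET difference,
#' back-converted to luminance.
#' \code{BCF}: cross-bilateral base/detail split; bases averaged, details
#' selected by absolute strength.
#'
#' @param ct,pet \linkS4class{RadVolume}s on the same grid, values in [0,1].
#' @param method one of \code{"WEIGHTED"}, \code{"PCA"}, \code{"HSI"},
#'   \code{"BCF"}.
#' @param w weight for WEIGHTED.
#' @return fused \linkS4class{RadVolume} (clamped to [0,1]).
#' @export
fuseSimple <- function(ct, pet, method = c("WEIGHTED", "PCA", "HSI", "BCF"),
                       w = 0.5) {
  method <- match.arg(method)
  .check_pair(ct, pet)
  a <- ct@data; b <- pet@data
  out <- switch(method,
    WEIGHTED = w * a + (1 - w) * b,
    PCA = {
      wts <- pcaFusionWeights(as.numeric(a), as.numeric(b))
      wts[1] * a + wts[2] * b
    },
    HSI = {
      I <- (a + b) / 2
      s <- abs(a - b)
      col <- .hue_rgb(as.numeric(b))
      Y <- 0.299 * col$R + 0.587 * col$G + 0.114 * col$B
      meanC <- (col$R + col$G + col$B) / 3
      array(as.numeric(I) + as.numeric(s) * (Y - meanC), dim(a))
    },
    BCF = {
      o <- array(0, dim(a))
      for (z in seq_len(dim(a)[3])) {
        base_a <- .cross_bilateral(a[, , z], b[, , z])
        base_b <- .cross_bilateral(b[, , z], a[, , z])
        da <- a[, , z] - base_a; db <- b[, , z] - base_b
        det <- da; pick <- abs(db) > abs(da); det[pick] <- db[pick]
        o[, , z] <- (base_a + base_b) / 2 + det
      }
      o
    })
  RadVolume(pmin(pmax(out, 0), 1), ct@spacing, ct@origin, "FUSED")
}

#' First-principal-component fusion weights
#'
#' @param x,y numeric vectors (voxel intensities of the two modalities).
#' @return numeric(2) weights summing to 1 (0.5/0.5 for degenerate input).
#' @export
pcaFusionWeights <- function(x, y) {
  S <- stats::cov(cbind(x, y))
  if (!all(is.finite(S)) || sum(diag(S)) < 1e-24) return(c(0.5, 0.5))
  e <- eigen(S, symmetric = TRUE)$vectors[, 1]
  if (sum(e) < 0) e <- -e
  if (abs(sum(e)) < 1e-12) return(c(0.5, 0.5))
  e / sum(e)
}

.check_pair <- function(ct, pet) {
  if (!identical(dim(ct@data), dim(pet@data)))
    stop("CT and PET grids differ")
  if (any(abs(ct@spacing - pet@spacing) > 1e-9))
    stop("CT and PET spacings differ")
  rng <- range(ct@data, pet@data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("fusion inputs must be normalized to [0,1]")
  invisible(TRUE)
}

#' Fuse one co-registered CT/PET pair with a named method
#'
#' Transform-based methods are applied axial-slice-wise and restacked; the
#' fused volume is clamped to [0,1].
#'
#' @param ct,pet \linkS4class{RadVolume}s on one grid, values in [0,1].
#' @param method a method name from \code{\link{fusionRegistry}} or a
#'   registry descriptor.
#' @param dict optional \code{SparseDictionary} for SR-based methods; if
#'   missing it is trained on patches pooled from both inputs.
#' @param seed RNG seed for dictionary training.
#' @param sr_params list(n_atoms, sparsity, iters, max_patches) overriding
#'   the SR training defaults.
#' @return fused \linkS4class{RadVolume}.
#' @export
fusePair <- function(ct, pet, method, dict = NULL, seed = 1L,
                     sr_params = list()) {
  if (is.character(method)) method <- fusionRegistry(method)[[1]]
  .check_pair(ct, pet)
  if (method$type %in% c("sr", "hybrid") && is.null(dict))
    dict <- .train_pair_dictionary(ct, pet, seed, sr_params)
  switch(method$type,
    simple = fuseSimple(ct, pet, method$name,
                        w = if (!is.null(method$params$w)) method$params$w else 0.5),
    sr = {
      d <- dim(ct@data)
      stride <- if (!is.null(sr_params$fuse_stride)) sr_params$fuse_stride
                else 4L
      out <- array(0, d)
      for (z in seq_len(d[3]))
        out[, , z] <- fuseSR(ct@data[, , z], pet@data[, , z], dict, stride)
      RadVolume(pmin(pmax(out, 0), 1), ct@spacing, ct@origin, "FUSED")
    },
    hybrid = fuseHybrid(ct, pet, method$params$base, dict),
    pyramid = {
      d <- dim(ct@data)
      lv <- method$params$levels
      lv <- max(1L, min(lv, floor(log2(min(d[1], d[2])))))
      out <- array(0, d)
      for (z in seq_len(d[3])) {
        pa <- decomposeSlice(ct@data[, , z], method$name, lv)
        pb <- decomposeSlice(pet@data[, , z], method$name, lv)
        out[, , z] <- reconstructSlice(fuseCoefficients(pa, pb))
      }
      RadVolume(pmin(pmax(out, 0), 1), ct@spacing, ct@origin, "FUSED")
    })
}

.train_pair_dictionary <- function(ct, pet, seed = 1L, sr_params = list()) {
  p <- utils::modifyList(list(n_atoms = 64L, sparsity = 4L, iters = 3L,
                              max_patches = 1500L, patch = 8L, stride = 4L),
                         sr_params)
  P <- .pool_patches(ct@data, pet@data, p$patch, p$stride, p$max_patches,
                     seed)
  if (ncol(P) < p$n_atoms) p$n_atoms <- max(4L, ncol(P) %/% 2L)
  learnDictionary(P, n_atoms = p$n_atoms, sparsity = p$sparsity,
                  seed = seed, iters = p$iters)
}

#' Build the full flavour set for one patient
#'
#' Applies every registry method to the preprocessed pair and returns the
#' CT, PET and fused volumes as one \linkS4class{FlavourSet} (17 entries
#' with the default registry). Deterministic under a fixed seed.
#'
#' @param ct,pet preprocessed \linkS4class{RadVolume}s in [0,1].
#' @param registry result of \code{\link{fusionRegistry}} (possibly
#'   subset).
#' @param seed seed for the sparse-dictionary training.
#' @param sr_params SR training overrides, see \code{\link{fusePair}}.
#' @return A \linkS4class{FlavourSet}.
#' @export
buildFlavourSet <- function(ct, pet, registry = fusionRegistry(), seed = 1L,
                            sr_params = list()) {
  .check_pair(ct, pet)
  vols <- list(CT = ct, PET = pet)
  needSR <- any(vapply(registry, function(m) m$type %in% c("sr", "hybrid"),
                       TRUE))
  dict <- if (needSR) .train_pair_dictionary(ct, pet, seed, sr_params)
          else NULL
  for (m in registry) {
    vols[[m$name]] <- tryCatch(
      fusePair(ct, pet, m, dict = dict, seed = seed, sr_params = sr_params),
      error = function(e) stop("fusion method ", m$name, " failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  FlavourSet(vols)
}
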