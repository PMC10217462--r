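# 2D multiscale decompositions used by the image-fusion registry. All
# transforms operate on a single axial slice; fusePair() applies them
# slice-wise over a volume.

# orthonormal Daubechies-4 and Symlet-4 lowpass filters
.db4 <- c(0.23037781330885523, 0.71484657055254150, 0.63088076792959040,
          -0.02798376941698385, -0.18703481171888114, 0.03084138183598696,
          0.03288301166698294, -0.01059740178499728)
.sym4 <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
           -0.01260396726203783, 0.03222310060404270)

.qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

# one level of the periodized orthogonal DWT along a vector (length even)
.dwt1 <- function(x, h) {
  N <- length(x)
  g <- .qmf(h)
  k <- seq.int(0L, N / 2L - 1L)
  a <- numeric(N / 2L); d <- numeric(N / 2L)
  for (n in seq_along(h)) {
    xi <- x[((2L * k + n - 1L) %% N) + 1L]
    a <- a + h[n] * xi
    d <- d + g[n] * xi
  }
  list(a = a, d = d)
}

.idwt1 <- function(a, d, h) {
  N <- 2L * length(a)
  g <- .qmf(h)
  k <- seq.int(0L, N / 2L - 1L)
  y <- numeric(N)
  for (n in seq_along(h)) {
    idx <- ((2L * k + n - 1L) %% N) + 1L
    y[idx] <- y[idx] + a * h[n] + d * g[n]
  }
  y
}

# columns of a matrix transformed at once (each column one signal)
.dwt1m <- function(M, h) {
  N <- nrow(M)
  g <- .qmf(h)
  k <- seq.int(0L, N / 2L - 1L)
  A <- matrix(0, N / 2L, ncol(M)); D <- A
  for (n in seq_along(h)) {
    idx <- ((2L * k + n - 1L) %% N) + 1L
    A <- A + h[n] * M[idx, , drop = FALSE]
    D <- D + g[n] * M[idx, , drop = FALSE]
  }
  list(a = A, d = D)
}

.idwt1m <- function(A, D, h) {
  N <- 2L * nrow(A)
  g <- .qmf(h)
  k <- seq.int(0L, N / 2L - 1L)
  Y <- matrix(0, N, ncol(A))
  for (n in seq_along(h)) {
    idx <- ((2L * k + n - 1L) %% N) + 1L
    Y[idx, ] <- Y[idx, ] + A * h[n] + D * g[n]
  }
  Y
}

.dwt2_level <- function(m, h) {
  r <- .dwt1m(m, h)                      # along columns
  rl <- .dwt1m(t(r$a), h)                # along rows of A
  rh <- .dwt1m(t(r$d), h)
  list(LL = t(rl$a), LH = t(rl$d), HL = t(rh$a), HH = t(rh$d))
}

.idwt2_level <- function(LL, LH, HL, HH, h) {
  A <- t(.idwt1m(t(LL), t(LH), h))
  D <- t(.idwt1m(t(HL), t(HH), h))
  .idwt1m(A, D, h)
}

# pad a slice by edge replication to dims divisible by 2^levels
.pad_pow2 <- function(m, levels) {
  mult <- 2L^levels
  nr <- ceiling(nrow(m) / mult) * mult
  nc <- ceiling(ncol(m) / mult) * mult
  if (nr == nrow(m) && nc == ncol(m)) return(list(m = m, dim = dim(m)))
  ri <- pmin(seq_len(nr), nrow(m)); ci <- pmin(seq_len(nc), ncol(m))
  list(m = m[ri, ci, drop = FALSE], dim = dim(m))
}

.dwt2 <- function(m, h, levels) {
  p <- .pad_pow2(m, levels)
  cur <- p$m
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    r <- .dwt2_level(cur, h)
    details[[l]] <- list(LH = r$LH, HL = r$HL, HH = r$HH)
    cur <- r$LL
  }
  list(low = cur, details = details, origdim = p$dim)
}

.idwt2 <- function(dec, h) {
  cur <- dec$low
  for (l in rev(seq_along(dec$details))) {
    b <- dec$details[[l]]
    cur <- .idwt2_level(cur, b$LH, b$HL, b$HH, h)
  }
  cur[seq_len(dec$origdim[1]), seq_len(dec$origdim[2]), drop = FALSE]
}

# --- Gaussian / Laplacian / ratio pyramids --------------------------------

.k5 <- c(1, 4, 6, 4, 1) / 16

.blur5 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (o in -2:2)
    out <- out + .k5[o + 3] * m[pmin(pmax(seq_len(n1) + o, 1L), n1), , drop = FALSE]
  m2 <- out; out <- matrix(0, n1, n2)
  for (o in -2:2)
    out <- out + .k5[o + 3] * m2[, pmin(pmax(seq_len(n2) + o, 1L), n2), drop = FALSE]
  out
}

.pyr_reduce <- function(m) {
  b <- .blur5(m)
  b[seq.int(1L, nrow(b), 2L), seq.int(1L, ncol(b), 2L), drop = FALSE]
}

.pyr_expand <- function(m, targetdim) {
  ri <- seq.int(1L, targetdim[1], 2L)
  ci <- seq.int(1L, targetdim[2], 2L)
  up <- matrix(0, targetdim[1], targetdim[2])
  up[ri, ci] <- m[seq_along(ri), seq_along(ci), drop = FALSE]
  ones <- matrix(0, targetdim[1], targetdim[2])
  ones[ri, ci] <- 1
  # normalized interpolation: constants expand to constants, edges included
  .blur5(up) / .blur5(ones)
}

.lp_dec <- function(m, levels, ratio = FALSE, eps = 1e-9) {
  G <- list(m)
  for (l in seq_len(levels)) G[[l + 1]] <- .pyr_reduce(G[[l]])
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    E <- .pyr_expand(G[[l + 1]], dim(G[[l]]))
    details[[l]] <- if (ratio) G[[l]] / (E + eps) else G[[l]] - E
  }
  list(low = G[[levels + 1]], details = details, ratio = ratio, eps = eps)
}

.lp_rec <- function(dec) {
  cur <- dec$low
  for (l in rev(seq_along(dec$details))) {
    E <- .pyr_expand(cur, dim(dec$details[[l]]))
    cur <- if (dec$ratio) dec$details[[l]] * (E + dec$eps)
           else dec$details[[l]] + E
  }
  cur
}

# --- FFT-based nonsubsampled directional decompositions -------------------
# Smooth radial partition of unity times angular partition; reconstruction
# is the plain sum of bands, so it is exact to FFT round-off. The "CVT"
# variant uses triangular angular windows, the "NSCT" variant raised-cosine
# windows and different orientation counts, echoing curvelet and
# nonsubsampled-contourlet constructions.

.rstep <- function(r, t, w) {
  u <- (r - (t - w / 2)) / w
  u <- pmin(pmax(u, 0), 1)
  0.5 * (1 - cos(pi * u))
}

.freq_grids <- function(nr, nc) {
  fx <- (seq_len(nr) - 1); fx <- ifelse(fx <= nr / 2, fx, fx - nr) / nr
  fy <- (seq_len(nc) - 1); fy <- ifelse(fy <= nc / 2, fy, fy - nc) / nc
  FX <- matrix(fx, nr, nc); FY <- matrix(fy, nr, nc, byrow = TRUE)
  list(r = sqrt(FX^2 + FY^2), th = atan2(FY, FX) %% pi)
}

.ang_windows <- function(th, K, smooth) {
  lapply(seq_len(K), function(k) {
    cen <- (k - 0.5) * pi / K
    dlt <- th - cen
    dlt <- ((dlt + pi / 2) %% pi) - pi / 2  # wrap to (-pi/2, pi/2]
    if (smooth) {
      w <- cos(dlt * K / 2)^2
      w[abs(dlt) > pi / K] <- 0
    } else {
      w <- pmax(0, 1 - abs(dlt) / (pi / K))
    }
    w
  })
}

# window multipliers cached per (variant, slice size): rebuilding them per
# slice dominates the cost of the transform on small grids
.freq_win_cache <- new.env(parent = emptyenv())

.freq_windows <- function(nr, nc, variant) {
  key <- paste(variant, nr, nc, sep = "_")
  if (!is.null(.freq_win_cache[[key]])) return(.freq_win_cache[[key]])
  g <- .freq_grids(nr, nc)
  if (variant == "CVT") {
    cuts <- c(0.30, 0.15, 0.075); orient <- c(8, 8, 8); smooth <- FALSE
  } else {
    cuts <- c(0.33, 0.17, 0.085); orient <- c(8, 8, 4); smooth <- TRUE
  }
  C <- lapply(cuts, function(t) .rstep(g$r, t, t))
  radial <- list(C[[1]], C[[2]] - C[[1]], C[[3]] - C[[2]])
  win <- list(low = 1 - C[[3]],
              bands = lapply(seq_along(radial), function(j) {
                aw <- .ang_windows(g$th, orient[j], smooth)
                lapply(aw, function(A) radial[[j]] * A)
              }))
  if (nr * nc <= 65536L) .freq_win_cache[[key]] <- win
  win
}

.freq_dec <- function(m, variant = c("CVT", "NSCT")) {
  variant <- match.arg(variant)
  nr <- nrow(m); nc <- ncol(m)
  win <- .freq_windows(nr, nc, variant)
  FM <- stats::fft(m)
  bands <- lapply(win$bands, function(scale)
    lapply(scale, function(Wm)
      Re(stats::fft(FM * Wm, inverse = TRUE)) / (nr * nc)))
  low <- Re(stats::fft(FM * win$low, inverse = TRUE)) / (nr * nc)
  list(low = low, details = bands)
}

.freq_rec <- function(dec) {
  out <- dec$low
  for (j in seq_along(dec$details))
    for (b in dec$details[[j]]) out <- out + b
  out
}

# --- public slice-level API -----------------------------------------------

#' Decompose a 2D slice with a named multiscale transform
#'
#' @param slice numeric matrix, finite values; both dims must be at least
#'   \code{2^levels} for the subsampled transforms.
#' @param method one of \code{"LP"} (Laplacian pyramid), \code{"RP"} (ratio
#'   of low-pass pyramid), \code{"DWT"} (db4), \code{"WAVELET"} (sym4),
#'   \code{"DTCWT"} (dual-tree, two orthogonal trees with time-reversed
#'   filters), \code{"CVT"}, \code{"NSCT"} (FFT-based nonsubsampled
#'   directional decompositions).
#' @param levels decomposition depth (pyramids and wavelets). Default 3.
#' @return A \code{RadPyramid} list: \code{method}, \code{levels},
#'   method-specific coefficient bands, original dims.
#' @export
decomposeSlice <- function(slice, method = c("LP", "RP", "DWT", "WAVELET",
                                             "DTCWT", "CVT", "NSCT"),
                           levels = 3L) {
  method <- match.arg(method)
  if (!all(is.finite(slice))) stop("slice has non-finite values")
  if (method %in% c("LP", "RP", "DWT", "WAVELET", "DTCWT") &&
      min(dim(slice)) < 2^levels)
    stop("slice too small for ", levels, " levels")
  dec <- switch(method,
    LP = .lp_dec(slice, levels, ratio = FALSE),
    RP = .lp_dec(slice, levels, ratio = TRUE),
    DWT = .dwt2(slice, .db4, levels),
    WAVELET = .dwt2(slice, .sym4, levels),
    DTCWT = {
      hA <- .db4; hB <- rev(.db4)
      trees <- list(aa = .dwt2(slice, hA, levels))
      # separable filter pairs per (row, column) tree
      trees$ab <- .dwt2_mixed(slice, hA, hB, levels)
      trees$ba <- .dwt2_mixed(slice, hB, hA, levels)
      trees$bb <- .dwt2(slice, hB, levels)
      list(trees = trees)
    },
    CVT = .freq_dec(slice, "CVT"),
    NSCT = .freq_dec(slice, "NSCT"))
  structure(list(method = method, levels = levels, dec = dec,
                 dim = dim(slice)), class = "RadPyramid")
}

# separable DWT with different column/row filters (dual-tree variants)
.dwt2_mixed <- function(m, hcol, hrow, levels) {
  p <- .pad_pow2(m, levels)
  cur <- p$m
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    r <- .dwt1m(cur, hcol)
    rl <- .dwt1m(t(r$a), hrow)
    rh <- .dwt1m(t(r$d), hrow)
    details[[l]] <- list(LH = t(rl$d), HL = t(rh$a), HH = t(rh$d))
    cur <- t(rl$a)
  }
  list(low = cur, details = details, origdim = p$dim)
}

.idwt2_mixed <- function(dec, hcol, hrow) {
  cur <- dec$low
  for (l in rev(seq_along(dec$details))) {
    b <- dec$details[[l]]
    A <- t(.idwt1m(t(cur), t(b$LH), hrow))
    D <- t(.idwt1m(t(b$HL), t(b$HH), hrow))
    cur <- .idwt1m(A, D, hcol)
  }
  cur[seq_len(dec$origdim[1]), seq_len(dec$origdim[2]), drop = FALSE]
}

#' Reconstruct a slice from a RadPyramid
#' @param pyr result of \code{\link{decomposeSlice}}.
#' @return numeric matrix with the original slice dims.
#' @export
reconstructSlice <- function(pyr) {
  stopifnot(inherits(pyr, "RadPyramid"))
  switch(pyr$method,
    LP = , RP = .lp_rec(pyr$dec),
    DWT = .idwt2(pyr$dec, .db4),
    WAVELET = .idwt2(pyr$dec, .sym4),
    DTCWT = {
      hA <- .db4; hB <- rev(.db4)
      (.idwt2(pyr$dec$trees$aa, hA) +
       .idwt2_mixed(pyr$dec$trees$ab, hA, hB) +
       .idwt2_mixed(pyr$dec$trees$ba, hB, hA) +
       .idwt2(pyr$dec$trees$bb, hB)) / 4
    },
    CVT = , NSCT = .freq_rec(pyr$dec))
}

#' Number of coefficient bands in a pyramid
#' @param pyr a \code{RadPyramid}.
#' @return integer count: one low-pass band plus all detail bands (for the
#'   dual-tree transform, bands are counted per tree quadruple).
#' @export
bandCount <- function(pyr) {
  stopifnot(inherits(pyr, "RadPyramid"))
  switch(pyr$method,
    LP = , RP = 1L + length(pyr$dec$details),
    DWT = , WAVELET = 1L + 3L * length(pyr$dec$details),
    DTCWT = 1L + 3L * length(pyr$dec$trees$aa$details),
    CVT = , NSCT = 1L + sum(vapply(pyr$dec$details, length, 1L)))
}

# max-abs coefficient selection; ties keep the first (CT) argument
.selmax <- function(a, b, keya = abs(a), keyb = abs(b)) {
  out <- a
  pick <- keyb > keya
  out[pick] <- b[pick]
  out
}

#' Fuse two pyramids coefficient-wise
#'
#' Low-pass bands are averaged; each detail coefficient takes the input
#' coefficient of larger activity (absolute value; for the ratio pyramid,
#' distance of the ratio from 1; for the dual-tree transform, the joint
#' quadrature modulus across the four trees). Ties keep the coefficient of
#' the first argument.
#'
#' @param a,b \code{RadPyramid}s from the same method and levels
#'   (conventionally \code{a} = CT, \code{b} = PET).
#' @return fused \code{RadPyramid}.
#' @export
fuseCoefficients <- function(a, b) {
  stopifnot(inherits(a, "RadPyramid"), inherits(b, "RadPyramid"))
  if (a$method != b$method || a$levels != b$levels ||
      !identical(a$dim, b$dim))
    stop("pyramids are not compatible")
  out <- a
  m <- a$method
  if (m %in% c("LP", "RP")) {
    out$dec$low <- (a$dec$low + b$dec$low) / 2
    for (l in seq_along(a$dec$details)) {
      da <- a$dec$details[[l]]; db <- b$dec$details[[l]]
      out$dec$details[[l]] <- if (m == "RP")
        .selmax(da, db, abs(da - 1), abs(db - 1)) else .selmax(da, db)
    }
  } else if (m %in% c("DWT", "WAVELET")) {
    out$dec$low <- (a$dec$low + b$dec$low) / 2
    for (l in seq_along(a$dec$details))
      for (bn in c("LH", "HL", "HH"))
        out$dec$details[[l]][[bn]] <-
          .selmax(a$dec$details[[l]][[bn]], b$dec$details[[l]][[bn]])
  } else if (m %in% c("CVT", "NSCT")) {
    out$dec$low <- (a$dec$low + b$dec$low) / 2
    for (j in seq_along(a$dec$details))
      for (k in seq_along(a$dec$details[[j]]))
        out$dec$details[[j]][[k]] <-
          .selmax(a$dec$details[[j]][[k]], b$dec$details[[j]][[k]])
  } else if (m == "DTCWT") {
    tn <- c("aa", "ab", "ba", "bb")
    for (t in tn)
      out$dec$trees[[t]]$low <-
        (a$dec$trees[[t]]$low + b$dec$trees[[t]]$low) / 2
    nl <- length(a$dec$trees$aa$details)
    for (l in seq_len(nl))
      for (bn in c("LH", "HL", "HH")) {
        keya <- 0; keyb <- 0
        for (t in tn) {
          keya <- keya + a$dec$trees[[t]]$details[[l]][[bn]]^2
          keyb <- keyb + b$dec$trees[[t]]$details[[l]][[bn]]^2
        }
        pick <- keyb > keya
        for (t in tn) {
          cur <- a$dec$trees[[t]]$details[[l]][[bn]]
          other <- b$dec$trees[[t]]$details[[l]][[bn]]
          cur[pick] <- other[pick]
          out$dec$trees[[t]]$details[[l]][[bn]] <- cur
        }
      }
  }
  out
}
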