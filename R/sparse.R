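# Sparse-representation (K-SVD + OMP) image fusion.

# overlapping patch grid covering the whole slice (final row/col forced)
.patch_positions <- function(n, psize, stride) {
  if (n <= psize) return(1L)
  pos <- seq.int(1L, n - psize + 1L, by = stride)
  if (pos[length(pos)] != n - psize + 1L) pos <- c(pos, n - psize + 1L)
  pos
}

# gather-index table for a patch grid, cached per (dims, psize, stride)
.patch_grid_cache <- new.env(parent = emptyenv())

.patch_grid <- function(nr, nc, psize, stride) {
  key <- paste(nr, nc, psize, stride, sep = "_")
  g <- .patch_grid_cache[[key]]
  if (!is.null(g)) return(g)
  pr <- min(psize, nr); pc <- min(psize, nc)
  rows <- .patch_positions(nr, pr, stride)
  cols <- .patch_positions(nc, pc, stride)
  pos <- cbind(rep(rows, times = length(cols)),
               rep(cols, each = length(rows)))
  inpatch <- as.numeric(outer(seq_len(pr) - 1L,
                              (seq_len(pc) - 1L) * nr, "+"))
  start <- (pos[, 1] - 1L) + (pos[, 2] - 1L) * nr
  idx <- outer(inpatch, start, "+") + 1L  # (pr*pc) x npatch linear indices
  wgt <- numeric(nr * nc)
  tab <- table(idx)
  wgt[as.integer(names(tab))] <- as.numeric(tab)
  g <- list(idx = idx, pos = pos, pr = pr, pc = pc, wgt = pmax(wgt, 1))
  if (nr * nc <= 65536L) .patch_grid_cache[[key]] <- g
  g
}

.extract_patches <- function(slice, psize, stride) {
  g <- .patch_grid(nrow(slice), ncol(slice), psize, stride)
  out <- matrix(slice[g$idx], nrow(g$idx), ncol(g$idx))
  list(patches = out, pos = g$pos, pr = g$pr, pc = g$pc, grid = g)
}

#' Learn a patch dictionary by K-SVD
#'
#' Trains unit-norm atoms on mean-removed patches by alternating OMP sparse
#' coding and rank-1 (SVD) atom updates. The per-iteration mean
#' reconstruction error is tracked; if an iteration would increase it, the
#' previous dictionary is kept and training stops, so the recorded trace is
#' non-increasing.
#'
#' @param patches d x N matrix of vectorized patches (N >= n_atoms).
#' @param n_atoms dictionary size.
#' @param sparsity atoms per patch used during training.
#' @param seed RNG seed (initial atoms are random patches).
#' @param iters maximum K-SVD iterations.
#' @return A \code{SparseDictionary}: unit-norm \code{atoms} (d x n_atoms),
#'   the training parameters and the error trace.
#' @export
learnDictionary <- function(patches, n_atoms = 64L, sparsity = 4L, seed = 1L,
                            iters = 5L) {
  d <- nrow(patches); N <- ncol(patches)
  if (N < n_atoms) stop("too few patches (", N, ") for ", n_atoms, " atoms")
  X <- patches - matrix(colMeans(patches), d, N, byrow = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  init <- sample.int(N, n_atoms)
  D <- X[, init, drop = FALSE] + matrix(rnorm(d * n_atoms, sd = 1e-6), d)
  D <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1e-12), "/")
  errs <- numeric(0)
  prevD <- D; prevErr <- Inf
  for (it in seq_len(iters)) {
    C <- cpp_omp(D, X, sparsity, 1e-9)
    R <- X - D %*% C
    err <- mean(sqrt(colSums(R^2)))
    if (err > prevErr + 1e-12) { D <- prevD; break }
    errs <- c(errs, err)
    prevD <- D; prevErr <- err
    for (k in seq_len(n_atoms)) {
      users <- which(C[k, ] != 0)
      if (!length(users)) {
        worst <- which.max(colSums(R^2))
        a <- X[, worst]
        D[, k] <- a / max(sqrt(sum(a^2)), 1e-12)
        next
      }
      E <- R[, users, drop = FALSE] + outer(D[, k], C[k, users])
      sv <- svd(E, nu = 1, nv = 1)
      D[, k] <- sv$u[, 1]
      C[k, users] <- sv$d[1] * sv$v[, 1]
      R[, users] <- E - outer(D[, k], C[k, users])
    }
  }
  structure(list(atoms = D, sparsity = as.integer(sparsity),
                 patch_size = as.integer(sqrt(d)), err_trace = errs,
                 seed = as.integer(seed)),
            class = "SparseDictionary")
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# pooled patch sample from both slices/volumes for dictionary training
.pool_patches <- function(ct_arr, pet_arr, psize = 8L, stride = 4L,
                          max_patches = 2000L, seed = 1L) {
  grab <- function(a) {
    if (length(dim(a)) == 3L) {
      zs <- unique(round(seq(1, dim(a)[3], length.out = min(dim(a)[3], 8L))))
      do.call(cbind, lapply(zs, function(z)
        .extract_patches(a[, , z], psize, stride)$patches))
    } else .extract_patches(a, psize, stride)$patches
  }
  P <- cbind(grab(ct_arr), grab(pet_arr))
  if (ncol(P) > max_patches) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    P <- P[, sample.int(ncol(P), max_patches), drop = FALSE]
  }
  P
}

#' Sparse-representation fusion of two slices
#'
#' Both slices are cut into overlapping patches on a common grid; each
#' mean-removed patch is sparse-coded by OMP over the dictionary, and per
#' patch the source whose code has the larger L1 norm is kept (ties,
#' including the all-zero code of a flat patch, keep the first/CT source).
#' The kept source's patch content is written back and overlapping patches
#' are averaged, so fusing a slice with itself returns it to within
#' stacking round-off.
#'
#' @param ct_slice,pet_slice numeric matrices of equal shape.
#' @param dict a \code{\link{learnDictionary}} result.
#' @param stride patch stride (default half overlap).
#' @return fused slice matrix.
#' @export
fuseSR <- function(ct_slice, pet_slice, dict, stride = 4L) {
  if (!identical(dim(ct_slice), dim(pet_slice))) stop("slice shape mismatch")
  psize <- dict$patch_size
  pa <- .extract_patches(ct_slice, psize, stride)
  pb <- .extract_patches(pet_slice, psize, stride)
  Xa <- pa$patches; Xb <- pb$patches
  ma <- colMeans(Xa); mb <- colMeans(Xb)
  Ca <- cpp_omp(dict$atoms, Xa - matrix(ma, nrow(Xa), ncol(Xa), byrow = TRUE),
                dict$sparsity, 1e-6)
  Cb <- cpp_omp(dict$atoms, Xb - matrix(mb, nrow(Xb), ncol(Xb), byrow = TRUE),
                dict$sparsity, 1e-6)
  l1a <- colSums(abs(Ca)); l1b <- colSums(abs(Cb))
  pickB <- l1b > l1a
  sel <- Xa
  if (any(pickB)) sel[, pickB] <- Xb[, pickB, drop = FALSE]
  acc <- numeric(length(ct_slice))
  agg <- rowsum(as.numeric(sel), group = as.numeric(pa$grid$idx))
  acc[as.integer(rownames(agg))] <- agg
  matrix(acc / pa$grid$wgt, nrow(ct_slice), ncol(ct_slice))
}

#' Hybrid transform + sparse-representation fusion
#'
#' Decomposes both volumes' slices with a base multiscale transform, fuses
#' the low-pass band(s) by sparse-representation fusion and every detail
#' band by max-absolute selection, then reconstructs.
#'
#' @param ct,pet \linkS4class{RadVolume}s on one grid, values in [0,1].
#' @param base "DTCWT", "CVT" or "NSCT".
#' @param dict a \code{\link{learnDictionary}} result.
#' @return fused \linkS4class{RadVolume}.
#' @export
fuseHybrid <- function(ct, pet, base = c("DTCWT", "CVT", "NSCT"), dict) {
  base <- match.arg(base)
  d <- dim(ct@data)
  out <- array(0, d)
  levels <- if (base == "DTCWT")
    max(1L, min(3L, floor(log2(min(d[1], d[2]) / dict$patch_size)))) else 3L
  for (z in seq_len(d[3])) {
    pa <- decomposeSlice(ct@data[, , z], base, levels)
    pb <- decomposeSlice(pet@data[, , z], base, levels)
    fused <- fuseCoefficients(pa, pb)
    if (base == "DTCWT") {
      for (t in c("aa", "ab", "ba", "bb"))
        fused$dec$trees[[t]]$low <-
          fuseSR(pa$dec$trees[[t]]$low, pb$dec$trees[[t]]$low, dict,
                 stride = max(1L, dict$patch_size %/% 2L))
    } else {
      fused$dec$low <- fuseSR(pa$dec$low, pb$dec$low, dict)
    }
    out[, , z] <- reconstructSlice(fused)
  }
  RadVolume(pmin(pmax(out, 0), 1), ct@spacing, ct@origin, "FUSED")
}
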