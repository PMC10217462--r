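# Shared fixtures and independent brute-force oracles. Everything is
# generated in code under fixed seeds; nothing is read from disk.

ball_mask <- function(radius, pad = 5L, spacing = c(1, 1, 1)) {
  g <- 2L * radius + 2L * pad
  cc <- (g + 1) / 2
  ax <- seq_len(g) - cc
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  RadMask((r <= radius) + 0, spacing = spacing)
}

rand_volume <- function(dim, seed, lo = 0, hi = 1) {
  set.seed(seed)
  RadVolume(array(runif(prod(dim), lo, hi), dim))
}

# a tiny preprocessed phantom pair, cached across tests
.fixture_env <- new.env()

tiny_pair <- function() {
  if (is.null(.fixture_env$pair)) {
    co <- generateCohort(phantomParams(n_patients = 2, grid = c(32, 32, 32),
                                       spacing = c(2, 2, 2), seed = 11))
    .fixture_env$pair <- processPhantom(co[[1]])
    .fixture_env$cohort2 <- co
  }
  .fixture_env$pair
}

# ---- brute-force texture oracles (independent of the C++ accumulators) --

bf_glcm <- function(lev, ng, off) {
  d <- dim(lev)
  M <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- lev[x, y, z]
    if (li == 0) next
    for (s in c(1, -1)) {
      p <- c(x, y, z) + s * off
      if (any(p < 1) || any(p > d)) next
      lj <- lev[p[1], p[2], p[3]]
      if (lj == 0) next
      M[li, lj] <- M[li, lj] + 1
    }
  }
  M
}

bf_glrlm <- function(lev, ng, off, maxrun) {
  d <- dim(lev)
  M <- matrix(0, ng, maxrun)
  seen <- array(FALSE, d)  # voxels already assigned to a run
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- lev[x, y, z]
    if (li == 0 || seen[x, y, z]) next
    # walk backwards to the run start
    p <- c(x, y, z)
    while (TRUE) {
      q <- p - off
      if (any(q < 1) || any(q > d) || lev[q[1], q[2], q[3]] != li) break
      p <- q
    }
    if (seen[p[1], p[2], p[3]]) next
    len <- 0L
    q <- p
    while (!(any(q < 1) || any(q > d)) && lev[q[1], q[2], q[3]] == li) {
      seen[q[1], q[2], q[3]] <- TRUE
      len <- len + 1L
      q <- q + off
    }
    M[li, len] <- M[li, len] + 1
  }
  M
}

# zones via igraph connected components (26-connectivity, equal level)
bf_zones <- function(lev) {
  d <- dim(lev)
  idx <- which(lev > 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(matrix(0, 0, 2))
  key <- (idx[, 1] - 1) + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
  lookup <- integer(prod(d)); lookup[key + 1] <- seq_len(n)
  edges <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_len(n)) {
    for (k in seq_len(nrow(offs))) {
      p <- idx[i, ] + offs[k, ]
      if (any(p < 1) || any(p > d)) next
      if (lev[p[1], p[2], p[3]] != lev[idx[i, 1], idx[i, 2], idx[i, 3]])
        next
      j <- lookup[(p[1] - 1) + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1) + 1]
      if (j > i) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  lv <- lev[idx]
  t(vapply(seq_len(comp$no), function(c) {
    mem <- which(comp$membership == c)
    c(level = lv[mem[1]], size = length(mem))
  }, numeric(2)))
}

bf_cheb_dist <- function(mask) {
  d <- dim(mask)
  inm <- which(mask == 1, arr.ind = TRUE)
  outm <- which(mask == 0, arr.ind = TRUE)
  # pad: any voxel on the array border is also adjacent to outside
  dist <- numeric(nrow(inm))
  for (i in seq_len(nrow(inm))) {
    p <- inm[i, ]
    border <- min(p, d - p + 1)  # steps to leave the grid
    if (nrow(outm)) {
      cheb <- min(pmax(abs(outm[, 1] - p[1]),
                       pmax(abs(outm[, 2] - p[2]), abs(outm[, 3] - p[3]))))
      dist[i] <- min(cheb, border)
    } else dist[i] <- border
  }
  list(idx = inm, dist = dist)
}

bf_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  out <- matrix(0, ng, 2)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- lev[x, y, z]
    if (li == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (any(p < 1) || any(p > d)) next
      lj <- lev[p[1], p[2], p[3]]
      if (lj > 0) nb <- c(nb, lj)
    }
    if (!length(nb)) next
    out[li, 1] <- out[li, 1] + 1
    out[li, 2] <- out[li, 2] + abs(li - mean(nb))
  }
  out
}

bf_ngldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  out <- matrix(0, ng, 27)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- lev[x, y, z]
    if (li == 0) next
    k <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (any(p < 1) || any(p > d)) next
      lj <- lev[p[1], p[2], p[3]]
      if (lj > 0 && abs(lj - li) <= alpha) k <- k + 1
    }
    out[li, k + 1] <- out[li, k + 1] + 1
  }
  out
}

rand_disc <- function(seed, dim = c(4, 4, 4), ng = 3, p_mask = 0.8) {
  set.seed(seed)
  lev <- array(sample(0:ng, prod(dim), replace = TRUE,
                      prob = c(1 - p_mask, rep(p_mask / ng, ng))), dim)
  if (sum(lev > 0) == 0) lev[1] <- 1L
  structure(list(levels = lev, ng = as.integer(ng),
                 scheme = "fixed_bin_number", spacing = c(1, 1, 1)),
            class = "DiscretizedVolume")
}
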