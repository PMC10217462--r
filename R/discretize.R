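# Fixed-bin-number grey-level discretization.

#' Discretize intensities within the mask (fixed bin number)
#'
#' Levels are \code{floor(ng * (x - min) / (max - min)) + 1}, capped at
#' \code{ng}; min/max are taken within the mask. A constant region maps to
#' level 1 everywhere. Voxels outside the mask are coded 0 (excluded).
#'
#' @param vol \linkS4class{RadVolume}.
#' @param mask \linkS4class{RadMask} on the same grid.
#' @param ng number of grey levels (>= 2).
#' @return A \code{DiscretizedVolume}: integer array of levels (0 outside
#'   the mask), with attributes \code{ng} and \code{scheme}.
#' @export
discretizeFBN <- function(vol, mask, ng = 32L) {
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("volume and mask grids differ")
  if (sum(mask@data) < 1) stop("empty mask")
  if (ng < 2) stop("ng must be >= 2")
  x <- vol@data
  inm <- mask@data == 1
  v <- x[inm]
  lev <- array(0L, dim(x))
  rng <- range(v)
  if (rng[2] > rng[1]) {
    l <- floor(ng * (v - rng[1]) / (rng[2] - rng[1])) + 1
    lev[inm] <- as.integer(pmin(l, ng))
  } else {
    lev[inm] <- 1L
  }
  structure(list(levels = lev, ng = as.integer(ng),
                 scheme = "fixed_bin_number", spacing = vol@spacing),
            class = "DiscretizedVolume")
}

# the 13 unique 3D direction offsets (one per +/- pair)
.offsets13 <- function() {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    if (!is.null(out) && any(apply(out, 1, function(r) all(r == -v)))) next
    out <- rbind(out, v)
  }
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' 3D grey-level co-occurrence matrices
#'
#' Symmetrized co-occurrence counts for the 13 unique 3D directions (or a
#' supplied subset), voxel pairs restricted to the mask.
#'
#' @param disc a \code{\link{discretizeFBN}} result.
#' @param offsets integer matrix of direction offsets (rows); default the
#'   13 unique 3D directions.
#' @return ng x ng x n_directions array of counts.
#' @export
glcm3d <- function(disc, offsets = .offsets13()) {
  stopifnot(inherits(disc, "DiscretizedVolume"))
  if (is.vector(offsets)) offsets <- matrix(as.integer(offsets), 1L)
  storage.mode(offsets) <- "integer"
  cpp_glcm(as.integer(disc$levels), dim(disc$levels), disc$ng, offsets)
}

#' 3D grey-level run-length matrices
#' @inheritParams glcm3d
#' @return ng x max_run x n_directions array of run counts.
#' @export
glrlm3d <- function(disc, offsets = .offsets13()) {
  stopifnot(inherits(disc, "DiscretizedVolume"))
  if (is.vector(offsets)) offsets <- matrix(as.integer(offsets), 1L)
  storage.mode(offsets) <- "integer"
  cpp_glrlm(as.integer(disc$levels), dim(disc$levels), disc$ng, offsets)
}

#' Grey-level zones (26-connectivity), with Chebyshev distance to the edge
#' @param disc a \code{\link{discretizeFBN}} result.
#' @param with_distance also compute each zone's minimum Chebyshev distance
#'   to the mask edge (for the distance-zone matrix).
#' @return matrix with columns \code{level}, \code{size}, \code{mindist}.
#' @export
greyLevelZones <- function(disc, with_distance = FALSE) {
  stopifnot(inherits(disc, "DiscretizedVolume"))
  dist <- NULL
  if (with_distance) {
    mask <- (disc$levels > 0L) + 0L
    dist <- cpp_cheb_dist(as.integer(mask), dim(disc$levels))
  }
  z <- cpp_zones(as.integer(disc$levels), dim(disc$levels), dist)
  colnames(z) <- c("level", "size", "mindist")
  z
}
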