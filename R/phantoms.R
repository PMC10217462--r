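# Seeded synthetic PET/CT phantom cohorts. Outcome signal is split across
# modalities by construction: a CT morphology latent m drives tumor shape
# irregularity, a PET texture latent t drives the correlation length of
# in-tumor uptake texture, and the binary label is sampled from a logistic
# model on (m, t).

#' Isotropic Gaussian random field (spectral synthesis)
#'
#' Zero-mean, unit-variance field with Gaussian autocorrelation
#' \eqn{\rho(r) = exp(-r^2 / (2 l^2))} (so \eqn{\rho(l) = exp(-1/2)}).
#'
#' @param shape integer(3) grid.
#' @param correlation_length l, in voxels (> 0).
#' @param seed RNG seed.
#' @return 3D array, standardized to mean 0 / sd 1.
#' @export
gaussianRandomField <- function(shape, correlation_length, seed = 1L) {
  stopifnot(correlation_length > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noise <- array(rnorm(prod(shape)), shape)
  f <- lapply(shape, function(n) {
    k <- seq_len(n) - 1
    ifelse(k <= n / 2, k, k - n) / n
  })
  K2 <- outer(outer(f[[1]]^2, f[[2]]^2, "+"), f[[3]]^2, "+")
  H <- exp(-(2 * pi)^2 * K2 * correlation_length^2 / 4)
  field <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) /
    prod(shape)
  (field - mean(field)) / stats::sd(field)
}

# real spherical harmonics of degree 2 and 3 on unit directions
.sh_basis <- function(ux, uy, uz) {
  cbind(ux * uy, uy * uz, ux * uz, ux^2 - uy^2, 3 * uz^2 - 1,
        uz * (5 * uz^2 - 3), ux * (5 * uz^2 - 1), uy * (5 * uz^2 - 1),
        uz * (ux^2 - uy^2), ux * uy * uz,
        ux * (ux^2 - 3 * uy^2), uy * (3 * ux^2 - uy^2))
}

#' Star-convex tumor mask with controllable irregularity
#'
#' A sphere of the given radius whose boundary radius is modulated along
#' each direction by a random combination of degree-2/3 spherical
#' harmonics with amplitude \code{m}; \code{m = 0} gives an exact sphere.
#'
#' @param grid integer(3) voxel grid.
#' @param radius sphere radius in voxels.
#' @param m irregularity amplitude (relative radius modulation, >= 0).
#' @param seed RNG seed for the harmonic coefficients.
#' @param center voxel coordinates of the blob centre (default grid mid).
#' @param spacing mm per voxel for the returned \linkS4class{RadMask}.
#' @return A \linkS4class{RadMask}.
#' @export
makeTumorMask <- function(grid, radius, m = 0, seed = 1L, center = NULL,
                          spacing = c(1, 1, 1)) {
  grid <- as.integer(grid)
  if (is.null(center)) center <- (grid + 1) / 2
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cf <- rnorm(12L)
  ax <- seq_len(grid[1]) - center[1]
  ay <- seq_len(grid[2]) - center[2]
  az <- seq_len(grid[3]) - center[3]
  DX <- array(ax, grid)
  DY <- array(rep(ay, each = grid[1]), grid)
  DZ <- array(rep(az, each = grid[1] * grid[2]), grid)
  r <- sqrt(DX^2 + DY^2 + DZ^2)
  r0 <- pmax(r, 1e-9)
  B <- .sh_basis(as.numeric(DX / r0), as.numeric(DY / r0),
                 as.numeric(DZ / r0))
  P <- as.numeric(B %*% cf)
  P <- (P - mean(P)) / stats::sd(P)
  P <- P / max(abs(P))  # m is the maximum relative radius modulation
  rad_dir <- radius * (1 + m * array(P, grid))
  rad_dir <- pmax(rad_dir, 1)
  if (max(rad_dir) > min(grid) / 2 - 1)
    stop("perturbed blob exits the grid; reduce radius or irregularity")
  mask <- (r <= rad_dir) + 0
  RadMask(mask, spacing = spacing)
}

#' Phantom cohort parameters
#'
#' Defaults define the package's reference synthetic study conditions:
#' 48^3 voxel grids at 2 mm spacing, tumor radii 8-14 mm, shape
#' irregularity up to 0.35 driven by the CT morphology latent m, PET
#' texture correlation lengths 1-4 voxels driven by the texture latent t,
#' additive Gaussian noise, and labels sampled from
#' \eqn{Bernoulli(plogis(b0 + bm (2m-1) + bt (2t-1)))} so the Bayes error
#' is controlled and both modalities carry complementary signal.
#'
#' @param n_patients cohort size.
#' @param grid integer(3), divisible by 8.
#' @param spacing mm per voxel.
#' @param radius_range_mm tumor radius range (uniform draw).
#' @param irregularity maximum relative shape irregularity (amplitude m).
#' @param pet_corr_range texture correlation length range, voxels.
#' @param noise_sd named c(ct=, pet=) additive noise sd.
#' @param beta named c(b0=, bm=, bt=) outcome coefficients.
#' @param min_per_class resample labels (up to 100 draws) until each class
#'   has at least this many patients.
#' @param seed master seed.
#' @return a \code{PhantomParams} list.
#' @export
phantomParams <- function(n_patients = 120L, grid = c(48L, 48L, 48L),
                          spacing = c(2, 2, 2),
                          radius_range_mm = c(8, 14), irregularity = 0.35,
                          pet_corr_range = c(1, 4),
                          noise_sd = c(ct = 0.03, pet = 0.05),
                          beta = c(b0 = 0, bm = 2, bt = 2),
                          min_per_class = 4L, seed = 1L) {
  grid <- as.integer(grid)
  if (any(grid %% 8L != 0L)) stop("grid must be divisible by 8")
  stopifnot(all(noise_sd >= 0), radius_range_mm[1] <= radius_range_mm[2])
  if (radius_range_mm[2] / min(spacing) * (1 + irregularity) >
      min(grid) / 2 - 1)
    stop("radius range does not fit inside the grid")
  structure(list(n_patients = as.integer(n_patients), grid = grid,
                 spacing = spacing, radius_range_mm = radius_range_mm,
                 irregularity = irregularity,
                 pet_corr_range = pet_corr_range, noise_sd = noise_sd,
                 beta = beta, min_per_class = as.integer(min_per_class),
                 seed = as.integer(seed)),
            class = "PhantomParams")
}

#' Generate a phantom cohort
#'
#' @param params \code{\link{phantomParams}}.
#' @return a \code{PhantomCohort}: list of records (\code{ct}, \code{pet},
#'   \code{mask}, \code{label}, \code{latents}, \code{id}) with the params
#'   attached as an attribute.
#' @export
generateCohort <- function(params = phantomParams()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  n <- params$n_patients
  m <- runif(n); tl <- runif(n)
  # labels from the logistic model, resampled if a class is near-empty
  pr <- stats::plogis(params$beta["b0"] + params$beta["bm"] * (2 * m - 1) +
                      params$beta["bt"] * (2 * tl - 1))
  lab <- NULL
  for (att in seq_len(100L)) {
    cand <- rbinom(n, 1, pr)
    if (min(sum(cand), n - sum(cand)) >=
        min(params$min_per_class, floor(n / 2))) {
      lab <- cand; break
    }
  }
  if (is.null(lab)) stop("class balance infeasible after 100 attempts")
  seeds <- sample.int(2^30, 4L * n)
  g <- params$grid
  records <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seeds[(4L * (i - 1L) + 1L):(4L * i)]
    rad_mm <- params$radius_range_mm[1] +
      runif(1) * diff(params$radius_range_mm)
    rad_vox <- rad_mm / min(params$spacing)
    mask <- makeTumorMask(g, rad_vox, m = m[i] * params$irregularity,
                          seed = s[1], spacing = params$spacing)
    bg1 <- gaussianRandomField(g, 8, seed = s[2])
    ct <- 0.35 + 0.08 * bg1 + 0.30 * mask@data +
      rnorm(prod(g), sd = params$noise_sd["ct"])
    ell <- params$pet_corr_range[1] +
      tl[i] * diff(params$pet_corr_range)
    tex <- gaussianRandomField(g, ell, seed = s[3])
    bg2 <- gaussianRandomField(g, 6, seed = s[4])
    pet <- 0.20 + 0.05 * bg2 +
      mask@data * (0.45 + 0.18 * tex) +
      rnorm(prod(g), sd = params$noise_sd["pet"])
    records[[i]] <- list(
      ct = RadVolume(array(ct, g), params$spacing, modality = "CT"),
      pet = RadVolume(array(pet, g), params$spacing, modality = "PET"),
      mask = mask,
      label = lab[i],
      latents = c(m = m[i], t = tl[i]),
      id = sprintf("P%03d", i))
  }
  structure(records, class = "PhantomCohort", params = params)
}
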