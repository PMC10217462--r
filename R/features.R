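# Full handcrafted feature vector: 79 first-order + 136 3D texture = 215.

#' Radiomics configuration
#' @param ng grey levels for fixed-bin-number discretization (default 32).
#' @param autocorr_max_voxels subsample cap for Moran/Geary.
#' @return a \code{RadiomicsConfig} list.
#' @export
radiomicsConfig <- function(ng = 32L, autocorr_max_voxels = 600L) {
  stopifnot(ng >= 2)
  structure(list(ng = as.integer(ng),
                 autocorr_max_voxels = as.integer(autocorr_max_voxels)),
            class = "RadiomicsConfig")
}

#' Canonical feature names (215, fixed order)
#'
#' Order: morphology (29), local intensity (2), intensity statistics (18),
#' intensity histogram (23), intensity-volume histogram (7), then 3D
#' texture: GLCM averaged/merged (25 each), GLRLM averaged/merged (16
#' each), GLSZM (16), GLDZM (16), NGTDM (5), NGLDM (17).
#'
#' @return character vector of length 215.
#' @export
featureNames <- function() {
  c(.morph_names,
    c("loc_peak_local", "loc_peak_global"),
    .is_names,
    .ih_names,
    .ivh_names,
    paste0("glcm_averaged_", .glcm_feature_names),
    paste0("glcm_merged_", .glcm_feature_names),
    paste0("glrlm_averaged_", .rl_feature_names),
    paste0("glrlm_merged_", .rl_feature_names),
    paste0("glszm_", {
      nm <- .rl_feature_names
      ren <- c(sre = "sze", lre = "lze", srlge = "szlge", srhge = "szhge",
               lrlge = "lzlge", lrhge = "lzhge", rlnu = "zsnu",
               rlnu_norm = "zsnu_norm", run_pct = "zone_pct",
               rl_var = "zs_var", run_entropy = "zs_entropy")
      hit <- nm %in% names(ren); nm[hit] <- ren[nm[hit]]; nm
    }),
    paste0("gldzm_", {
      nm <- .rl_feature_names
      ren <- c(sre = "sde", lre = "lde", srlge = "sdlge", srhge = "sdhge",
               lrlge = "ldlge", lrhge = "ldhge", rlnu = "zdnu",
               rlnu_norm = "zdnu_norm", run_pct = "zone_pct",
               rl_var = "zd_var", run_entropy = "zd_entropy")
      hit <- nm %in% names(ren); nm[hit] <- ren[nm[hit]]; nm
    }),
    paste0("ngtdm_", .ngtdm_names),
    paste0("ngldm_", .ngldm_names))
}

#' Extract the 215-feature handcrafted vector from one volume/mask pair
#'
#' Deterministic; undefined features (IBSI degenerate cases) are returned
#' as \code{NA} and imputed later, inside cross-validation.
#'
#' @param vol \linkS4class{RadVolume} (preprocessed, cropped).
#' @param mask \linkS4class{RadMask} on the same grid.
#' @param config \code{\link{radiomicsConfig}}.
#' @param cache optional \code{\link{featureCache}} (reused across the
#'   flavours of one patient).
#' @return named numeric vector of length 215 in canonical order.
#' @export
extractFeatures <- function(vol, mask, config = radiomicsConfig(),
                            cache = NULL) {
  if (sum(mask@data) < 1) stop("empty mask")
  if (is.null(cache)) cache <- featureCache(mask, config)
  disc <- discretizeFBN(vol, mask, config$ng)
  out <- c(
    morphologyFeatures(mask, vol, config$autocorr_max_voxels,
                       geom = cache$geom),
    localIntensityPeaks(vol, mask, cache = cache$peaks),
    intensityStats(vol, mask),
    histogramFeatures(disc),
    ivhFeatures(vol, mask),
    textureFeatures("GLCM", disc, "averaged"),
    textureFeatures("GLCM", disc, "merged"),
    textureFeatures("GLRLM", disc, "averaged"),
    textureFeatures("GLRLM", disc, "merged"),
    textureFeatures("GLSZM", disc),
    textureFeatures("GLDZM", disc),
    textureFeatures("NGTDM", disc),
    textureFeatures("NGLDM", disc))
  stopifnot(identical(names(out), featureNames()))
  out
}

#' Extract features for every flavour of a FlavourSet
#' @param fs \linkS4class{FlavourSet}.
#' @param mask \linkS4class{RadMask} on the shared grid.
#' @param config \code{\link{radiomicsConfig}}.
#' @return matrix features x flavours (215 x 17 with the default registry).
#' @export
extractFlavourFeatures <- function(fs, mask, config = radiomicsConfig()) {
  cache <- featureCache(mask, config)
  vapply(fs@volumes, function(v) extractFeatures(v, mask, config, cache),
         numeric(215L))
}

#' Per-patient cache of mask-dependent quantities
#' @param mask \linkS4class{RadMask}.
#' @param config \code{\link{radiomicsConfig}}.
#' @return list with the \code{\link{maskGeometry}} and the peak
#'   neighborhood gather table.
#' @export
featureCache <- function(mask, config = radiomicsConfig()) {
  list(geom = maskGeometry(mask, config$autocorr_max_voxels),
       peaks = .peak_cache(mask))
}
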