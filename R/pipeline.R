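# Cohort-level convenience pipeline: phantom records -> preprocessed pairs
# -> 17-flavour sets -> handcrafted feature tensor.

#' Preprocess one phantom record
#'
#' Normalizes both modalities to [0,1], optionally applies slice-wise
#' adaptive histogram equalization, and applies the centroid-centred
#' fixed-size crop (defaulting to the full grid extent, which recentres
#' the tumor).
#'
#' @param record one element of a \code{\link{generateCohort}} result.
#' @param config \code{\link{preprocessConfig}}; when \code{NULL} a config
#'   with a crop matching the record's grid and no enhancement is used.
#' @return list \code{ct}, \code{pet}, \code{mask}.
#' @export
processPhantom <- function(record, config = NULL) {
  if (is.null(config)) {
    g <- dim(record$ct@data)
    config <- preprocessConfig(crop_size_mm = g * record$ct@spacing,
                               target_spacing = record$ct@spacing,
                               enhance = "none")
  }
  preprocessPair(record$ct, record$pet, record$mask, config)
}

#' Build flavour sets for a whole cohort
#'
#' @param cohort \code{\link{generateCohort}} result.
#' @param registry \code{\link{fusionRegistry}} subset to apply.
#' @param config optional \code{\link{preprocessConfig}}.
#' @param seed base seed for per-patient dictionary training.
#' @param sr_params SR overrides passed to \code{\link{buildFlavourSet}}.
#' @param progress print a dot per patient.
#' @return list with \code{flavour_sets} (per patient
#'   \linkS4class{FlavourSet}) and \code{masks} (cropped
#'   \linkS4class{RadMask}s).
#' @export
cohortFlavourSets <- function(cohort, registry = fusionRegistry(),
                              config = NULL, seed = 1L,
                              sr_params = list(), progress = FALSE) {
  fsets <- vector("list", length(cohort))
  masks <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    pp <- processPhantom(cohort[[i]], config)
    fsets[[i]] <- buildFlavourSet(pp$ct, pp$pet, registry,
                                  seed = seed + i, sr_params = sr_params)
    masks[[i]] <- pp$mask
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  list(flavour_sets = fsets, masks = masks)
}

#' Handcrafted-feature tensor for a cohort
#'
#' Extracts the 215-feature vector from every flavour of every patient and
#' assembles the patients x features x flavours tensor.
#'
#' @param flavoured result of \code{\link{cohortFlavourSets}}.
#' @param cohort the generating \code{\link{generateCohort}} result
#'   (labels, latents, ids).
#' @param config \code{\link{radiomicsConfig}}.
#' @return A \linkS4class{FlavourTensor}.
#' @export
cohortRadiomicsTensor <- function(flavoured, cohort,
                                  config = radiomicsConfig()) {
  flavs <- flavourNames(flavoured$flavour_sets[[1]])
  ids <- vapply(cohort, function(r) r$id, "")
  labels <- vapply(cohort, function(r) r$label, 0L)
  latents <- t(vapply(cohort, function(r) r$latents, numeric(2)))
  perPat <- lapply(seq_along(cohort), function(i)
    extractFlavourFeatures(flavoured$flavour_sets[[i]],
                           flavoured$masks[[i]], config))
  tables <- lapply(flavs, function(fl) {
    M <- vapply(perPat, function(m) m[, fl], numeric(215L))
    colnames(M) <- ids
    M
  })
  names(tables) <- flavs
  assembleTensor(tables, labels, ids, latents)
}
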