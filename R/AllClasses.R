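#' @import methods
#' @importFrom stats var sd median quantile prcomp rnorm runif rbinom
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib tensorRad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' RadVolume: a 3D scalar image with voxel geometry
#'
#' Container for one 3D image volume (CT in Hounsfield units, PET in
#' normalized uptake, or a fused image) together with its voxel spacing and
#' physical origin. Physical coordinates follow
#' \code{origin + (index - 1) * spacing} (indices 1-based in R; the first
#' voxel centre sits at \code{origin}).
#'
#' @slot data 3D numeric array, all values finite.
#' @slot spacing numeric(3), mm per voxel along each axis, all > 0.
#' @slot origin numeric(3), mm offset of the first voxel centre.
#' @slot modality one of \code{"CT"}, \code{"PET"}, \code{"FUSED"}.
#' @export
setClass("RadVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 modality = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), modality = "FUSED"))

setValidity("RadVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must have rank exactly 3")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data contains non-finite values")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (!object@modality %in% c("CT", "PET", "FUSED"))
    msg <- c(msg, "modality must be CT, PET or FUSED")
  if (length(msg)) msg else TRUE
})

#' RadMask: a binary tumor mask on the grid of its paired RadVolume
#'
#' @slot data 3D array with values in \{0,1\}; at least one foreground voxel.
#' @slot spacing,origin as in \linkS4class{RadVolume}.
#' @export
setClass("RadMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("RadMask", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "mask must have rank exactly 3")
  if (!all(object@data %in% c(0, 1)))
    msg <- c(msg, "mask values must be 0 or 1")
  if (sum(object@data) < 1)
    msg <- c(msg, "mask has no foreground voxel")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' FlavourSet: the 17 per-patient image flavours
#'
#' Named list of \linkS4class{RadVolume}s: \code{CT}, \code{PET} and one per
#' fusion method. All volumes share one grid.
#'
#' @slot volumes named list of RadVolume.
#' @export
setClass("FlavourSet", representation(volumes = "list"))

setValidity("FlavourSet", function(object) {
  v <- object@volumes
  if (!length(v)) return("empty flavour set")
  if (is.null(names(v)) || any(!nzchar(names(v))) || anyDuplicated(names(v)))
    return("flavours must have unique non-empty names")
  if (!all(vapply(v, is, TRUE, "RadVolume")))
    return("all entries must be RadVolume")
  d <- dim(v[[1]]@data)
  for (x in v) if (!identical(dim(x@data), d))
    return("all flavours must share one grid")
  TRUE
})

#' FlavourTensor: patients x features x flavours
#'
#' A \linkS4class{SummarizedExperiment} with one assay per flavour, each
#' assay a features x patients matrix (rows = base features, columns =
#' patients). \code{colData} carries the binary outcome \code{label} and,
#' for phantom cohorts, the generating latents. Undefined features (IBSI
#' degenerate cases) are stored as \code{NA} and imputed inside
#' cross-validation, never here.
#'
#' @export
setClass("FlavourTensor", contains = "SummarizedExperiment")

setValidity("FlavourTensor", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!length(a)) return("no flavour assays")
  if (is.null(SummarizedExperiment::assayNames(object)))
    return("assays must be named by flavour")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a binary 'label' column")
  lab <- SummarizedExperiment::colData(object)$label
  if (!all(lab %in% c(0, 1))) return("label must be 0/1")
  TRUE
})

setMethod("show", "RadVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("RadVolume [%s]: %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              object@modality, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "RadMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("RadMask: %d x %d x %d voxels, %d foreground, spacing %s mm\n",
              d[1], d[2], d[3], sum(object@data),
              paste(format(object@spacing, digits = 3), collapse = " x ")))
})

setMethod("show", "FlavourSet", function(object) {
  cat(sprintf("FlavourSet with %d flavours: %s\n", length(object@volumes),
              paste(names(object@volumes), collapse = ", ")))
})

#' Construct a RadVolume
#' @param data 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical origin in mm.
#' @param modality "CT", "PET" or "FUSED".
#' @return A \linkS4class{RadVolume}.
#' @export
RadVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      modality = "FUSED") {
  new("RadVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

#' Construct a RadMask
#' @param data 3D array of 0/1.
#' @param spacing,origin voxel geometry, as in \code{\link{RadVolume}}.
#' @return A \linkS4class{RadMask}.
#' @export
RadMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("RadMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a FlavourSet
#' @param volumes named list of \linkS4class{RadVolume}s sharing one grid.
#' @return A \linkS4class{FlavourSet}.
#' @export
FlavourSet <- function(volumes) new("FlavourSet", volumes = volumes)

#' @rdname accessors
#' @param x a FlavourSet or FlavourTensor.
#' @return \code{flavourNames}: character vector of flavour names.
#' @export
setGeneric("flavourNames", function(x) standardGeneric("flavourNames"))

#' Accessors for flavour containers
#' @name accessors
#' @aliases flavourNames,FlavourSet-method
#' @export
setMethod("flavourNames", "FlavourSet", function(x) names(x@volumes))

#' @rdname accessors
#' @export
setMethod("flavourNames", "FlavourTensor",
          function(x) SummarizedExperiment::assayNames(x))

#' @rdname accessors
#' @param name flavour name.
#' @return \code{getFlavour}: the named \linkS4class{RadVolume}.
#' @export
setGeneric("getFlavour", function(x, name) standardGeneric("getFlavour"))

#' @rdname accessors
#' @export
setMethod("getFlavour", "FlavourSet", function(x, name) {
  if (!name %in% names(x@volumes))
    stop("unknown flavour: ", name)
  x@volumes[[name]]
})

#' Voxel data of a volume or mask
#' @param x RadVolume or RadMask.
#' @return the 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "RadVolume", function(x) x@data)

#' @rdname voxels
#' @export
setMethod("voxels", "RadMask", function(x) x@data)

#' Voxel spacing in mm
#' @param x RadVolume or RadMask.
#' @return numeric(3).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "RadVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "RadMask", function(x) x@spacing)
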