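#' Preprocessing configuration
#'
#' Settings for intensity normalization, enhancement and the fixed-size
#' physical bounding box applied around the tumor before feature extraction.
#'
#' @param crop_size_mm numeric(3), physical edge lengths of the bounding box
#'   in mm. Default \code{c(224, 224, 224)}.
#' @param target_spacing numeric(3), mm; the reference grid spacing after
#'   resampling. Default \code{c(1, 1, 1.4)} (in-plane 1 mm, through-plane
#'   1.4 mm), which makes the default crop a 224 x 224 x 160 voxel grid.
#' @param normalize_mode \code{"minmax01"} or \code{"hu_window"}.
#' @param hu_window numeric(2) \code{c(lower, upper)}, required for
#'   \code{"hu_window"}.
#' @param enhance \code{"none"} or \code{"adaptive_hist_eq"} (slice-wise
#'   contrast-limited adaptive histogram equalization on axial slices).
#' @return A \code{PreprocessConfig} list.
#' @export
preprocessConfig <- function(crop_size_mm = c(224, 224, 224),
                             target_spacing = c(1, 1, 1.4),
                             normalize_mode = c("minmax01", "hu_window"),
                             hu_window = NULL,
                             enhance = c("adaptive_hist_eq", "none")) {
  normalize_mode <- match.arg(normalize_mode)
  enhance <- match.arg(enhance)
  crop_size_mm <- rep_len(as.numeric(crop_size_mm), 3L)
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  stopifnot(all(crop_size_mm > 0), all(target_spacing > 0))
  if (normalize_mode == "hu_window") {
    if (is.null(hu_window) || length(hu_window) != 2L ||
        hu_window[1] >= hu_window[2])
      stop("hu_window must be c(lower, upper) with lower < upper")
  }
  structure(list(crop_size_mm = crop_size_mm,
                 target_spacing = target_spacing,
                 normalize_mode = normalize_mode,
                 hu_window = hu_window, enhance = enhance),
            class = "PreprocessConfig")
}

#' Read a 3D volume from NIfTI
#'
#' @param path path to a \code{.nii}/\code{.nii.gz} file.
#' @param modality "CT", "PET" or "FUSED".
#' @return A \linkS4class{RadVolume} carrying spacing and origin from the
#'   header.
#' @export
readVolume <- function(path, modality = "FUSED") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3D image: ", path)
  dat <- array(as.numeric(img), dim = d)
  if (!all(is.finite(dat))) stop("non-finite voxels in: ", path)
  sp <- attr(img, "pixdim")[seq_len(3)]
  orig <- tryCatch(RNifti::xform(img)[seq_len(3), 4],
                   error = function(e) c(0, 0, 0))
  RadVolume(dat, spacing = sp, origin = as.numeric(orig), modality = modality)
}

#' Write a RadVolume (or RadMask) to NIfTI
#'
#' @param vol a \linkS4class{RadVolume} or \linkS4class{RadMask}.
#' @param path output path (\code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  sp <- vol@spacing
  aff <- diag(c(sp, 1))
  aff[seq_len(3), 4] <- vol@origin
  img <- RNifti::asNifti(vol@data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a mask from NIfTI
#' @param path NIfTI path; voxels are binarized at 0.5.
#' @return A \linkS4class{RadMask}.
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  RadMask((v@data > 0.5) + 0, spacing = v@spacing, origin = v@origin)
}

#' Read binary outcome labels
#'
#' @param path CSV file with header \code{patient_id,label}.
#' @return data.frame with character \code{patient_id} and integer
#'   \code{label} in \{0,1\}; ids unique.
#' @export
readOutcomeLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "label") %in% names(df)))
    stop("labels file must have columns patient_id,label")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient ids")
  if (!all(df$label %in% c(0, 1))) stop("labels must be 0/1")
  df$patient_id <- as.character(df$patient_id)
  df$label <- as.integer(df$label)
  df
}

#' Resample a volume onto the grid of a reference volume
#'
#' Pulls values from \code{vol} at the physical voxel centres of
#' \code{reference}, by trilinear (images) or nearest-neighbour (masks)
#' interpolation. Registration proper is assumed done upstream; this is a
#' grid-alignment step only. Points outside \code{vol}'s physical extent
#' take the volume minimum.
#'
#' @param vol RadVolume (or RadMask with \code{interpolation = "nearest"}).
#' @param reference RadVolume defining the output grid.
#' @param interpolation "trilinear" or "nearest".
#' @return RadVolume (or RadMask if \code{vol} is a RadMask) on the
#'   reference grid.
#' @export
resampleToGrid <- function(vol, reference,
                           interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  isMask <- is(vol, "RadMask")
  if (isMask) interpolation <- "nearest"
  src <- vol@data
  sd3 <- dim(src)
  rd <- dim(reference@data)
  # physical coordinates of reference voxel centres, per axis
  ax <- lapply(1:3, function(k)
    reference@origin[k] + (seq_len(rd[k]) - 1) * reference@spacing[k])
  # continuous source index per axis (1-based)
  si <- lapply(1:3, function(k) (ax[[k]] - vol@origin[k]) / vol@spacing[k] + 1)
  if (max(si[[1]]) < 1 || min(si[[1]]) > sd3[1] ||
      max(si[[2]]) < 1 || min(si[[2]]) > sd3[2] ||
      max(si[[3]]) < 1 || min(si[[3]]) > sd3[3])
    stop("volumes do not overlap in physical space")
  G <- expand.grid(x = si[[1]], y = si[[2]], z = si[[3]])
  fill <- min(src)
  if (interpolation == "nearest") {
    ix <- round(G$x); iy <- round(G$y); iz <- round(G$z)
    ok <- ix >= 1 & ix <= sd3[1] & iy >= 1 & iy <= sd3[2] & iz >= 1 & iz <= sd3[3]
    out <- rep(if (isMask) 0 else fill, nrow(G))
    out[ok] <- src[cbind(ix[ok], iy[ok], iz[ok])]
  } else {
    x0 <- pmin(pmax(floor(G$x), 1), sd3[1]); x1 <- pmin(x0 + 1, sd3[1])
    y0 <- pmin(pmax(floor(G$y), 1), sd3[2]); y1 <- pmin(y0 + 1, sd3[2])
    z0 <- pmin(pmax(floor(G$z), 1), sd3[3]); z1 <- pmin(z0 + 1, sd3[3])
    fx <- pmin(pmax(G$x - x0, 0), 1); fy <- pmin(pmax(G$y - y0, 0), 1)
    fz <- pmin(pmax(G$z - z0, 0), 1)
    v000 <- src[cbind(x0, y0, z0)]; v100 <- src[cbind(x1, y0, z0)]
    v010 <- src[cbind(x0, y1, z0)]; v110 <- src[cbind(x1, y1, z0)]
    v001 <- src[cbind(x0, y0, z1)]; v101 <- src[cbind(x1, y0, z1)]
    v011 <- src[cbind(x0, y1, z1)]; v111 <- src[cbind(x1, y1, z1)]
    out <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                       fy * ((1 - fx) * v010 + fx * v110)) +
           fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
                 fy * ((1 - fx) * v011 + fx * v111))
    outside <- G$x < 1 | G$x > sd3[1] | G$y < 1 | G$y > sd3[2] |
               G$z < 1 | G$z > sd3[3]
    out[outside] <- fill
  }
  arr <- array(out, dim = rd)
  if (isMask)
    RadMask(arr, spacing = reference@spacing, origin = reference@origin)
  else
    RadVolume(arr, spacing = reference@spacing, origin = reference@origin,
              modality = vol@modality)
}

#' Normalize volume intensities
#'
#' \code{minmax01}: linear map of the data range onto [0,1]; a constant
#' volume maps to all zeros. \code{hu_window}: values are clipped to the
#' window, then scaled linearly so the window maps onto [0,1].
#'
#' @param vol RadVolume with finite data.
#' @param config \code{\link{preprocessConfig}}.
#' @return RadVolume with values in [0,1].
#' @export
normalizeIntensity <- function(vol, config = preprocessConfig()) {
  x <- vol@data
  if (config$normalize_mode == "hu_window") {
    w <- config$hu_window
    x <- pmin(pmax(x, w[1]), w[2])
    x <- (x - w[1]) / (w[2] - w[1])
  } else {
    r <- range(x)
    x <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else array(0, dim(x))
  }
  RadVolume(array(x, dim(vol@data)), vol@spacing, vol@origin, vol@modality)
}

#' Contrast enhancement
#'
#' Slice-wise contrast-limited adaptive histogram equalization (CLAHE) on
#' axial slices, or the identity. Input must already be normalized to [0,1].
#'
#' @param vol RadVolume with values in [0,1].
#' @param config \code{\link{preprocessConfig}}.
#' @return RadVolume with values in [0,1].
#' @export
enhanceVolume <- function(vol, config = preprocessConfig()) {
  x <- vol@data
  if (min(x) < 0 || max(x) > 1)
    stop("enhanceVolume expects values in [0,1]; run normalizeIntensity first")
  if (config$enhance == "none") return(vol)
  d <- dim(x)
  nx <- max(2L, min(8L, d[1] %/% 8L))
  ny <- max(2L, min(8L, d[2] %/% 8L))
  for (k in seq_len(d[3])) {
    sl <- x[, , k]
    if (diff(range(sl)) < 1e-12) next  # constant slice stays constant
    eq <- EBImage::clahe(sl, nx = nx, ny = ny, bins = 256, limit = 2)
    x[, , k] <- pmin(pmax(as.numeric(eq), 0), 1)
  }
  RadVolume(array(x, d), vol@spacing, vol@origin, vol@modality)
}

#' Crop a fixed-size physical bounding box around the tumor
#'
#' The box is centred on the mask centroid and has physical edge lengths
#' \code{config$crop_size_mm}; the voxel count per axis is
#' \code{round(crop_size_mm / spacing)}. Regions outside the image are
#' padded with the volume minimum (the mask with 0).
#'
#' @param vol RadVolume.
#' @param mask RadMask on the same grid.
#' @param config \code{\link{preprocessConfig}}.
#' @return list with elements \code{volume} and \code{mask}.
#' @export
cropBoundingBox <- function(vol, mask, config = preprocessConfig()) {
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("volume and mask grids differ")
  if (sum(mask@data) < 1) stop("empty mask")
  d <- dim(vol@data)
  n <- pmax(1L, as.integer(round(config$crop_size_mm / vol@spacing)))
  idx <- which(mask@data == 1, arr.ind = TRUE)
  centroid <- colMeans(idx)
  first <- as.integer(round(centroid - (n - 1) / 2))
  fill <- min(vol@data)
  outV <- array(fill, n)
  outM <- array(0, n)
  # overlap of requested box with the image
  lo <- pmax(first, 1L)
  hi <- pmin(first + n - 1L, d)
  if (all(lo <= hi)) {
    tlo <- lo - first + 1L
    thi <- hi - first + 1L
    outV[tlo[1]:thi[1], tlo[2]:thi[2], tlo[3]:thi[3]] <-
      vol@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    outM[tlo[1]:thi[1], tlo[2]:thi[2], tlo[3]:thi[3]] <-
      mask@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  }
  neworig <- vol@origin + (first - 1) * vol@spacing
  list(volume = RadVolume(outV, vol@spacing, neworig, vol@modality),
       mask = RadMask(outM, vol@spacing, neworig))
}

#' Full preprocessing of one co-registered CT/PET pair
#'
#' Resamples PET (and the mask, if it lives on the PET grid) onto the CT
#' grid, normalizes both modalities, optionally enhances, and crops the
#' physical bounding box around the tumor.
#'
#' @param ct,pet RadVolume inputs (assumed co-registered).
#' @param mask RadMask on the CT grid.
#' @param config \code{\link{preprocessConfig}}.
#' @return list \code{ct}, \code{pet}, \code{mask}, all cropped and in [0,1].
#' @export
preprocessPair <- function(ct, pet, mask, config = preprocessConfig()) {
  if (!identical(dim(pet@data), dim(ct@data)) ||
      any(abs(pet@spacing - ct@spacing) > 1e-9))
    pet <- resampleToGrid(pet, ct, "trilinear")
  ctN <- enhanceVolume(normalizeIntensity(ct, config), config)
  petCfg <- config; petCfg$normalize_mode <- "minmax01"
  petN <- enhanceVolume(normalizeIntensity(pet, petCfg), petCfg)
  cct <- cropBoundingBox(ctN, mask, config)
  cpt <- cropBoundingBox(petN, mask, config)
  list(ct = cct$volume, pet = cpt$volume, mask = cct$mask)
}
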