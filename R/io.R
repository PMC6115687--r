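# Formats and reproducibility plumbing: NIfTI / multi-page TIFF / MetaImage
# volume I/O, orientation-field serialization, legacy-VTK activation-map
# export, run manifests.

.niftiSpacing <- function(img) {
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("volume header lacks voxel-size (spacing) metadata")
  pd
}

#' Read a 3D volume from NIfTI, multi-page TIFF or MetaImage
#'
#' Voxel size is taken from the header (NIfTI, MetaImage) and must be
#' isotropic; for TIFF, which stores no 3D spacing, \code{spacingMm} is
#' required. Anisotropic headers are an error unless
#' \code{allowAnisotropic} (the structure-tensor scales assume isotropic
#' voxels); then the mean spacing is used with a warning.
#'
#' @param path File path (.nii/.nii.gz, .tif/.tiff, .mhd).
#' @param type "image" or "label" (label volumes are rounded to integers).
#' @param spacingMm Voxel size in mm, required for TIFF.
#' @param dictionary Label dictionary to attach to a label volume.
#' @param allowAnisotropic Accept anisotropic headers (resampled-elsewhere
#'   escape hatch).
#' @return An [ImageVolume-class] or [LabelVolume-class].
#' @export
readVolume <- function(path, type = c("image", "label"), spacingMm = NULL,
                       dictionary = defaultLabelDictionary(),
                       allowAnisotropic = FALSE) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii", "hdr")) {
    img <- RNifti::readNifti(path)
    sp <- .niftiSpacing(img)
    arr <- array(as.vector(img), dim = dim(img)[1:3])
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(spacingMm))
      stop("TIFF stores no 3D voxel size: pass spacingMm explicitly")
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    d <- dim(pages[[1]])
    # readTIFF returns row-major (y, x) matrices; transpose to (x, y)
    arr <- array(0, dim = c(d[2], d[1], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    sp <- rep(spacingMm, 3)
  } else if (ext == "mhd") {
    vol <- .readMetaImage(path)
    arr <- vol$data
    sp <- vol$spacing
  } else stop(sprintf("unsupported volume format '.%s'", ext))
  if (max(sp) - min(sp) > 1e-6 * mean(sp)) {
    if (!allowAnisotropic)
      stop(sprintf(paste0("anisotropic voxels (%s mm): resample to isotropic ",
                          "first or pass allowAnisotropic = TRUE"),
                   paste(signif(sp, 4), collapse = " x ")))
    warning("anisotropic voxels; using the mean spacing")
  }
  spacing <- mean(sp)
  if (type == "label")
    new("LabelVolume", data = array(as.integer(round(arr)), dim = dim(arr)),
        spacing = spacing, dictionary = dictionary)
  else new("ImageVolume", data = arr, spacing = spacing)
}

#' Write a 3D volume to NIfTI, multi-page TIFF or MetaImage
#'
#' @param vol An [ImageVolume-class] or [LabelVolume-class].
#' @param path Output path; format chosen by extension.
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  arr <- voxelData(vol)
  sp <- spacing(vol)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(sp, 3)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    rng <- range(arr)
    if (rng[1] < 0 || rng[2] > 1)
      stop("TIFF output expects intensities in [0, 1]; rescale first")
    pages <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "mhd") {
    .writeMetaImage(arr, sp, path)
  } else stop(sprintf("unsupported volume format '.%s'", ext))
  invisible(path)
}

.readMetaImage <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get <- function(k) vals[match(k, keys)]
  if (is.na(get("ElementSpacing")) && is.na(get("ElementSize")))
    stop("MetaImage header lacks spacing metadata (ElementSpacing)")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(
    if (!is.na(get("ElementSpacing"))) get("ElementSpacing") else get("ElementSize"),
    "\\s+")[[1]])
  etype <- get("ElementType")
  raw <- file.path(dirname(path), get("ElementDataFile"))
  size <- switch(etype, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                 MET_USHORT = 2L, MET_UCHAR = 1L, MET_INT = 4L,
                 stop(sprintf("unsupported MetaImage ElementType '%s'", etype)))
  what <- if (etype %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  con <- file(raw, "rb")
  on.exit(close(con))
  v <- readBin(con, what, n = prod(dims), size = size,
               signed = !(etype %in% c("MET_UCHAR", "MET_USHORT")) || size > 2)
  list(data = array(as.numeric(v), dim = dims), spacing = sp)
}

.writeMetaImage <- function(arr, spacingMm, path) {
  rawName <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(arr), collapse = " ")),
           paste("ElementSpacing =", paste(rep(spacingMm, 3), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", rawName))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawName), "wb")
  on.exit(close(con))
  writeBin(as.double(as.vector(arr)), con, size = 8L)
  invisible(path)
}

#' Write / read an orientation field as 4-component NIfTI
#'
#' Components 1..3 are the direction vector, component 4 the coherence.
#'
#' @param field An [OrientationField-class].
#' @param path Output .nii path.
#' @return The path (write) / an [OrientationField-class] (read).
#' @export
writeOrientation <- function(field, path) {
  stopifnot(is(field, "OrientationField"))
  d <- dim(field@coherence)
  arr <- array(0, dim = c(d, 4L))
  arr[, , , 1:3] <- field@vectors
  arr[, , , 4] <- field@coherence
  img <- RNifti::asNifti(arr, pixdim = rep(field@spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeOrientation
#' @export
readOrientation <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- .niftiSpacing(img)
  arr <- array(as.vector(img), dim = dim(img))
  new("OrientationField", vectors = arr[, , , 1:3, drop = FALSE],
      coherence = arr[, , , 4], spacing = mean(sp))
}

#' Export an activation map to legacy ASCII VTK
#'
#' Writes a STRUCTURED_POINTS dataset over the full grid with point
#' arrays \code{activation_time} (ms; -1 where not activated or inert),
#' \code{activated} (0/1 mask) and \code{isochrone_band}.
#'
#' @param map An [ActivationMap-class].
#' @param model The [TissueModel-class].
#' @param path Output .vtk path.
#' @param beat Beat number.
#' @param isochroneMs Isochrone band width in ms.
#' @return The path, invisibly.
#' @export
writeVtkActivation <- function(map, model, path, beat = 1, isochroneMs = 5) {
  stopifnot(is(map, "ActivationMap"), is(model, "TissueModel"))
  d <- model@dims
  h <- model@spacing
  tAct <- map@times[, beat]
  band <- isochrones(map, isochroneMs, beat)
  full <- rep(-1, prod(d)); fullMask <- rep(0L, prod(d)); fullBand <- rep(-1L, prod(d))
  act <- !is.nan(tAct)
  full[model@activeIndex[act]] <- tAct[act]
  fullMask[model@activeIndex[act]] <- 1L
  fullBand[model@activeIndex[act]] <- band[act]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "activation map", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN 0 0 0"),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS activation_time float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(formatC(full, format = "g"), collapse = " "), con)
  writeLines(c("SCALARS activated int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(fullMask, collapse = " "), con)
  writeLines(c("SCALARS isochrone_band int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(fullBand, collapse = " "), con)
  invisible(path)
}

#' Write a label dictionary as a JSON sidecar
#' @param dictionary Named integer vector.
#' @param path Output .json path.
#' @return The path, invisibly.
#' @export
writeLabelDictionary <- function(dictionary, path) {
  jsonlite::write_json(as.list(dictionary), path, auto_unbox = TRUE)
  invisible(path)
}

# stable content hash for cache keys and manifests
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run manifest
#'
#' A reproducibility record: configuration snapshot, stage content
#' digests, package version, seed registry and timestamps.
#'
#' @param config The pipeline configuration list.
#' @param stageHashes Named character vector of stage digests.
#' @param seed Integer seed in force.
#' @param path Optional path to write the manifest JSON.
#' @return The manifest list, invisibly if written.
#' @export
runManifest <- function(config, stageHashes = character(), seed = NA_integer_,
                        path = NULL) {
  man <- list(package = "atriasim",
              version = as.character(utils::packageVersion("atriasim")),
              seed = seed, configHash = .hashObject(config),
              config = config, stageHashes = as.list(stageHashes),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(man))
  }
  man
}
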