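# Generics, accessors and show methods for the core containers.

#' Voxel spacing of a gridded object
#' @param x A gridded object (ImageVolume, LabelVolume, OrientationField,
#'   TensorField or TissueModel).
#' @return Isotropic voxel size in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname spacing
setMethod("spacing", "LabelVolume", function(x) x@spacing)
#' @rdname spacing
setMethod("spacing", "OrientationField", function(x) x@spacing)
#' @rdname spacing
setMethod("spacing", "TensorField", function(x) x@spacing)
#' @rdname spacing
setMethod("spacing", "TissueModel", function(x) x@spacing)

#' Underlying voxel array
#' @param x An ImageVolume or LabelVolume.
#' @return The 3D array of intensities or label codes.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname voxelData
setMethod("voxelData", "ImageVolume", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "LabelVolume", function(x) x@data)

#' Label dictionary of a label volume or tissue model
#' @param x A LabelVolume or TissueModel.
#' @return Named integer vector mapping region names to label codes.
#' @export
setGeneric("dictionary", function(x) standardGeneric("dictionary"))
#' @rdname dictionary
setMethod("dictionary", "LabelVolume", function(x) x@dictionary)
#' @rdname dictionary
setMethod("dictionary", "TissueModel", function(x) x@dictionary)

#' Orientation vectors and coherence
#' @param x An OrientationField.
#' @return \code{orientationVectors}: the (nx, ny, nz, 3) array of unit
#'   direction vectors; \code{coherence}: the 3D coherence array.
#' @export
setGeneric("orientationVectors", function(x) standardGeneric("orientationVectors"))
#' @rdname orientationVectors
setMethod("orientationVectors", "OrientationField", function(x) x@vectors)

#' @rdname orientationVectors
#' @export
setGeneric("coherence", function(x) standardGeneric("coherence"))
#' @rdname orientationVectors
setMethod("coherence", "OrientationField", function(x) x@coherence)

#' Tensor components of a structure-tensor field
#' @param x A TensorField.
#' @return 4D array (nx, ny, nz, 6): Jxx, Jyy, Jzz, Jxy, Jxz, Jyz.
#' @export
setGeneric("tensorComponents", function(x) standardGeneric("tensorComponents"))
#' @rdname tensorComponents
setMethod("tensorComponents", "TensorField", function(x) x@comps)

#' Active-node bookkeeping of a tissue model
#' @param x A TissueModel.
#' @return \code{activeIndex}: 1-based linear voxel indices;
#'   \code{nActiveNodes}: their count; \code{nodeCoords}: nAct x 3 voxel
#'   coordinates; \code{nodeClasses}: per-node class names;
#'   \code{nodeLabels}: per-node anatomical label codes;
#'   \code{diffusionTensors}: nAct x 6 tensor components (mm^2/ms).
#' @export
setGeneric("activeIndex", function(x) standardGeneric("activeIndex"))
#' @rdname activeIndex
setMethod("activeIndex", "TissueModel", function(x) x@activeIndex)

#' @rdname activeIndex
#' @export
setGeneric("nActiveNodes", function(x) standardGeneric("nActiveNodes"))
#' @rdname activeIndex
setMethod("nActiveNodes", "TissueModel", function(x) length(x@activeIndex))

#' @rdname activeIndex
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))
#' @rdname activeIndex
setMethod("nodeCoords", "TissueModel", function(x) x@coords)

#' @rdname activeIndex
#' @export
setGeneric("nodeClasses", function(x) standardGeneric("nodeClasses"))
#' @rdname activeIndex
setMethod("nodeClasses", "TissueModel", function(x) x@classNames[x@classId])

#' @rdname activeIndex
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname activeIndex
setMethod("nodeLabels", "TissueModel", function(x) x@labels)

#' @rdname activeIndex
#' @export
setGeneric("diffusionTensors", function(x) standardGeneric("diffusionTensors"))
#' @rdname activeIndex
setMethod("diffusionTensors", "TissueModel", function(x) x@D6)

#' Activation times of an activation map
#' @param x An ActivationMap.
#' @param beat Beat number (column); NULL returns the full matrix.
#' @return Numeric vector (or matrix) of activation times in ms, NaN where
#'   the node did not activate within the beat window.
#' @export
setGeneric("activationTimes", function(x, beat = NULL) standardGeneric("activationTimes"))
#' @rdname activationTimes
setMethod("activationTimes", "ActivationMap", function(x, beat = NULL) {
  if (is.null(beat)) x@times else x@times[, beat]
})

#' Route metadata of a synthetic AVSD geometry
#' @param x An AvsdGeometry.
#' @return Named list of route descriptors (slow, fast, annulus).
#' @export
setGeneric("routeInfo", function(x) standardGeneric("routeInfo"))
#' @rdname routeInfo
setMethod("routeInfo", "AvsdGeometry", function(x) x@routes)

#' @rdname dictionary
setMethod("dictionary", "AvsdGeometry", function(x) x@labels@dictionary)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %d x %d x %d voxels @ %.4g mm (range %.3g..%.3g)\n",
              d[1], d[2], d[3], object@spacing,
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  nlab <- sum(object@data != 0)
  cat(sprintf("LabelVolume: %d x %d x %d voxels @ %.4g mm, %d labelled, %d regions\n",
              d[1], d[2], d[3], object@spacing, nlab,
              length(setdiff(unique(as.vector(object@data)), 0L))))
})

setMethod("show", "OrientationField", function(object) {
  d <- dim(object@coherence)
  ntis <- sum(object@coherence > 0)
  cat(sprintf("OrientationField: %d x %d x %d voxels @ %.4g mm (%d with orientation)\n",
              d[1], d[2], d[3], object@spacing, ntis))
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@comps)
  cat(sprintf("TensorField: %d x %d x %d voxels @ %.4g mm\n",
              d[1], d[2], d[3], object@spacing))
})

setMethod("show", "TissueModel", function(object) {
  cat(sprintf("TissueModel: %d active nodes on %s grid @ %.4g mm (%s)\n",
              length(object@activeIndex),
              paste(object@dims, collapse = " x "), object@spacing,
              if (object@modelId == 0L) "detailed atrial model"
              else "phenomenological model"))
  tab <- table(object@classNames[object@classId])
  for (nm in names(tab)) cat(sprintf("  %-10s %d nodes\n", nm, tab[[nm]]))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d nodes, t = %.3g..%.3g ms (%d samples, %d threshold crossings)\n",
              nrow(object@V), object@tStart, object@tEnd,
              length(object@times), nrow(object@crossings)))
})

setMethod("show", "ActivationMap", function(object) {
  nb <- ncol(object@times)
  frac <- colMeans(is.nan(object@times))
  cat(sprintf("ActivationMap: %d nodes x %d beat(s), threshold %.4g mV\n",
              nrow(object@times), nb, object@threshold))
  cat(sprintf("  not-activated fraction per beat: %s\n",
              paste(sprintf("%.3f", frac), collapse = ", ")))
})

setMethod("show", "AvsdGeometry", function(object) {
  cat("AvsdGeometry\n")
  show(object@labels)
  for (nm in names(object@routes))
    cat(sprintf("  route %-8s length %.3g mm via %s\n", nm,
                object@routes[[nm]]$length,
                paste(object@routes[[nm]]$labels, collapse = "+")))
})

setMethod("show", "CellParams", function(object) {
  cat(sprintf("CellParams: %s / %s%s (Cm = %.4g pF)\n", object@modelId,
              object@variant,
              if (object@blockScaled) " [block-scaled]" else "", object@Cm))
})
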