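#' @import methods
NULL

#' 3D scalar image volume with isotropic voxel size
#'
#' A minimal container for a "virtual micro-CT": a 3D numeric array of
#' intensities plus the isotropic voxel edge length in millimetres.
#'
#' @slot data 3D numeric array of voxel intensities.
#' @slot spacing Isotropic voxel size in mm (single positive number).
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number (mm)")
    if (is.null(msg)) TRUE else msg
  })

#' 3D integer label volume with a label dictionary
#'
#' An anatomical region map sharing a grid with an [ImageVolume-class].
#' Label code 0 is background; the dictionary maps region names to codes.
#'
#' @slot data 3D integer array of region codes.
#' @slot spacing Isotropic voxel size in mm.
#' @slot dictionary Named integer vector mapping region name to label code.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", dictionary = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 1L || object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number (mm)")
    d <- object@dictionary
    if (length(d)) {
      if (anyDuplicated(d)) msg <- c(msg, "label codes must be unique")
      if (is.null(names(d)) || any(!nzchar(names(d))))
        msg <- c(msg, "dictionary must be a named integer vector")
      if (!is.na(d["background"]) && d[["background"]] != 0L)
        msg <- c(msg, "background label code must be 0")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Per-voxel myocyte orientation field
#'
#' Unit myocyte-chain direction vectors (axial data: f and -f are
#' equivalent) with a coherence score in [0, 1] per voxel. Vectors are zero
#' on background/non-tissue voxels.
#'
#' @slot vectors 4D numeric array (nx, ny, nz, 3) of direction components.
#' @slot coherence 3D numeric array of coherence values.
#' @slot spacing Isotropic voxel size in mm.
#' @exportClass OrientationField
setClass("OrientationField",
  representation(vectors = "array", coherence = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    dv <- dim(object@vectors)
    if (length(dv) != 4L || dv[4] != 3L)
      msg <- c(msg, "vectors must be a 4D array with last dimension 3")
    if (!identical(dim(object@coherence), dv[1:3]))
      msg <- c(msg, "coherence grid must match vector grid")
    if (length(object@spacing) != 1L || object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number (mm)")
    if (is.null(msg)) TRUE else msg
  })

#' Per-voxel 3D structure tensor field
#'
#' Six unique components (Jxx, Jyy, Jzz, Jxy, Jxz, Jyz) of the smoothed
#' outer product of Gaussian-derivative image gradients.
#'
#' @slot comps 4D numeric array (nx, ny, nz, 6).
#' @slot spacing Isotropic voxel size in mm.
#' @slot params The [structureTensorParams()] used to build the field.
#' @exportClass TensorField
setClass("TensorField",
  representation(comps = "array", spacing = "numeric", params = "list"),
  validity = function(object) {
    dv <- dim(object@comps)
    if (length(dv) != 4L || dv[4] != 6L)
      return("comps must be a 4D array with last dimension 6")
    TRUE
  })

#' Simulation-ready anisotropic tissue model
#'
#' The active-node representation of a labelled, oriented tissue grid:
#' electrophysiological class, anisotropic diffusion tensor and face
#' connectivity per active node. Inert voxels (background, fat, connective
#' tissue, surgical patch) carry no state; dropped links realize zero-flux
#' boundaries.
#'
#' @slot dims Grid dimensions (3 integers).
#' @slot spacing Node spacing h in mm (default pipeline value 0.15).
#' @slot activeIndex 1-based linear voxel indices of active nodes.
#' @slot coords nAct x 3 integer matrix of voxel coordinates (1-based).
#' @slot classId Integer class per node, indexing \code{classNames}.
#' @slot classNames Electrophysiological class names (e.g. RA, CT, RA_block).
#' @slot cellParams List of \code{CellParams} objects, one per class.
#' @slot D6 nAct x 6 diffusion tensor components (mm^2/ms):
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#' @slot faceNb nAct x 6 matrix of 0-based face-neighbour node indices
#'   (+x, -x, +y, -y, +z, -z; -1 where the link is absent).
#' @slot fibers nAct x 3 unit myocyte direction per node.
#' @slot labels Integer anatomical label code per node.
#' @slot dictionary Label dictionary (named integer vector).
#' @slot modelId 0 = detailed atrial model, 1 = phenomenological fallback.
#' @exportClass TissueModel
setClass("TissueModel",
  representation(dims = "integer", spacing = "numeric",
                 activeIndex = "integer", coords = "matrix",
                 classId = "integer", classNames = "character",
                 cellParams = "list", D6 = "matrix", faceNb = "matrix",
                 fibers = "matrix", labels = "integer",
                 dictionary = "integer", modelId = "integer"),
  validity = function(object) {
    n <- length(object@activeIndex)
    msg <- NULL
    if (nrow(object@D6) != n || ncol(object@D6) != 6L)
      msg <- c(msg, "D6 must be nActive x 6")
    if (nrow(object@faceNb) != n || ncol(object@faceNb) != 6L)
      msg <- c(msg, "faceNb must be nActive x 6")
    if (length(object@classId) != n)
      msg <- c(msg, "classId must have one entry per active node")
    if (n > 0) {
      nrm <- sqrt(rowSums(object@fibers^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "every active node must carry a unit fiber vector")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Result of a monodomain simulation
#'
#' Sampled membrane potential over space and time, the log of upward
#' threshold crossings (the raw material of activation maps), the stimulus
#' event log and the final state (for checkpoint-continued runs).
#'
#' @slot times Sample times in ms (strictly increasing).
#' @slot V nActive x nSamples matrix of membrane potential (mV).
#' @slot crossings data.frame with columns \code{node} (1-based active-node
#'   index) and \code{time} (ms) of upward crossings of the threshold.
#' @slot stimLog data.frame of delivered stimuli (onset, dur, amp, label).
#' @slot finalState nStates x nActive state matrix at \code{tEnd}.
#' @slot tStart,tEnd Simulated interval in ms.
#' @slot config Solver configuration used (list).
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(times = "numeric", V = "matrix", crossings = "data.frame",
                 stimLog = "data.frame", finalState = "matrix",
                 tStart = "numeric", tEnd = "numeric", config = "list"),
  validity = function(object) {
    if (is.unsorted(object@times, strictly = TRUE))
      return("time axis must be strictly increasing")
    TRUE
  })

#' Per-node, per-beat activation times
#'
#' Activation time is the first upward crossing of the threshold voltage
#' within each beat window; NaN marks nodes that never activated in the
#' window.
#'
#' @slot times nActive x nBeats matrix of activation times (ms, NaN = none).
#' @slot beats data.frame of beat windows (onset, end, label).
#' @slot threshold Threshold voltage in mV.
#' @exportClass ActivationMap
setClass("ActivationMap",
  representation(times = "matrix", beats = "data.frame", threshold = "numeric"))

#' Parametric AVSD atrial geometry
#'
#' The synthetic dual-pathway circuit: a label volume, the matching
#' analytic orientation field, and per-route metadata (label sets, analytic
#' centerlines and arc lengths).
#'
#' @slot labels A [LabelVolume-class].
#' @slot orientation An [OrientationField-class].
#' @slot routes Named list of route descriptors (slow, fast, annulus), each
#'   with elements \code{labels}, \code{centerline} (n x 3 mm) and
#'   \code{length} (mm).
#' @slot spec The generating [avsdGeometrySpec()].
#' @exportClass AvsdGeometry
setClass("AvsdGeometry",
  representation(labels = "LabelVolume", orientation = "OrientationField",
                 routes = "list", spec = "list"))

#' Single-cell parameter set
#'
#' Versioned parameters for one cell variant of one ionic model, loaded
#' from the JSON data files shipped with the package.
#'
#' @slot modelId "atrial_detailed" or "phenomenological".
#' @slot variant "RA" or "CT" (block-scaled sets keep the source variant).
#' @slot params Named numeric vector in the solver's parameter order.
#' @slot Cm Membrane capacitance in pF.
#' @slot initState Named numeric initial state vector.
#' @slot blockScaled TRUE once [applyBlockScaling()] has been applied.
#' @exportClass CellParams
setClass("CellParams",
  representation(modelId = "character", variant = "character",
                 params = "numeric", Cm = "numeric", initState = "numeric",
                 blockScaled = "logical"),
  validity = function(object) {
    if (any(!is.finite(object@params))) return("parameters must be finite")
    TRUE
  })
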