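# From labels + orientation to a simulation-ready tissue model:
# electrophysiological classes, virtual suturing, anisotropic diffusion
# tensors and active-node connectivity.

# label name -> electrophysiological class
.CLASS_OF_LABEL <- c(
  background = "inert", working_myocardium_RA = "RA", sinus_node = "CT",
  terminal_crest = "CT", bachmann_bundle = "CT", slow_pathway = "CT",
  fast_pathway_septal_bundle = "CT", valve_annulus = "CT",
  compact_AV_node = "CT", AVCA = "CT", block_zone = "RA_block",
  fat = "inert", connective_tissue = "inert", patch_inert = "inert")

#' Assign electrophysiological cell classes to a label volume
#'
#' Conduction-system and segmented muscle-bundle labels become "CT" type,
#' working myocardium "RA", the block zone "RA_block" (RA with sodium and
#' calcium conductance halved) and non-tissue labels (background, fat,
#' connective tissue, surgical patch) "inert" - excluded from the active
#' mask. The assignment is total: an unknown label is an error.
#'
#' @param labels A [LabelVolume-class].
#' @param includeBlockZone If FALSE the block-zone label is assigned plain
#'   "RA" (the block zone as an on/off toggle).
#' @return List with \code{classNames} (the class levels), \code{id}
#'   (3D integer array indexing classNames), \code{classOfLabel} (named
#'   map label name -> class) and \code{counts} (voxels per class).
#' @export
assignCellClasses <- function(labels, includeBlockZone = TRUE) {
  stopifnot(is(labels, "LabelVolume"))
  dict <- labels@dictionary
  present <- sort(unique(as.vector(labels@data)))
  unknown <- setdiff(present, dict)
  if (length(unknown))
    stop(sprintf("unknown label code(s): %s", paste(unknown, collapse = ", ")))
  classOf <- .CLASS_OF_LABEL[names(dict)]
  if (anyNA(classOf))
    stop(sprintf("no class mapping for label(s): %s",
                 paste(names(dict)[is.na(classOf)], collapse = ", ")))
  names(classOf) <- names(dict)
  if (!includeBlockZone) classOf["block_zone"] <- "RA"
  classNames <- c("inert", "RA", "CT", "RA_block")
  lut <- integer(max(dict) + 1L)
  lut[dict + 1L] <- match(classOf, classNames)
  id <- array(lut[labels@data + 1L], dim = dim(labels@data))
  counts <- tabulate(id, nbins = length(classNames))
  names(counts) <- classNames
  list(classNames = classNames, id = id, classOfLabel = classOf,
       counts = counts)
}

#' Virtually suture dissected borders
#'
#' Voxels in the border mask are assigned working-myocardium (RA)
#' electrophysiological characteristics, restoring conduction across a
#' dissection gap. Existing tissue voxels are never relabelled: the mask
#' must be disjoint from tissue.
#'
#' @param labels A [LabelVolume-class].
#' @param borderMask Logical 3D array marking the gap to close.
#' @return The sutured [LabelVolume-class].
#' @export
virtualSuture <- function(labels, borderMask) {
  stopifnot(is(labels, "LabelVolume"),
            identical(dim(borderMask), dim(labels@data)))
  if (any(borderMask & labels@data != 0L))
    stop("border mask must be disjoint from existing tissue voxels")
  out <- labels@data
  out[borderMask] <- labels@dictionary[["working_myocardium_RA"]]
  initialize(labels, data = out)
}

#' Count conduction-connected components of a label volume
#'
#' Connected components (26-connectivity) of the non-inert tissue mask;
#' the oracle for verifying that virtual suturing restores connectivity.
#'
#' @param labels A [LabelVolume-class].
#' @return Number of connected tissue components.
#' @export
countTissueComponents <- function(labels) {
  cls <- assignCellClasses(labels)
  mask <- array(as.integer(cls$id != 1L), dim = dim(cls$id))
  max(.ccLabel3(mask, dim(mask), 26L))
}

#' Assemble per-node anisotropic diffusion tensors
#'
#' D = d_t I + (d_l - d_t) f f^T per node, with d_l the along-chain and
#' d_t = d_l / ratio the cross-chain coefficient (mm^2/ms). The largest
#' eigenvalue of D is d_l with eigenvector f; the tensor is positive
#' definite wherever f is defined.
#'
#' @param fibers nNodes x 3 matrix of unit fiber vectors.
#' @param dL Along-chain diffusion coefficient (mm^2/ms), > 0.
#' @param ratio Along:cross coefficient ratio (>= 1); default 8.
#' @return nNodes x 6 matrix (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @export
buildDiffusionField <- function(fibers, dL, ratio = 8) {
  stopifnot(is.matrix(fibers), ncol(fibers) == 3L, dL > 0, ratio >= 1)
  dT <- dL / ratio
  dd <- dL - dT
  cbind(dT + dd * fibers[, 1]^2,
        dT + dd * fibers[, 2]^2,
        dT + dd * fibers[, 3]^2,
        dd * fibers[, 1] * fibers[, 2],
        dd * fibers[, 1] * fibers[, 3],
        dd * fibers[, 2] * fibers[, 3])
}

#' Build a simulation-ready tissue model
#'
#' Combines a label volume and an orientation field (same grid) into the
#' active-node representation used by the monodomain solver: per-node cell
#' class and parameters, anisotropic diffusion tensor, and face
#' connectivity. Links to inert or out-of-grid voxels are dropped, which
#' realizes zero-flux boundary conditions; inert regions are no-flux holes.
#'
#' @param labels A [LabelVolume-class].
#' @param orientation An [OrientationField-class] on the same grid.
#' @param dL Along-chain diffusion coefficient (mm^2/ms), e.g. from
#'   [calibrateDiffusion()].
#' @param ratio Along:cross diffusion ratio (default 8).
#' @param modelId "atrial_detailed" or "phenomenological".
#' @param ctDlScale Optional scaling of d_l on CT-class nodes (default 1:
#'   bundles share the working-myocardium coefficient).
#' @param nodalDlScale Scaling of d_l on the compact AV node and
#'   atrioventricular conduction axis labels (default 0.05, giving a
#'   nodal conduction velocity near 15 cm/s). Nodal tissue conducts
#'   decrementally, several-fold slower than working myocardium; it is
#'   the arrival target of the pathway analysis, not a fast bypass
#'   between the routes that converge on it.
#' @param includeBlockZone Toggle for the block zone (see
#'   [assignCellClasses()]).
#' @return A [TissueModel-class].
#' @export
buildTissueModel <- function(labels, orientation, dL, ratio = 8,
                             modelId = c("atrial_detailed", "phenomenological"),
                             ctDlScale = 1, nodalDlScale = 0.05,
                             includeBlockZone = TRUE) {
  modelId <- match.arg(modelId)
  stopifnot(is(labels, "LabelVolume"), is(orientation, "OrientationField"))
  d <- dim(labels@data)
  stopifnot(identical(d, dim(orientation@coherence)))
  if (abs(labels@spacing - orientation@spacing) > 1e-9)
    stop("label and orientation spacing must match")
  cls <- assignCellClasses(labels, includeBlockZone = includeBlockZone)
  activeMaskArr <- cls$id != 1L
  activeIndex <- which(activeMaskArr)
  n <- length(activeIndex)
  if (n == 0L) stop("no active tissue voxels")

  vx <- matrix(c(orientation@vectors[, , , 1][activeIndex],
                 orientation@vectors[, , , 2][activeIndex],
                 orientation@vectors[, , , 3][activeIndex]), ncol = 3L)
  nrm <- sqrt(rowSums(vx^2))
  if (any(nrm < 1e-9))
    stop(sprintf("%d active voxel(s) lack an orientation vector",
                 sum(nrm < 1e-9)))
  vx <- vx / nrm

  coords <- arrayInd(activeIndex, d)
  nodeOf <- array(-1L, dim = d)
  nodeOf[activeIndex] <- seq_len(n) - 1L  # 0-based for the solver
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  faceNb <- matrix(-1L, n, 6L)
  for (k in 1:6) {
    nc <- sweep(coords, 2, off[k, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] & nc[, 2] >= 1 & nc[, 2] <= d[2] &
          nc[, 3] >= 1 & nc[, 3] <= d[3]
    idx <- rep(-1L, n)
    idx[ok] <- nodeOf[cbind(nc[ok, 1], nc[ok, 2], nc[ok, 3])]
    faceNb[, k] <- idx
  }

  # class-local ids: keep only classes present among active nodes
  classAll <- cls$classNames[cls$id[activeIndex]]
  presentClasses <- intersect(c("RA", "CT", "RA_block"), unique(classAll))
  classId <- match(classAll, presentClasses)
  paramsByClass <- lapply(presentClasses, function(cn) {
    switch(cn,
           RA = makeCellParams("RA", modelId),
           CT = makeCellParams("CT", modelId),
           RA_block = applyBlockScaling(makeCellParams("RA", modelId)))
  })
  names(paramsByClass) <- presentClasses

  D6 <- buildDiffusionField(vx, dL, ratio)
  if (ctDlScale != 1) {
    ct <- classAll == "CT"
    D6[ct, ] <- buildDiffusionField(vx[ct, , drop = FALSE],
                                    dL * ctDlScale, ratio)
  }
  labAtNodes <- labels@data[activeIndex]
  nodalCodes <- labels@dictionary[c("compact_AV_node", "AVCA")]
  nodal <- labAtNodes %in% nodalCodes[!is.na(nodalCodes)]
  if (nodalDlScale != 1 && any(nodal))
    D6[nodal, ] <- buildDiffusionField(vx[nodal, , drop = FALSE],
                                       dL * nodalDlScale, ratio)
  new("TissueModel", dims = as.integer(d), spacing = labels@spacing,
      activeIndex = as.integer(activeIndex),
      coords = coords, classId = as.integer(classId),
      classNames = presentClasses, cellParams = paramsByClass,
      D6 = D6, faceNb = faceNb, labels = as.integer(labels@data[activeIndex]),
      dictionary = labels@dictionary,
      modelId = .modelIdInt(modelId))
}

#' Per-class node counts of a tissue model
#' @param model A [TissueModel-class].
#' @param file Optional path; when given the table is also written as CSV.
#' @return data.frame with class and node count.
#' @export
tissueModelReport <- function(model, file = NULL) {
  stopifnot(is(model, "TissueModel"))
  tab <- table(factor(model@classNames[model@classId],
                      levels = model@classNames))
  df <- data.frame(class = names(tab), nodes = as.integer(tab))
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}

#' Resolve the active nodes carrying a given anatomical label
#' @param model A [TissueModel-class].
#' @param labelName Region name from the label dictionary.
#' @return Integer vector of 1-based active-node indices.
#' @export
nodesOfLabel <- function(model, labelName) {
  stopifnot(is(model, "TissueModel"))
  code <- model@dictionary[labelName]
  if (anyNA(code)) stop(sprintf("unknown label name '%s'", labelName))
  which(model@labels %in% code)
}
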