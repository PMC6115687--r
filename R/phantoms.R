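# Synthetic inputs: fiber phantoms with analytic ground-truth orientation,
# and the parametric dual-pathway AVSD atrial geometry.

#' Specification of a fiber phantom
#'
#' Describes a synthetic image volume whose texture is elongated along an
#' analytically known myocyte direction, used to validate orientation
#' extraction end to end.
#'
#' @param pattern One of "parallel" (fibers along +x), "circular"
#'   (fibers tangent to circles around the z axis) or "helical" (circular
#'   plus a fixed axial pitch per turn).
#' @param gridShape Three positive integers, each >= 16.
#' @param voxelSizeUm Isotropic voxel size in micrometres.
#' @param fiberTexturePeriodUm Spatial period of the texture perpendicular
#'   to the fibers, in micrometres.
#' @param noiseSd Standard deviation of additive Gaussian intensity noise,
#'   as a fraction of the intensity range (must be < 1).
#' @param seed Integer seed for the noise generator.
#' @param helixPitchUm Axial rise per turn for the helical pattern.
#' @return A validated list of class \code{FiberPhantomSpec}.
#' @export
fiberPhantomSpec <- function(pattern = c("parallel", "circular", "helical"),
                             gridShape = c(32L, 32L, 32L),
                             voxelSizeUm = 38.5,
                             fiberTexturePeriodUm = 8 * voxelSizeUm,
                             noiseSd = 0,
                             seed = 1L,
                             helixPitchUm = 10 * fiberTexturePeriodUm) {
  pattern <- match.arg(pattern)
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape > 0))
  if (any(gridShape < 16L))
    stop("gridShape must be at least 16 voxels per axis")
  stopifnot(voxelSizeUm > 0, fiberTexturePeriodUm > 0,
            noiseSd >= 0, noiseSd < 1, helixPitchUm > 0)
  structure(list(pattern = pattern, gridShape = gridShape,
                 voxelSizeUm = voxelSizeUm,
                 fiberTexturePeriodUm = fiberTexturePeriodUm,
                 noiseSd = noiseSd, seed = as.integer(seed),
                 helixPitchUm = helixPitchUm),
            class = "FiberPhantomSpec")
}

#' Generate a fiber phantom and its ground-truth orientation field
#'
#' The intensity texture varies along the two directions perpendicular to
#' the local fiber direction and is constant along it, so the direction of
#' least intensity variation is the fiber axis by construction. Identical
#' spec and seed give bit-identical output; noise perturbs only the
#' intensities, never the ground truth.
#'
#' @param spec A [fiberPhantomSpec()].
#' @return List with elements \code{volume} ([ImageVolume-class]) and
#'   \code{truth} ([OrientationField-class]).
#' @export
makeFiberPhantom <- function(spec) {
  stopifnot(inherits(spec, "FiberPhantomSpec"))
  n <- spec$gridShape
  vox <- spec$voxelSizeUm
  p <- spec$fiberTexturePeriodUm
  minExtent <- min(n) * vox
  if (minExtent < 2 * p)
    stop(sprintf(paste0("grid too small for texture period: need at least ",
                        "%d voxels per axis at %g um for a %g um period"),
                 ceiling(2 * p / vox), vox, p))
  # voxel-centre coordinates in um, origin at the volume centre
  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * vox
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * vox
  cz <- (seq_len(n[3]) - (n[3] + 1) / 2) * vox
  X <- array(rep(cx, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(cy, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(cz, each = n[1] * n[2]), dim = n)

  vec <- array(0, dim = c(n, 3L))
  if (spec$pattern == "parallel") {
    intensity <- 0.5 + 0.25 * sin(2 * pi * Y / p) + 0.25 * sin(2 * pi * Z / p)
    vec[, , , 1] <- 1
  } else {
    R <- sqrt(X^2 + Y^2)
    safeR <- pmax(R, 1e-9)
    if (spec$pattern == "circular") {
      intensity <- 0.5 + 0.25 * sin(2 * pi * R / p) + 0.25 * sin(2 * pi * Z / p)
      tx <- -Y / safeR; ty <- X / safeR; tz <- array(0, dim = n)
    } else {
      pitch <- spec$helixPitchUm
      m <- max(1, round(pitch / p))
      theta <- atan2(Y, X)
      intensity <- 0.5 + 0.25 * sin(2 * pi * R / p) +
        0.25 * sin(2 * pi * m * (Z / pitch - theta / (2 * pi)))
      hz <- pitch / (2 * pi)
      nrm <- sqrt(R^2 + hz^2)
      tx <- -Y / nrm; ty <- X / nrm; tz <- array(hz, dim = n) / nrm
    }
    # on the axis the tangent is undefined; use the convention (0, 1, 0)
    onAxis <- R < vox / 4
    tx[onAxis] <- 0; ty[onAxis] <- 1; tz[onAxis] <- 0
    vec[, , , 1] <- tx; vec[, , , 2] <- ty; vec[, , , 3] <- tz
  }

  if (spec$noiseSd > 0) {
    set.seed(spec$seed)
    intensity <- intensity + array(stats::rnorm(prod(n), 0, spec$noiseSd), dim = n)
  }
  vol <- new("ImageVolume", data = intensity, spacing = vox / 1000)
  truth <- new("OrientationField", vectors = vec,
               coherence = array(1, dim = n), spacing = vox / 1000)
  list(volume = vol, truth = truth)
}

#' Canonical label dictionary for the synthetic atrial geometry
#'
#' @return Named integer vector of label codes; background is 0 and every
#'   non-background code maps to exactly one electrophysiological class
#'   (see [assignCellClasses()]).
#' @export
defaultLabelDictionary <- function() {
  c(background = 0L, working_myocardium_RA = 1L, sinus_node = 2L,
    terminal_crest = 3L, bachmann_bundle = 4L, slow_pathway = 5L,
    fast_pathway_septal_bundle = 6L, valve_annulus = 7L,
    compact_AV_node = 8L, AVCA = 9L, block_zone = 10L, fat = 11L,
    connective_tissue = 12L, patch_inert = 13L)
}

#' Specification of the parametric AVSD atrial geometry
#'
#' Encodes the dual-pathway topology of an atrioventricular septal defect:
#' the compact AV node is displaced posterior-inferiorly (anterior to the
#' coronary sinus ostium), which shortens the "slow" pathway and lengthens
#' the "fast" pathway, so by construction
#' slow < fast < annulus route length.
#'
#' @param pathLengthSlowMm Arc length of the slow pathway (SN to node).
#' @param pathLengthFastMm Arc length of the fast route via the septal
#'   bundle; must exceed the slow length.
#' @param annulusLengthMm Arc length of the valve-annulus route (longest).
#' @param bundleWidthMm Width of the muscle bundles.
#' @param sheetThicknessMm Wall thickness of the sheet (z extent).
#' @param blockZoneExtentMm Edge length of the low-excitability block-zone
#'   slab placed between the sinus node and the septal bundle.
#' @param voxelSizeMm Isotropic voxel size of the rasterized volume.
#' @param fanWidthFactor Width multiplier of the transitional fan where the
#'   slow pathway spreads into the compact-node region.
#' @param fanLengthMm Length of that transitional fan.
#' @param nodePositions Optional named list of 3D positions (mm) overriding
#'   the automatic layout for "sinus_node" and "compact_AV_node".
#' @return A validated list of class \code{AvsdGeometrySpec}.
#' @export
avsdGeometrySpec <- function(pathLengthSlowMm = 12, pathLengthFastMm = 15,
                             annulusLengthMm = 26, bundleWidthMm = 0.6,
                             sheetThicknessMm = 0.15,
                             blockZoneExtentMm = 2, voxelSizeMm = 0.15,
                             fanWidthFactor = 2.5, fanLengthMm = 2.5,
                             nodePositions = NULL) {
  stopifnot(pathLengthSlowMm > 0, pathLengthFastMm > 0, annulusLengthMm > 0,
            bundleWidthMm > 0, sheetThicknessMm > 0, blockZoneExtentMm > 0,
            voxelSizeMm > 0, fanWidthFactor >= 1, fanLengthMm >= 0)
  if (pathLengthFastMm <= pathLengthSlowMm)
    stop("pathLengthFastMm must exceed pathLengthSlowMm (displaced node: slow pathway shortened, fast lengthened)")
  if (annulusLengthMm <= pathLengthFastMm)
    stop("annulusLengthMm must exceed pathLengthFastMm (annulus is the longest route)")
  if (min(pathLengthSlowMm, pathLengthFastMm, annulusLengthMm) <=
      4 * bundleWidthMm)
    stop("all route lengths must exceed 4 x bundleWidthMm")
  structure(list(pathLengthSlowMm = pathLengthSlowMm,
                 pathLengthFastMm = pathLengthFastMm,
                 annulusLengthMm = annulusLengthMm,
                 bundleWidthMm = bundleWidthMm,
                 sheetThicknessMm = sheetThicknessMm,
                 blockZoneExtentMm = blockZoneExtentMm,
                 voxelSizeMm = voxelSizeMm,
                 fanWidthFactor = fanWidthFactor,
                 fanLengthMm = fanLengthMm,
                 nodePositions = nodePositions),
            class = "AvsdGeometrySpec")
}

# Paint a capsule (segment with round caps, possibly tapering width) into
# the label and tangent arrays. Operates on the painter environment.
.paintSegment <- function(env, P, Q, halfWidth, code, tangent = NULL,
                          halfWidthEnd = halfWidth, backgroundOnly = FALSE) {
  d <- Q - P
  len <- sqrt(sum(d^2))
  u <- if (len > 0) d / len else c(1, 0, 0)
  rel <- sweep(env$coords, 2, P)
  tpar <- pmin(pmax(as.vector(rel %*% u) / max(len, 1e-12), 0), 1)
  proj <- outer(tpar, d)
  dist2 <- rowSums((rel - proj)^2)
  hw <- halfWidth + (halfWidthEnd - halfWidth) * tpar
  sel <- dist2 <= hw^2
  if (backgroundOnly) sel <- sel & env$lab == 0L
  env$lab[sel] <- code
  tg <- if (is.null(tangent)) u else tangent / sqrt(sum(tangent^2))
  env$tan[sel, 1] <- tg[1]; env$tan[sel, 2] <- tg[2]; env$tan[sel, 3] <- tg[3]
  invisible(sum(sel))
}

.paintDisc <- function(env, C, radius, code, tangent = c(1, 0, 0)) {
  rel <- sweep(env$coords, 2, C)
  sel <- rowSums(rel^2) <= radius^2
  env$lab[sel] <- code
  env$tan[sel, 1] <- tangent[1]; env$tan[sel, 2] <- tangent[2]
  env$tan[sel, 3] <- tangent[3]
  invisible(sum(sel))
}

#' Generate the synthetic AVSD atrial geometry
#'
#' Rasterizes a thin-walled sheet in which the sinus node connects to the
#' compact AV node through three label-disjoint routes forming a closed
#' circuit: the shortened slow pathway (straight, with a transitional fan
#' spreading into the node), the elongated fast route via a septal bundle,
#' and the valve annulus (longest). A low-excitability block-zone slab sits
#' between the sinus node and the septal bundle; small fat, connective
#' tissue and surgical-patch patches provide inert labels for the
#' attenuation model. Orientation vectors run along the local bundle
#' centerline.
#'
#' @param spec An [avsdGeometrySpec()].
#' @return An [AvsdGeometry-class].
#' @export
makeAvsdAtria <- function(spec) {
  stopifnot(inherits(spec, "AvsdGeometrySpec"))
  dict <- defaultLabelDictionary()
  vox <- spec$voxelSizeMm
  w2 <- spec$bundleWidthMm / 2
  cdist <- spec$pathLengthSlowMm          # SN-to-node chord (slow is straight)
  # fast and annulus are circular arcs bulging above / below the chord:
  # turning is distributed along the route (no sharp-corner conduction
  # penalty under anisotropic diffusion) and the three routes approach
  # the node through disjoint angular corridors. For chord c and arc
  # length L the half-angle phi solves sin(phi)/phi = c/L.
  .arcHalfAngle <- function(L) {
    stats::uniroot(function(phi) sin(phi) / phi - cdist / L,
                   c(1e-6, pi - 1e-6))$root
  }
  phiF <- .arcHalfAngle(spec$pathLengthFastMm)
  phiA <- .arcHalfAngle(spec$annulusLengthMm)
  Rf <- spec$pathLengthFastMm / (2 * phiF)
  Ra <- spec$annulusLengthMm / (2 * phiA)
  sagF <- Rf * (1 - cos(phiF))
  sagA <- Ra * (1 - cos(phiA))
  extraX <- max(0, Rf - cdist / 2, Ra - cdist / 2)
  stub <- max(2.5, 6 * w2)
  margin <- stub + 2 * spec$bundleWidthMm + extraX

  S <- c(margin, margin + sagA, spec$sheetThicknessMm / 2)
  N <- c(margin + cdist, margin + sagA, spec$sheetThicknessMm / 2)
  if (!is.null(spec$nodePositions)) {
    if (!is.null(spec$nodePositions$sinus_node)) S <- spec$nodePositions$sinus_node
    if (!is.null(spec$nodePositions$compact_AV_node)) N <- spec$nodePositions$compact_AV_node
  }
  # polyline sampling of the arc from S to N bulging toward side (+1 = +y)
  .arcPoints <- function(phi, R, side, nSeg = 48L) {
    chord <- N - S
    c2 <- sqrt(sum(chord^2))
    th <- chord / c2
    nh <- side * c(-th[2], th[1], 0)
    O <- (S + N) / 2 - nh * (R * cos(phi))
    ang <- seq(pi / 2 + phi, pi / 2 - phi, length.out = nSeg + 1L)
    t(vapply(ang, function(a) O + R * (cos(a) * th + sin(a) * nh),
             numeric(3)))
  }
  arcFast <- .arcPoints(phiF, Rf, +1)
  arcAnn <- .arcPoints(phiA, Ra, -1)

  nx <- ceiling((cdist + 2 * margin) / vox)
  ny <- ceiling((sagA + sagF + 2 * margin) / vox)
  nz <- max(1L, round(spec$sheetThicknessMm / vox))
  dims <- c(nx, ny, nz)

  cx <- (seq_len(nx) - 0.5) * vox
  cy <- (seq_len(ny) - 0.5) * vox
  cz <- (seq_len(nz) - 0.5) * vox
  coords <- cbind(rep(cx, times = ny * nz),
                  rep(rep(cy, each = nx), times = nz),
                  rep(cz, each = nx * ny))
  env <- new.env()
  env$coords <- coords
  env$lab <- integer(nrow(coords))
  env$tan <- matrix(0, nrow(coords), 3)

  # inert reference patches (isolated corners)
  half <- 0.75
  .paintDisc(env, c(half + vox, half + vox, S[3]), half, dict[["fat"]])
  .paintDisc(env, c(nx * vox - half - vox, half + vox, S[3]), half,
             dict[["connective_tissue"]])
  .paintDisc(env, c(half + vox, ny * vox - half - vox, S[3]), half,
             dict[["patch_inert"]])

  # working-myocardium apron around the sinus node
  rSN <- max(0.9, spec$bundleWidthMm)
  .paintDisc(env, S, rSN + 0.5, dict[["working_myocardium_RA"]])

  # accessory bundles (anatomical context, not on any analysed route);
  # the terminal crest leaves the SN up-left, clear of the fast arc's
  # near-vertical exit corridor
  tcDir <- c(cos(3 * pi / 4), sin(3 * pi / 4), 0)
  .paintSegment(env, S, S + stub * tcDir, w2, dict[["terminal_crest"]])
  .paintSegment(env, S, S + c(-stub, 0, 0), w2, dict[["bachmann_bundle"]])
  .paintSegment(env, N, N + c(stub, 0, 0), w2, dict[["AVCA"]])

  # the three routes (painted before the node/SN discs so the discs cap them)
  .paintPolyline <- function(pts, code) {
    for (i in seq_len(nrow(pts) - 1L))
      .paintSegment(env, pts[i, ], pts[i + 1L, ], w2, code)
  }
  .paintPolyline(arcAnn, dict[["valve_annulus"]])
  fanStart <- N - c(spec$fanLengthMm, 0, 0)
  .paintSegment(env, S, fanStart, w2, dict[["slow_pathway"]])
  if (spec$fanLengthMm > 0)
    .paintSegment(env, fanStart, N, w2, dict[["slow_pathway"]],
                  halfWidthEnd = spec$fanWidthFactor * w2)
  .paintPolyline(arcFast, dict[["fast_pathway_septal_bundle"]])

  # block zone: slab between SN and the septal bundle, touching the fast
  # bundle near its SN end but a conduction cul-de-sac
  uf <- arcFast[2, ] - arcFast[1, ]
  uf <- uf / sqrt(sum(uf^2))
  perp <- c(uf[2], -uf[1], 0)
  bc <- S + (rSN + 1.2) * uf + (w2 + spec$blockZoneExtentMm / 2) * perp
  .paintSegment(env, bc - c(spec$blockZoneExtentMm / 2, 0, 0) * 1,
                bc + c(spec$blockZoneExtentMm / 2, 0, 0) * 1,
                spec$blockZoneExtentMm / 2, dict[["block_zone"]],
                backgroundOnly = TRUE)

  .paintDisc(env, S, rSN, dict[["sinus_node"]])
  # the node region must absorb the fan's end cap and keep the three
  # approach corridors separated
  rNode <- max(1.2, 1.3 * spec$fanWidthFactor * w2)
  .paintDisc(env, N, rNode, dict[["compact_AV_node"]])

  labArr <- array(env$lab, dim = dims)
  vecArr <- array(0, dim = c(dims, 3L))
  nrm <- sqrt(rowSums(env$tan^2))
  tissue <- env$lab != 0L & nrm > 0
  tanU <- env$tan
  tanU[tissue, ] <- tanU[tissue, , drop = FALSE] / nrm[tissue]
  tanU[!tissue, ] <- 0
  vecArr[, , , 1] <- array(tanU[, 1], dim = dims)
  vecArr[, , , 2] <- array(tanU[, 2], dim = dims)
  vecArr[, , , 3] <- array(tanU[, 3], dim = dims)
  cohArr <- array(as.numeric(tissue), dim = dims)

  labels <- new("LabelVolume", data = labArr, spacing = vox, dictionary = dict)
  orientation <- new("OrientationField", vectors = vecArr, coherence = cohArr,
                     spacing = vox)
  routes <- list(
    slow = list(labels = "slow_pathway", centerline = rbind(S, N),
                length = spec$pathLengthSlowMm),
    fast = list(labels = "fast_pathway_septal_bundle",
                centerline = arcFast,
                length = spec$pathLengthFastMm),
    annulus = list(labels = "valve_annulus", centerline = arcAnn,
                   length = spec$annulusLengthMm))

  geom <- new("AvsdGeometry", labels = labels, orientation = orientation,
              routes = routes, spec = unclass(spec))
  .checkRouteConnectivity(geom)
  geom
}

# Every route must connect SN to the compact node after rasterization.
.checkRouteConnectivity <- function(geom) {
  lab <- geom@labels@data
  dict <- geom@labels@dictionary
  for (nm in names(geom@routes)) {
    codes <- c(dict[["sinus_node"]], dict[["compact_AV_node"]],
               dict[geom@routes[[nm]]$labels])
    mask <- array(as.integer(lab %in% codes), dim = dim(lab))
    cc <- .ccLabel3(mask, dim(lab), 26L)
    snComp <- unique(cc[lab == dict[["sinus_node"]]])
    avComp <- unique(cc[lab == dict[["compact_AV_node"]]])
    if (length(intersect(snComp, avComp)) == 0L)
      stop(sprintf("route '%s' is not conduction-wise connected after rasterization", nm))
  }
  invisible(TRUE)
}

#' Default tissue-contrast map for the attenuation model
#'
#' Mean intensities (fraction of the dynamic range) per region, encoding
#' the iodine-contrast attenuation ordering
#' fat > working myocardium > nodal tissue > connective tissue.
#'
#' @return Named numeric vector over all dictionary labels.
#' @export
defaultContrastMap <- function() {
  c(background = 0.05, working_myocardium_RA = 0.70, sinus_node = 0.50,
    terminal_crest = 0.70, bachmann_bundle = 0.70, slow_pathway = 0.70,
    fast_pathway_septal_bundle = 0.70, valve_annulus = 0.70,
    compact_AV_node = 0.50, AVCA = 0.50, block_zone = 0.55, fat = 0.90,
    connective_tissue = 0.35, patch_inert = 0.30)
}

#' Synthesize an attenuation (virtual micro-CT) volume from labels
#'
#' Each voxel receives the contrast value of its label plus optional
#' Gaussian noise; with the default contrast map the class means follow the
#' attenuation ordering fat > working myocardium > nodal > connective
#' tissue. Deterministic for a fixed seed.
#'
#' @param labels A [LabelVolume-class].
#' @param contrastMap Named numeric vector of per-label mean intensities;
#'   must cover every label present in the volume.
#' @param noiseSd Gaussian noise SD as a fraction of the intensity range.
#' @param seed Integer seed.
#' @return An [ImageVolume-class] on the same grid.
#' @export
makeAttenuationVolume <- function(labels, contrastMap = defaultContrastMap(),
                                  noiseSd = 0, seed = 1L) {
  stopifnot(is(labels, "LabelVolume"), noiseSd >= 0)
  dict <- labels@dictionary
  present <- sort(unique(as.vector(labels@data)))
  presentNames <- names(dict)[match(present, dict)]
  missing <- presentNames[!presentNames %in% names(contrastMap)]
  if (length(missing) || anyNA(presentNames))
    stop(sprintf("contrastMap is missing labels: %s",
                 paste(c(missing, present[is.na(presentNames)]), collapse = ", ")))
  lut <- numeric(max(dict) + 1L)
  lut[dict + 1L] <- contrastMap[names(dict)]
  img <- array(lut[labels@data + 1L], dim = dim(labels@data))
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    img <- img + array(stats::rnorm(length(img), 0, noiseSd), dim = dim(img))
  }
  new("ImageVolume", data = img, spacing = labels@spacing)
}
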