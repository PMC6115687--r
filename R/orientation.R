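# Myocyte-orientation estimation: 3D structure tensor, eigen-analysis,
# axial-safe downsampling and angular validation metrics.

.gaussKernel <- function(sigma, derivative = FALSE) {
  # sigma in voxels; radius covers +-3 sigma (at least 1 voxel)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (!derivative) return(g)
  dg <- -x / sigma^2 * g
  # enforce exact unit response to a linear ramp: sum(x * dg) == -1
  dg / abs(sum(x * dg))
}

.convSep <- function(arr, kx, ky, kz) {
  d <- dim(arr)
  out <- .conv3Axis(arr, d, kx, 0L)
  out <- .conv3Axis(out, d, ky, 1L)
  .conv3Axis(out, d, kz, 2L)
}

#' Parameters for structure-tensor orientation estimation
#'
#' @param sigmaGradientUm Gaussian derivative scale in micrometres.
#' @param sigmaWindowUm Tensor-smoothing window scale in micrometres; must
#'   be >= the gradient scale.
#' @param downsampleTargetMm Target spacing for modelling-resolution fields.
#' @return A validated list of class \code{StructureTensorParams}.
#' @export
structureTensorParams <- function(sigmaGradientUm, sigmaWindowUm,
                                  downsampleTargetMm = 0.15) {
  stopifnot(sigmaGradientUm > 0, sigmaWindowUm > 0, downsampleTargetMm > 0)
  if (sigmaWindowUm < sigmaGradientUm)
    stop("sigmaWindowUm must be >= sigmaGradientUm")
  structure(list(sigmaGradientUm = sigmaGradientUm,
                 sigmaWindowUm = sigmaWindowUm,
                 downsampleTargetMm = downsampleTargetMm),
            class = "StructureTensorParams")
}

#' Default structure-tensor scales for a volume
#'
#' Derivative scale of 1 voxel and window scale of 4 voxels at the
#' volume's native resolution.
#' @param vol An [ImageVolume-class].
#' @inheritParams structureTensorParams
#' @return A \code{StructureTensorParams}.
#' @export
defaultStructureTensorParams <- function(vol, downsampleTargetMm = 0.15) {
  voxUm <- spacing(vol) * 1000
  structureTensorParams(voxUm, 4 * voxUm, downsampleTargetMm)
}

#' Compute the 3D structure tensor of an image volume
#'
#' The tensor at each voxel is the Gaussian-window average of the outer
#' product of Gaussian-derivative gradients:
#' J = G_w * (grad I)(grad I)^T. J is symmetric positive semi-definite.
#'
#' @param vol An [ImageVolume-class] with isotropic voxels.
#' @param params A [structureTensorParams()]; defaults to
#'   [defaultStructureTensorParams()].
#' @return A [TensorField-class].
#' @export
computeStructureTensor <- function(vol, params = defaultStructureTensorParams(vol)) {
  stopifnot(is(vol, "ImageVolume"), inherits(params, "StructureTensorParams"))
  d <- dim(vol@data)
  if (any(d < 8L)) stop("volume must be at least 8 voxels per axis")
  voxUm <- spacing(vol) * 1000
  sg <- params$sigmaGradientUm / voxUm
  sw <- params$sigmaWindowUm / voxUm
  g <- .gaussKernel(sg); dg <- .gaussKernel(sg, derivative = TRUE)
  w <- .gaussKernel(sw)
  gx <- .convSep(vol@data, dg, g, g)
  gy <- .convSep(vol@data, g, dg, g)
  gz <- .convSep(vol@data, g, g, dg)
  comps <- array(0, dim = c(d, 6L))
  comps[, , , 1] <- .convSep(gx * gx, w, w, w)
  comps[, , , 2] <- .convSep(gy * gy, w, w, w)
  comps[, , , 3] <- .convSep(gz * gz, w, w, w)
  comps[, , , 4] <- .convSep(gx * gy, w, w, w)
  comps[, , , 5] <- .convSep(gx * gz, w, w, w)
  comps[, , , 6] <- .convSep(gy * gz, w, w, w)
  new("TensorField", comps = comps, spacing = vol@spacing,
      params = unclass(params))
}

# Enforce the deterministic axial sign convention: each vector is flipped
# into the hemisphere with nonnegative z (ties: nonnegative y, then x).
.axialSign <- function(v) {
  tol <- 1e-12
  flip <- v[, 3] < -tol |
    (abs(v[, 3]) <= tol & v[, 2] < -tol) |
    (abs(v[, 3]) <= tol & abs(v[, 2]) <= tol & v[, 1] < 0)
  v[flip, ] <- -v[flip, , drop = FALSE]
  v
}

#' Extract myocyte orientation from a structure-tensor field
#'
#' Intensity varies least along a myocyte chain, so the fiber direction is
#' the eigenvector of the smallest eigenvalue of J. With eigenvalues
#' sorted l1 >= l2 >= l3, coherence is (l2 - l3) / (l1 + l2 + l3 + eps):
#' zero for an isotropic tensor (no preferred direction) and for a
#' degenerate smallest eigenpair. Vectors follow a fixed axial sign
#' convention (nonnegative z; ties broken by y, then x) so outputs are
#' reproducible.
#'
#' @param tf A [TensorField-class].
#' @param tissueMask Optional logical 3D array; outside the mask vectors
#'   and coherence are zero.
#' @return An [OrientationField-class].
#' @export
extractOrientation <- function(tf, tissueMask = NULL) {
  stopifnot(is(tf, "TensorField"))
  d <- dim(tf@comps)[1:3]
  nvox <- prod(d)
  m <- matrix(tf@comps, nrow = nvox, ncol = 6L)
  eg <- .eigSym3Batch(m)
  vals <- eg$values
  eps <- 1e-12 * mean(vals[, 1] + vals[, 2] + vals[, 3])
  coh <- (vals[, 2] - vals[, 3]) / (vals[, 1] + vals[, 2] + vals[, 3] + max(eps, 1e-300))
  v <- .axialSign(eg$vmin)
  if (!is.null(tissueMask)) {
    stopifnot(identical(dim(tissueMask), d))
    out <- !as.vector(tissueMask)
    v[out, ] <- 0
    coh[out] <- 0
  }
  vec <- array(0, dim = c(d, 3L))
  vec[, , , 1] <- array(v[, 1], dim = d)
  vec[, , , 2] <- array(v[, 2], dim = d)
  vec[, , , 3] <- array(v[, 3], dim = d)
  new("OrientationField", vectors = vec, coherence = array(coh, dim = d),
      spacing = tf@spacing)
}

# integer decimation factor from spacings; warns when the ratio is not an
# integer and the block size has to be rounded
.decimationFactor <- function(sourceMm, targetMm) {
  if (targetMm < sourceMm - 1e-9)
    stop("target spacing must be >= source spacing")
  f <- targetMm / sourceMm
  fi <- max(1L, as.integer(round(f)))
  if (abs(f - fi) > 1e-6)
    warning(sprintf(paste0("non-integer decimation factor %.4g; resampling ",
                           "with block size %d (effective spacing %.4g mm)"),
                    f, fi, fi * sourceMm))
  fi
}

.blockReduceMean <- function(arr, f) {
  d <- dim(arr)
  d2 <- d %/% f
  a <- arr[seq_len(d2[1] * f), seq_len(d2[2] * f), seq_len(d2[3] * f), drop = FALSE]
  dim(a) <- c(f, d2[1], f, d2[2], f, d2[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(d2))
  array(colMeans(a), dim = d2)
}

#' Downsample a scalar volume by block averaging
#' @param vol An [ImageVolume-class].
#' @param targetMm Target isotropic spacing (>= native spacing).
#' @return An [ImageVolume-class] at the decimated resolution.
#' @export
downsampleScalar <- function(vol, targetMm = 0.15) {
  stopifnot(is(vol, "ImageVolume"))
  f <- .decimationFactor(vol@spacing, targetMm)
  if (f == 1L) return(vol)
  new("ImageVolume", data = .blockReduceMean(vol@data, f),
      spacing = vol@spacing * f)
}

#' Downsample a label volume by block majority vote
#'
#' Background loses ties to tissue: a tissue label wins whenever its count
#' reaches the background count in a block.
#'
#' @param labels A [LabelVolume-class].
#' @param targetMm Target isotropic spacing.
#' @return A [LabelVolume-class].
#' @export
downsampleLabels <- function(labels, targetMm = 0.15) {
  stopifnot(is(labels, "LabelVolume"))
  f <- .decimationFactor(labels@spacing, targetMm)
  if (f == 1L) return(labels)
  d <- dim(labels@data)
  d2 <- d %/% f
  a <- labels@data[seq_len(d2[1] * f), seq_len(d2[2] * f), seq_len(d2[3] * f),
                   drop = FALSE]
  dim(a) <- c(f, d2[1], f, d2[2], f, d2[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(d2))
  maxCode <- max(a)
  vote <- apply(a, 2, function(col) {
    counts <- tabulate(col + 1L, nbins = maxCode + 1L)
    bg <- counts[1]
    counts[1] <- 0L
    if (any(counts > 0L)) {
      top <- which.max(counts)
      if (counts[top] >= bg) return(top - 1L)
    }
    0L
  })
  new("LabelVolume", data = array(as.integer(vote), dim = d2),
      spacing = labels@spacing * f, dictionary = labels@dictionary)
}

#' Downsample an orientation field (axial-data-safe)
#'
#' Orientation is axial (f and -f are the same direction), so naive vector
#' averaging can cancel. Each block instead averages the outer products
#' f f^T and re-extracts the dominant eigenvector of the mean orientation
#' tensor; the returned coherence is the normalized eigenvalue spread
#' (l1 - l2) / trace of that tensor.
#'
#' @param field An [OrientationField-class].
#' @param targetMm Target isotropic spacing.
#' @return An [OrientationField-class].
#' @export
downsampleOrientation <- function(field, targetMm = 0.15) {
  stopifnot(is(field, "OrientationField"))
  f <- .decimationFactor(field@spacing, targetMm)
  if (f == 1L) return(field)
  vx <- field@vectors[, , , 1]; vy <- field@vectors[, , , 2]
  vz <- field@vectors[, , , 3]
  comps <- list(vx * vx, vy * vy, vz * vz, vx * vy, vx * vz, vy * vz)
  red <- lapply(comps, .blockReduceMean, f = f)
  d2 <- dim(red[[1]])
  m <- do.call(cbind, lapply(red, as.vector))
  eg <- .eigSym3Batch(m)
  tr <- rowSums(eg$values)
  ok <- tr > 1e-9
  v <- .axialSign(eg$vmax)
  v[!ok, ] <- 0
  coh <- ifelse(ok, (eg$values[, 1] - eg$values[, 2]) / (tr + 1e-300), 0)
  vec <- array(0, dim = c(d2, 3L))
  vec[, , , 1] <- array(v[, 1], dim = d2)
  vec[, , , 2] <- array(v[, 2], dim = d2)
  vec[, , , 3] <- array(v[, 3], dim = d2)
  new("OrientationField", vectors = vec, coherence = array(coh, dim = d2),
      spacing = field@spacing * f)
}

#' Angular error between two orientation fields
#'
#' Axial error per voxel: arccos(|f_est . f_truth|), in degrees (0..90).
#' Voxels where either field is zero (background) are excluded.
#'
#' @param est,truth [OrientationField-class] objects on the same grid.
#' @param mask Optional logical array restricting the comparison.
#' @return List with \code{median}, \code{p95}, \code{mean} (degrees),
#'   \code{n}, and the per-voxel \code{errors} array (NA outside tissue).
#' @export
angularError <- function(est, truth, mask = NULL) {
  stopifnot(is(est, "OrientationField"), is(truth, "OrientationField"))
  d <- dim(est@coherence)
  stopifnot(identical(d, dim(truth@coherence)))
  dot <- est@vectors[, , , 1] * truth@vectors[, , , 1] +
         est@vectors[, , , 2] * truth@vectors[, , , 2] +
         est@vectors[, , , 3] * truth@vectors[, , , 3]
  ne <- sqrt(est@vectors[, , , 1]^2 + est@vectors[, , , 2]^2 + est@vectors[, , , 3]^2)
  nt <- sqrt(truth@vectors[, , , 1]^2 + truth@vectors[, , , 2]^2 + truth@vectors[, , , 3]^2)
  valid <- ne > 1e-9 & nt > 1e-9
  if (!is.null(mask)) valid <- valid & mask
  err <- array(NA_real_, dim = d)
  err[valid] <- acos(pmin(1, abs(dot[valid]) / (ne[valid] * nt[valid]))) * 180 / pi
  e <- err[valid]
  list(median = stats::median(e), p95 = unname(stats::quantile(e, 0.95)),
       mean = mean(e), n = length(e), errors = err)
}
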