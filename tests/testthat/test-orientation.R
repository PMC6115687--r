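# Structure-tensor orientation estimation: tensor construction,
# eigen-extraction, downsampling and angular metrics.

test_that("structure tensor of degenerate volumes has the analytic form", {
  # constant volume -> J = 0 everywhere
  vol <- new("ImageVolume", data = array(0.5, dim = c(12, 12, 12)),
             spacing = 0.0385)
  tf <- computeStructureTensor(vol)
  expect_lt(max(abs(tensorComponents(tf))), 1e-12)

  # 1D ramp along x -> single nonzero eigenvalue with eigenvector (1,0,0)
  d <- c(16, 16, 16)
  ramp <- array(rep(seq_len(d[1]), times = prod(d[2:3])) / d[1], dim = d)
  tf <- computeStructureTensor(new("ImageVolume", data = ramp,
                                   spacing = 0.0385))
  m <- matrix(tensorComponents(tf)[8, 8, 8, ], 1, 6)
  eg <- .eigSym3Batch(m)
  expect_gt(eg$values[1, 1], 0)
  expect_lt(eg$values[1, 2] / eg$values[1, 1], 1e-6)
  expect_lt(axialAngleDeg(eg$vmax, matrix(c(1, 0, 0), 1)), 1)
})

test_that("structure tensor is symmetric positive semi-definite", {
  ph <- makeFiberPhantom(fiberPhantomSpec("helical", c(24, 24, 24),
                                          noiseSd = 0.1, seed = 3L))
  tf <- computeStructureTensor(ph$volume)
  comps <- tensorComponents(tf)
  m <- matrix(comps, ncol = 6)
  eg <- .eigSym3Batch(m)
  scaleTol <- 1e-9 * max(eg$values[, 1])
  expect_gt(min(eg$values[, 3]), -scaleTol)
})

test_that("orientation recovery on phantoms matches the analytic truth", {
  # noiseless parallel phantom: median angular error < 2 degrees
  ph <- makeFiberPhantom(fiberPhantomSpec("parallel", c(32, 32, 32)))
  est <- extractOrientation(computeStructureTensor(ph$volume))
  err <- angularError(est, ph$truth)
  expect_lt(err$median, 2)

  # circular phantom: < 5 degrees away from the axis singularity
  ph <- makeFiberPhantom(fiberPhantomSpec("circular", c(32, 32, 32)))
  est <- extractOrientation(computeStructureTensor(ph$volume))
  n <- c(32, 32, 32)
  cx <- (seq_len(32) - 16.5)
  R <- sqrt(outer(cx^2, cx^2, "+"))
  mask <- array(rep(R > 6, times = 32), dim = n)   # exclude the core
  err <- angularError(est, ph$truth, mask = mask)
  expect_lt(err$median, 5)
})

test_that("isotropic noise yields near-zero coherence", {
  set.seed(11)
  vol <- new("ImageVolume",
             data = array(stats::rnorm(24^3), dim = c(24, 24, 24)),
             spacing = 0.0385)
  est <- extractOrientation(computeStructureTensor(vol))
  expect_lt(stats::median(coherence(est)), 0.1)
})

test_that("extraction is rotation-equivariant for 90-degree grid rotations", {
  ph <- makeFiberPhantom(fiberPhantomSpec("helical", c(24, 24, 24)))
  est <- extractOrientation(computeStructureTensor(ph$volume))
  # rotate the volume 90 degrees about z: (x, y) -> (y, -x)
  rotVol <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  vrot <- new("ImageVolume", data = rotVol(voxelData(ph$volume)),
              spacing = spacing(ph$volume))
  estRot <- extractOrientation(computeStructureTensor(vrot))
  # rotate the unrotated field's vectors and compare on the interior
  v <- orientationVectors(est)
  vr <- orientationVectors(estRot)
  n <- 24
  ang <- c()
  for (i in 5:(n - 5)) for (j in 5:(n - 5)) {
    k <- 12
    pred <- c(-v[j, n + 1 - i, k, 2], v[j, n + 1 - i, k, 1],
              v[j, n + 1 - i, k, 3])
    ang <- c(ang, axialAngleDeg(matrix(vr[i, j, k, ], 1), matrix(pred, 1)))
  }
  expect_lt(stats::median(ang), 2)
})

test_that("angular error increases monotonically with phantom noise", {
  errAt <- function(sd, seed) {
    ph <- makeFiberPhantom(fiberPhantomSpec("parallel", c(24, 24, 24),
                                            noiseSd = sd, seed = seed))
    angularError(extractOrientation(computeStructureTensor(ph$volume)),
                 ph$truth)$median
  }
  meds <- vapply(c(0, 0.15, 0.5), function(sd)
    mean(vapply(1:3, function(s) errAt(sd, s), numeric(1))), numeric(1))
  expect_true(all(diff(meds) > -0.25))  # non-decreasing within sampling error
})

test_that("downsampling averages scalars, votes labels and is axial-safe", {
  # uniform scalar field is unchanged
  vol <- new("ImageVolume", data = array(0.3, dim = c(16, 16, 16)),
             spacing = 0.075)
  dn <- downsampleScalar(vol, 0.15)
  expect_true(all(voxelData(dn) == 0.3))
  expect_equal(spacing(dn), 0.15)

  # labels: majority vote, background loses ties to tissue
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1:2, , ] <- 0L; lab[3:4, , ] <- 5L     # 4^3 block: tie bg/tissue
  lv <- new("LabelVolume", data = lab, spacing = 0.075,
            dictionary = defaultLabelDictionary())
  dn <- downsampleLabels(lv, 0.3)            # 4x4x4 blocks -> 1 voxel
  expect_equal(as.vector(voxelData(dn)[1, 1, 1]), 5L)

  # orientation: a block of +x and -x vectors still averages to +-x
  vec <- array(0, dim = c(4, 4, 4, 3))
  vec[, , , 1] <- rep(c(1, -1), length.out = 64)
  of <- new("OrientationField", vectors = vec,
            coherence = array(1, dim = c(4, 4, 4)), spacing = 0.075)
  dn <- downsampleOrientation(of, 0.15)
  v <- orientationVectors(dn)
  expect_true(all(abs(abs(v[, , , 1]) - 1) < 1e-9))

  # 2x decimation of the parallel phantom leaves angular error unchanged
  # within 1 degree
  ph <- makeFiberPhantom(fiberPhantomSpec("parallel", c(32, 32, 32),
                                          noiseSd = 0.05, seed = 5L))
  est <- extractOrientation(computeStructureTensor(ph$volume))
  full <- angularError(est, ph$truth)$median
  dEst <- downsampleOrientation(est, 2 * spacing(est))
  dTruth <- downsampleOrientation(ph$truth, 2 * spacing(ph$truth))
  half <- angularError(dEst, dTruth)$median
  expect_lt(abs(full - half), 1)
})

test_that("non-integer decimation warns and target below source errors", {
  vol <- new("ImageVolume", data = array(0, dim = c(16, 16, 16)),
             spacing = 0.1)
  expect_warning(downsampleScalar(vol, 0.25), "non-integer")
  expect_error(downsampleScalar(vol, 0.05), ">= source")
})

test_that("angular error metric behaves axially and matches the uniform
           sphere median", {
  ph <- makeFiberPhantom(fiberPhantomSpec("parallel", c(16, 16, 16)))
  # identical fields -> 0; est = -truth -> 0 (axial)
  expect_equal(angularError(ph$truth, ph$truth)$median, 0)
  neg <- ph$truth
  neg@vectors <- -neg@vectors
  expect_equal(angularError(neg, ph$truth)$median, 0)
  # random unit vectors vs fixed truth: |cos theta| is uniform on [0,1]
  # under uniform sphere sampling, so the median error is exactly 60 deg
  set.seed(21)
  n <- c(16, 16, 16)
  raw <- array(stats::rnorm(prod(n) * 3), dim = c(n, 3))
  nrm <- sqrt(raw[, , , 1]^2 + raw[, , , 2]^2 + raw[, , , 3]^2)
  for (k in 1:3) raw[, , , k] <- raw[, , , k] / nrm
  rnd <- new("OrientationField", vectors = raw,
             coherence = array(1, dim = n), spacing = spacing(ph$truth))
  expect_lt(abs(angularError(rnd, ph$truth)$median - 60), 3)
})

test_that("structure-tensor parameter validation", {
  expect_error(structureTensorParams(40, 20), "sigmaWindowUm")
  vol <- new("ImageVolume", data = array(0, dim = c(6, 16, 16)),
             spacing = 0.0385)
  expect_error(computeStructureTensor(vol), "8 voxels")
})
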