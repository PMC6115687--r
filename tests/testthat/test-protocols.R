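# Protocol execution and analysis operators: activation maps, isochrones,
# pathway arrival, propagation direction, capture/block statistics.

# a small phenomenological strand shared across this file
protoStrand <- function() {
  cached("protoStrand",
         strandTissueModel(10, 0.15, dL = 0.08, ratio = 8,
                           modelId = "phenomenological"))
}

test_that("activation maps threshold upstrokes per beat", {
  m <- protoStrand()
  n <- nActiveNodes(m)
  cfg <- solverConfig(dtMs = 0.05, sampleEveryMs = 1)
  # fully quiescent run: all NaN
  r0 <- runSimulation(m, list(), 50, cfg)
  map0 <- computeActivationMap(r0, m)
  expect_true(all(is.nan(activationTimes(map0, 1))))
  # planar wave: activation time is affine in distance
  r <- runSimulation(m, stimulusSpec(40, 2, 0, 1:3), 80, cfg)
  map <- computeActivationMap(r, m)
  act <- activationTimes(map, 1)
  x <- m@coords[, 1]
  sel <- x > 10 & x < 57           # away from stimulus and far end
  fit <- stats::lm(act[sel] ~ x[sel])
  expect_gt(summary(fit)$r.squared, 0.999)
  # re-thresholding at -30 mV shifts times by < 1 ms for a healthy upstroke
  cfg30 <- solverConfig(dtMs = 0.05, sampleEveryMs = 1, thresholdMv = -30)
  r30 <- runSimulation(m, stimulusSpec(40, 2, 0, 1:3), 80, cfg30)
  act30 <- activationTimes(computeActivationMap(r30, m), 1)
  expect_lt(max(abs(act30[sel] - act[sel])), 1)
})

test_that("isochrone bands partition activated nodes with the expected
           count", {
  m <- protoStrand()
  r <- runSimulation(m, stimulusSpec(40, 2, 0, 1:3), 80,
                     solverConfig(dtMs = 0.05))
  map <- computeActivationMap(r, m)
  act <- activationTimes(map, 1)
  rng <- max(act) - min(act)
  # interval larger than the total spread: a single band
  b1 <- isochrones(map, rng * 1.5)
  expect_equal(attr(b1, "nBands"), 1L)
  expect_true(all(b1[!is.nan(act)] == 0L))
  # bands partition the activated nodes
  b <- isochrones(map, 5)
  expect_false(anyNA(b[!is.nan(act)]))
  expect_equal(attr(b, "nBands"), max(b, na.rm = TRUE) + 1L)
  expect_lte(attr(b, "nBands"), ceiling(rng / 5) + 1L)
})

test_that("propagation direction classifies synthetic maps", {
  m <- protoStrand()
  n <- nActiveNodes(m)
  h <- spacing(m)
  centerline <- cbind(seq(0.5, 9.5, by = 0.5), 0.075, 0.075)
  mkMap <- function(times) new("ActivationMap",
                               times = matrix(times, ncol = 1),
                               beats = data.frame(onset = 0, end = 100),
                               threshold = -40)
  xmm <- m@coords[, 1] * h - h / 2
  # times increasing along the strand: anterograde
  expect_equal(as.character(propagationDirection(
    mkMap(xmm * 2), m, centerline, "working_myocardium_RA")), "anterograde")
  # reversed: retrograde
  expect_equal(as.character(propagationDirection(
    mkMap(100 - xmm * 2), m, centerline, "working_myocardium_RA")),
    "retrograde")
  # constant times: none
  expect_equal(as.character(propagationDirection(
    mkMap(rep(5, n)), m, centerline, "working_myocardium_RA")), "none")
  # unactivated: none
  expect_equal(as.character(propagationDirection(
    mkMap(rep(NaN, n)), m, centerline, "working_myocardium_RA")), "none")
})

test_that("pathway arrival on a symmetric two-route toy geometry is
           balanced and NaN for a blocked route", {
  # two identical straight routes from an SN disc to a node disc
  h <- 0.15
  dims <- c(61, 41, 1)
  lab <- array(0L, dim = dims)
  dict <- defaultLabelDictionary()
  # SN at x ~ 5, node at x ~ 55, routes at y = 13 and y = 29
  lab[3:7, 19:23, 1] <- dict[["sinus_node"]]
  lab[53:57, 19:23, 1] <- dict[["compact_AV_node"]]
  lab[5:55, 12:14, 1] <- dict[["slow_pathway"]]
  lab[5:55, 28:30, 1] <- dict[["fast_pathway_septal_bundle"]]
  # connect the routes to the discs
  lab[5:7, 14:19, 1] <- dict[["slow_pathway"]]
  lab[5:7, 23:28, 1] <- dict[["fast_pathway_septal_bundle"]]
  lab[53:55, 14:19, 1] <- dict[["slow_pathway"]]
  lab[53:55, 23:28, 1] <- dict[["fast_pathway_septal_bundle"]]
  lv <- new("LabelVolume", data = lab, spacing = h, dictionary = dict)
  vec <- array(0, dim = c(dims, 3)); vec[, , , 1] <- 1
  of <- new("OrientationField", vectors = vec,
            coherence = array(as.numeric(lab != 0), dim = dims), spacing = h)
  m <- buildTissueModel(lv, of, dL = 0.08, ratio = 8,
                        modelId = "phenomenological", nodalDlScale = 1)
  routes <- list(
    slow = list(labels = "slow_pathway",
                centerline = cbind(c(0.8, 8.2), c(2, 2), h / 2)),
    fast = list(labels = "fast_pathway_septal_bundle",
                centerline = cbind(c(0.8, 8.2), c(4.3, 4.3), h / 2)))
  r <- runSimulation(m, stimulusSpec(40, 2, 0, "sinus_node"), 120,
                     solverConfig(dtMs = 0.05))
  map <- computeActivationMap(r, m)
  rep <- pathwayArrival(map, m, routes)
  # symmetric routes arrive together (within one sample)
  expect_lt(abs(rep$difference), 1)
  expect_equal(unname(rep$direction["slow"]), "anterograde")
  expect_equal(unname(rep$direction["fast"]), "anterograde")
  # sever the fast route at its nodal insertion (no voxel of the route
  # remains adjacent to the node region): arrival NaN, direction "none"
  lab2 <- lab
  lab2[47:57, 23:31, 1] <- 0L
  lv2 <- new("LabelVolume", data = lab2, spacing = h, dictionary = dict)
  m2 <- buildTissueModel(lv2, of, dL = 0.08, ratio = 8,
                         modelId = "phenomenological", nodalDlScale = 1)
  r2 <- runSimulation(m2, stimulusSpec(40, 2, 0, "sinus_node"), 120,
                      solverConfig(dtMs = 0.05))
  rep2 <- pathwayArrival(computeActivationMap(r2, m2), m2, routes)
  expect_true(is.nan(rep2$arrival["fast"]))
  expect_equal(unname(rep2$direction["fast"]), "none")
  expect_true(is.na(rep2$difference))
})

test_that("capture detection and the minimal capturing S2 behave at the
           sweep edges", {
  m <- protoStrand()
  # a sweep where every S2 captures: min of the sweep is returned and the
  # repeated-pacing ratio is 1:1
  prot <- pacingProtocol(s1Count = 2, s1CycleMs = 400,
                         s2SweepMs = c(350, 400), siteLabel = 1:3,
                         observeMs = 300)
  run <- runS1S2(m, prot, solverConfig(dtMs = 0.05))
  bt <- detectBlock(run, m)
  expect_true(all(bt$captured))
  expect_equal(findMinCapturingS2(bt), 350)
  # all-capture pacing train: stimulus:activation ratio 1
  pt <- paceTrain(m, 400, nStim = 3, siteLabel = 1:3,
                  config = solverConfig(dtMs = 0.05))
  expect_equal(pt$ratio, 1)
  # none capturing: NA with diagnostics
  btNone <- data.frame(s2 = c(250, 300), fractionActivated = c(0.1, 0.2),
                       captured = c(FALSE, FALSE))
  res <- findMinCapturingS2(btNone)
  expect_true(is.na(res))
  expect_s3_class(attr(res, "diagnostics"), "data.frame")
})

test_that("protocol validation enforces the S1/S2 contract", {
  expect_error(pacingProtocol(s2SweepMs = c(250, 500)), "<=")
  expect_error(pacingProtocol(s1Count = 0), "s1Count")
  p <- pacingProtocol(s2SweepMs = c(400, 250, 300))
  expect_equal(p$s2SweepMs, c(250, 300, 400))
})
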