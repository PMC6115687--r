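# Shared fixtures: small phantoms and geometries built in code, plus a
# per-session cache for expensive shared computations (CV calibration).

.testCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .testCache))
    assign(key, force(expr), envir = .testCache)
  get(key, envir = .testCache)
}

# compact AVSD geometry for structural unit tests (route physics tests use
# the full default geometry in the acceptance suite)
smallAvsdSpec <- function(...) {
  avsdGeometrySpec(pathLengthSlowMm = 8, pathLengthFastMm = 10,
                   annulusLengthMm = 16, ...)
}

# the calibrated longitudinal diffusion coefficient, shared across tests
calibratedDl <- function() {
  cached("calibration", calibrateDiffusion())
}

# a quick phenomenological-model calibration for cheap tissue tests
phenomDl <- function() {
  cached("phenomCal",
         calibrateDiffusion(modelId = "phenomenological", tolCv = 0.5))
}

expect_unit_vectors <- function(vecArray, mask) {
  nrm <- sqrt(vecArray[, , , 1]^2 + vecArray[, , , 2]^2 + vecArray[, , , 3]^2)
  expect_true(all(abs(nrm[mask] - 1) < 1e-6))
}

# angular difference between two unit-vector arrays (axial), degrees
axialAngleDeg <- function(a, b) {
  d <- pmin(1, abs(rowSums(a * b)))
  acos(d) * 180 / pi
}
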