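# Single-cell ionic kinetics: parameter loading, block-zone scaling,
# stepping and APD/ERP measurement.

.CRN_PARAM_ORDER <- c("gNa", "gK1", "gto", "gKr", "gKs", "gCaL", "gKurScale",
                      "gbNa", "gbCa", "INaKmax", "INaCamax", "IpCamax", "Cm")
.PHEN_PARAM_ORDER <- c("tauIn", "tauOut", "tauOpen", "tauClose", "vGate",
                       "Vrest", "Vamp")

.modelIdInt <- function(modelId) {
  switch(modelId, atrial_detailed = 0L, phenomenological = 1L,
         stop(sprintf("unknown model_id '%s'", modelId)))
}

#' Default stable time step of a cell model (ms)
#' @param modelId "atrial_detailed" or "phenomenological".
#' @return Time step in ms (0.005 detailed, 0.05 phenomenological).
#' @export
defaultCellDt <- function(modelId) {
  if (.modelIdInt(modelId) == 0L) 0.005 else 0.05
}

#' Load a cell parameter set
#'
#' Parameter values are versioned and frozen in JSON data files shipped
#' under \code{extdata/cell_params}; the same call always returns the same
#' set. The CT (bundle) variant of the detailed model differs from RA in
#' its L-type Ca2+ and transient-outward conductances.
#'
#' @param variant "RA" (working myocardium) or "CT" (conduction bundles).
#' @param modelId "atrial_detailed" (default) or "phenomenological".
#' @return A [CellParams-class].
#' @export
makeCellParams <- function(variant = c("RA", "CT"),
                           modelId = c("atrial_detailed", "phenomenological")) {
  variant <- match.arg(variant)
  modelId <- match.arg(modelId)
  path <- system.file("extdata", "cell_params",
                      sprintf("%s_%s.json", modelId, variant),
                      package = "atriasim", mustWork = TRUE)
  js <- jsonlite::fromJSON(path)
  ord <- if (modelId == "atrial_detailed") .CRN_PARAM_ORDER else .PHEN_PARAM_ORDER
  cond <- unlist(js$conductances)
  p <- numeric(length(ord))
  names(p) <- ord
  for (nm in setdiff(ord, "Cm")) {
    if (is.na(cond[nm])) stop(sprintf("parameter file lacks '%s'", nm))
    p[nm] <- cond[[nm]]
  }
  if ("Cm" %in% ord) p["Cm"] <- js$Cm_pF
  st <- unlist(js$initial_state)
  expected <- as.character(.cellStateNames(.modelIdInt(modelId)))
  st <- st[expected]
  names(st) <- expected
  new("CellParams", modelId = modelId, variant = variant, params = p,
      Cm = js$Cm_pF, initState = st, blockScaled = FALSE)
}

#' Apply block-zone conductance scaling
#'
#' Reduces sodium and calcium conductance to 50% of the source set (for
#' the detailed model: gNa and gCaL exactly x0.5, everything else
#' untouched; for the phenomenological fallback the inward time constant
#' is doubled, the equivalent excitability reduction). The result is
#' tagged so the scaling cannot be applied twice.
#'
#' @param p A [CellParams-class].
#' @return A block-scaled [CellParams-class].
#' @export
applyBlockScaling <- function(p) {
  stopifnot(is(p, "CellParams"))
  if (p@blockScaled)
    stop("block scaling has already been applied to this parameter set")
  q <- p@params
  if (p@modelId == "atrial_detailed") {
    q["gNa"] <- 0.5 * q["gNa"]
    q["gCaL"] <- 0.5 * q["gCaL"]
  } else {
    q["tauIn"] <- 2 * q["tauIn"]
  }
  initialize(p, params = q, blockScaled = TRUE)
}

#' Initial (resting) state of a cell parameter set
#' @param p A [CellParams-class].
#' @return Named numeric state vector.
#' @export
initialCellState <- function(p) {
  stopifnot(is(p, "CellParams"))
  p@initState
}

#' Advance a single cell by one time step
#'
#' Gates use an exponential (Rush-Larsen) update and are clamped to
#' [0, 1]; the membrane potential and concentrations advance by a forward
#' step. \code{iExt} is membrane-capacitance-normalized external current
#' in pA/pF, added directly to dV/dt.
#'
#' @param state Named numeric state vector (see [initialCellState()]).
#' @param p A [CellParams-class].
#' @param iExt External stimulus current (pA/pF), depolarizing positive.
#' @param dt Time step in ms; must not exceed the model's stable step.
#' @return The advanced state vector.
#' @export
stepCell <- function(state, p, iExt = 0, dt = defaultCellDt(p@modelId)) {
  stopifnot(is(p, "CellParams"))
  if (dt > defaultCellDt(p@modelId) + 1e-12)
    stop(sprintf("dt = %g ms exceeds the model's stable step %g ms",
                 dt, defaultCellDt(p@modelId)))
  mid <- .modelIdInt(p@modelId)
  r <- .cellRun(mid, unname(p@params), unname(state), dt, dt, 0,
                0, dt, iExt, dt)
  out <- r$finalState
  names(out) <- names(state)
  out
}

#' Integrate a single cell over time
#'
#' @param p A [CellParams-class].
#' @param duration Duration in ms.
#' @param stimuli data.frame with columns onset, dur, amp (ms, ms, pA/pF);
#'   NULL for an unstimulated run.
#' @param dt Time step (ms); defaults to the model's stable step.
#' @param state Initial state; defaults to the resting state.
#' @param sampleEvery Sampling interval of the voltage trace (ms).
#' @param t0 Start time (ms).
#' @return List with \code{time}, \code{V}, \code{dVdtMax}, \code{Vmax},
#'   \code{finalState}, \code{tEnd}.
#' @export
runCell <- function(p, duration, stimuli = NULL,
                    dt = defaultCellDt(p@modelId),
                    state = initialCellState(p), sampleEvery = 0.5, t0 = 0) {
  stopifnot(is(p, "CellParams"), duration > 0)
  if (dt > defaultCellDt(p@modelId) + 1e-12)
    stop(sprintf("dt = %g ms exceeds the model's stable step %g ms",
                 dt, defaultCellDt(p@modelId)))
  if (is.null(stimuli))
    stimuli <- data.frame(onset = numeric(0), dur = numeric(0), amp = numeric(0))
  r <- .cellRun(.modelIdInt(p@modelId), unname(p@params), unname(state),
                dt, duration, t0, stimuli$onset, stimuli$dur, stimuli$amp,
                sampleEvery)
  names(r$finalState) <- names(p@initState)
  r
}

# APD90 of the last action potential in a trace starting at stimOnset
.apd90 <- function(time, V, stimOnset) {
  idx <- which(time >= stimOnset)
  tt <- time[idx]; vv <- V[idx]
  vrest <- vv[1]
  vpeak <- max(vv)
  if (vpeak < 0) return(NA_real_)
  v90 <- vpeak - 0.9 * (vpeak - vrest)
  iup <- which(vv > -40)[1]
  if (is.na(iup)) return(NA_real_)
  idown <- which(tt > tt[iup] & vv <= v90)[1]
  if (is.na(idown)) return(NA_real_)
  tt[idown] - tt[iup]
}

#' Measure APD90 and effective refractory period of a cell
#'
#' Paces \code{nBeats} beats at the given cycle length, measures APD90 on
#' the last paced beat, then finds the ERP by bisecting the S2 coupling
#' interval to 1 ms resolution. An S2 "captures" when its action-potential
#' amplitude exceeds 80% of the S1 amplitude.
#'
#' @param p A [CellParams-class].
#' @param pacingCl Pacing cycle length in ms.
#' @param nBeats Number of conditioning beats (must be >= 1).
#' @param amp,dur Stimulus amplitude (pA/pF) and duration (ms).
#' @param dt Integration step (ms).
#' @return List with \code{apd90}, \code{erp} (ms), \code{s1Amplitude}
#'   (mV) and \code{dVdtMax} of the last S1 beat.
#' @export
measureApdErp <- function(p, pacingCl = 400, nBeats = 4, amp = 20, dur = 2,
                          dt = defaultCellDt(p@modelId)) {
  stopifnot(is(p, "CellParams"))
  if (nBeats < 1) stop("nBeats must be >= 1 (the cell must be paced)")
  onsets <- (seq_len(nBeats) - 1) * pacingCl
  lastOn <- onsets[nBeats]
  # run through the last S1 upstroke, checkpoint shortly after it
  tChk <- lastOn + min(50, pacingCl / 4)
  r1 <- runCell(p, tChk,
                stimuli = data.frame(onset = onsets, dur = dur, amp = amp),
                dt = dt, sampleEvery = max(dt, 0.25))
  rTail <- runCell(p, pacingCl, dt = dt, state = r1$finalState,
                   sampleEvery = max(dt, 0.25), t0 = r1$tEnd)
  timeAll <- c(r1$time, rTail$time)
  vAll <- c(r1$V, rTail$V)
  apd <- .apd90(timeAll, vAll, lastOn)
  vrest <- vAll[which(timeAll >= lastOn)[1]]
  s1Amp <- max(vAll[timeAll >= lastOn]) - vrest

  probe <- function(s2) {
    rs <- runCell(p, s2 + 320, stimuli = data.frame(
      onset = lastOn + s2, dur = dur, amp = amp),
      dt = dt, state = r1$finalState, sampleEvery = max(dt, 0.25),
      t0 = r1$tEnd)
    win <- rs$time >= lastOn + s2
    base <- rs$V[which(win)[1]]
    (max(rs$V[win]) - base) > 0.8 * s1Amp
  }
  lo <- min(60, pacingCl / 4); hi <- pacingCl
  if (probe(lo)) {
    erp <- lo
  } else if (!probe(hi)) {
    erp <- NA_real_
  } else {
    while (hi - lo > 1) {
      mid <- (lo + hi) / 2
      if (probe(mid)) hi <- mid else lo <- mid
    }
    erp <- hi
  }
  list(apd90 = apd, erp = erp, s1Amplitude = s1Amp, dVdtMax = r1$dVdtMax)
}
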