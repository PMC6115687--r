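# Pacing protocols and the headline readouts: activation maps, isochrones,
# dual-pathway nodal arrival, conduction-block statistics and
# retrograde-conduction detection.

#' S1-S2 pacing protocol
#'
#' A train of conditioning S1 stimuli followed by one premature S2 at each
#' coupling interval of a sweep, delivered at the sinus-node site. S1 uses
#' the standard stimulus (20 pA/pF x 2 ms), S2 the fast-pacing stimulus
#' (40 pA/pF x 4 ms).
#'
#' @param s1Count Number of conditioning beats (default 8).
#' @param s1CycleMs S1 cycle length in ms (default 400).
#' @param s2SweepMs Ascending S2 coupling intervals (ms); each must not
#'   exceed the S1 cycle length.
#' @param s1Amplitude,s1Duration Standard stimulus (pA/pF, ms).
#' @param s2Amplitude,s2Duration Fast-pacing stimulus (pA/pF, ms).
#' @param siteLabel Stimulated label (default "sinus_node").
#' @param observeMs Observation window after each S2 (ms).
#' @param captureFraction Fraction of active nodes that must activate
#'   within a beat window for the beat to count as capture (default 0.9).
#' @return A list of class \code{PacingProtocol}.
#' @export
pacingProtocol <- function(s1Count = 8, s1CycleMs = 400,
                           s2SweepMs = c(250, 275, 300, 350, 400),
                           s1Amplitude = 20, s1Duration = 2,
                           s2Amplitude = 40, s2Duration = 4,
                           siteLabel = "sinus_node", observeMs = 400,
                           captureFraction = 0.9) {
  stopifnot(s1Count >= 1, s1CycleMs > 0, length(s2SweepMs) >= 1)
  s2SweepMs <- sort(s2SweepMs)
  if (any(s2SweepMs > s1CycleMs))
    stop("every S2 interval must be <= the S1 cycle length")
  structure(list(s1Count = s1Count, s1CycleMs = s1CycleMs,
                 s2SweepMs = s2SweepMs, s1Amplitude = s1Amplitude,
                 s1Duration = s1Duration, s2Amplitude = s2Amplitude,
                 s2Duration = s2Duration, siteLabel = siteLabel,
                 observeMs = observeMs, captureFraction = captureFraction),
            class = "PacingProtocol")
}

#' Execute an S1-S2 protocol with a shared conditioning train
#'
#' The S1 train is simulated once and checkpointed shortly after the last
#' S1 upstroke; each S2 branch then continues from the checkpoint, so the
#' sweep costs one conditioning train plus one short run per coupling
#' interval.
#'
#' @param model A [TissueModel-class].
#' @param protocol A [pacingProtocol()].
#' @param config A [solverConfig()]; default model-appropriate step.
#' @return A list of class \code{S1S2Run}: \code{s1} (the conditioning
#'   [SimulationResult-class]), \code{branches} (one result per S2, named
#'   by interval), \code{lastS1Onset}, \code{protocol}.
#' @export
runS1S2 <- function(model, protocol,
                    config = solverConfig(
                      dtMs = if (model@modelId == 0L) 0.02 else 0.05)) {
  stopifnot(is(model, "TissueModel"), inherits(protocol, "PacingProtocol"))
  onsets <- (seq_len(protocol$s1Count) - 1) * protocol$s1CycleMs
  lastOn <- onsets[protocol$s1Count]
  site <- .resolveSite(model, protocol$siteLabel)
  s1Stims <- lapply(onsets, function(on)
    stimulusSpec(protocol$s1Amplitude, protocol$s1Duration, on, site))
  tChk <- lastOn + min(50, protocol$s1CycleMs / 4, min(protocol$s2SweepMs) / 2)
  s1res <- runSimulation(model, s1Stims, duration = tChk, config = config)
  branches <- lapply(protocol$s2SweepMs, function(s2) {
    s2on <- lastOn + s2
    runSimulation(model,
                  stimulusSpec(protocol$s2Amplitude, protocol$s2Duration,
                               s2on, site),
                  duration = s2on + protocol$observeMs - s1res@tEnd,
                  config = config, initState = s1res@finalState,
                  t0 = s1res@tEnd)
  })
  names(branches) <- as.character(protocol$s2SweepMs)
  structure(list(s1 = s1res, branches = branches, lastS1Onset = lastOn,
                 protocol = protocol),
            class = "S1S2Run")
}

#' Compute an activation map from a simulation result
#'
#' Activation time per node and beat = first upward crossing of the
#' threshold voltage (default -40 mV, set in the solver config) within
#' the beat window; NaN where the node never crossed.
#'
#' @param result A [SimulationResult-class].
#' @param model The [TissueModel-class] that produced it.
#' @param beats data.frame with columns \code{onset} and \code{end} (ms),
#'   one row per beat; defaults to one beat spanning the whole run.
#' @return An [ActivationMap-class].
#' @export
computeActivationMap <- function(result, model,
                                 beats = data.frame(onset = result@tStart,
                                                    end = result@tEnd)) {
  stopifnot(is(result, "SimulationResult"), is(model, "TissueModel"))
  n <- nActiveNodes(model)
  tm <- vapply(seq_len(nrow(beats)), function(b)
    firstActivation(result, n, c(beats$onset[b], beats$end[b])),
    numeric(n))
  tm <- matrix(tm, nrow = n)
  new("ActivationMap", times = tm, beats = beats,
      threshold = result@config$thresholdMv)
}

#' Isochrone bands of an activation map
#'
#' Band k collects nodes with activation time in
#' [t_min + k * interval, t_min + (k+1) * interval); bands partition the
#' activated nodes.
#'
#' @param map An [ActivationMap-class].
#' @param intervalMs Band width in ms.
#' @param beat Beat number.
#' @return Integer vector of band indices (0-based; NA for nodes that did
#'   not activate), with attribute \code{"nBands"}.
#' @export
isochrones <- function(map, intervalMs, beat = 1) {
  stopifnot(intervalMs > 0)
  t <- map@times[, beat]
  act <- !is.nan(t)
  band <- rep(NA_integer_, length(t))
  if (any(act)) {
    t0 <- min(t[act])
    band[act] <- as.integer(floor((t[act] - t0) / intervalMs))
    rng <- max(t[act]) - t0
    nb <- max(1L, as.integer(ceiling(rng / intervalMs)))
    if (rng > 0 && rng %% intervalMs == 0) nb <- nb  # right-open bands
    band[act][t[act] - t0 >= nb * intervalMs] <- nb - 1L
    attr(band, "nBands") <- max(band[act]) + 1L
  } else attr(band, "nBands") <- 0L
  band
}

#' Direction of propagation along a route centerline
#'
#' Robust (Theil-Sen) slope of activation time against arc length along
#' the centerline, sampled at the nearest route nodes. A positive slope
#' (time increasing from the start of the centerline, i.e. SN to node) is
#' anterograde, a negative slope retrograde; a total time spread below
#' resolution, or too few activated samples, is "none".
#'
#' @param map An [ActivationMap-class].
#' @param model The [TissueModel-class].
#' @param centerline n x 3 matrix of points along the route (mm), ordered
#'   SN -> node.
#' @param routeLabels Label names restricting the sampled nodes.
#' @param beat Beat number.
#' @param minSpreadMs Minimal time spread regarded as directed (ms).
#' @return "anterograde", "retrograde" or "none"; slope (ms/mm) and number
#'   of samples as attributes.
#' @export
propagationDirection <- function(map, model, centerline, routeLabels,
                                 beat = 1, minSpreadMs = 1) {
  stopifnot(is(map, "ActivationMap"), is(model, "TissueModel"))
  codes <- model@dictionary[routeLabels]
  routeNodes <- which(model@labels %in% codes)
  if (length(routeNodes) == 0L) return(structure("none", slope = NA_real_, n = 0L))
  h <- model@spacing
  # resample the polyline at ~h steps
  seg <- diff(centerline)
  segLen <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(segLen))
  sArc <- seq(0, arc[length(arc)], by = h)
  pts <- t(vapply(sArc, function(s) {
    i <- max(which(arc <= s + 1e-12)); i <- min(i, nrow(centerline) - 1L)
    frac <- (s - arc[i]) / max(segLen[i], 1e-12)
    centerline[i, ] + frac * seg[i, ]
  }, numeric(3)))
  nodeMm <- model@coords[routeNodes, , drop = FALSE] * h -  h / 2
  tAct <- map@times[routeNodes, beat]
  samp <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- rowSums(sweep(nodeMm, 2, pts[i, ])^2)
    j <- which.min(d2)
    if (d2[j] > (2 * h)^2) return(NA_real_)
    tAct[j]
  }, numeric(1))
  ok <- !is.na(samp) & !is.nan(samp)
  if (sum(ok) < 3) return(structure("none", slope = NA_real_, n = sum(ok)))
  s <- sArc[ok]; tt <- samp[ok]
  # Theil-Sen slope
  ij <- utils::combn(length(s), 2)
  ds <- s[ij[2, ]] - s[ij[1, ]]
  dtm <- tt[ij[2, ]] - tt[ij[1, ]]
  keep <- abs(ds) > 1e-9
  slope <- stats::median(dtm[keep] / ds[keep])
  spread <- abs(slope) * (max(s) - min(s))
  dir <- if (!is.finite(slope) || spread < minSpreadMs) "none"
         else if (slope > 0) "anterograde" else "retrograde"
  structure(dir, slope = slope, n = sum(ok))
}

#' Pathway arrival report at the compact-node region
#'
#' Earliest activation time, per labelled route, over the route's voxels
#' adjacent (26-neighbourhood) to the compact-node region; the
#' fast-minus-slow difference; the arrival ranking; and per-route
#' propagation direction.
#'
#' @param map An [ActivationMap-class].
#' @param model The [TissueModel-class].
#' @param routes Route metadata as in [routeInfo()] (named list with
#'   \code{labels} and \code{centerline} per route).
#' @param nodeRegionLabel Label of the arrival target region.
#' @param beat Beat number.
#' @return List of class \code{PathwayReport}: \code{arrival} (named ms
#'   vector, NaN = route never reached the node), \code{difference}
#'   (fast - slow, ms; NA unless both arrive), \code{order} (route names
#'   sorted by arrival), \code{direction} (named character vector).
#' @export
pathwayArrival <- function(map, model, routes,
                           nodeRegionLabel = "compact_AV_node", beat = 1) {
  stopifnot(is(map, "ActivationMap"), is(model, "TissueModel"))
  target <- nodesOfLabel(model, nodeRegionLabel)
  if (length(target) == 0L) stop("node region has no active nodes")
  tc <- model@coords[target, , drop = FALSE]
  arrival <- c(); direction <- c()
  for (nm in names(routes)) {
    codes <- model@dictionary[routes[[nm]]$labels]
    rn <- which(model@labels %in% codes)
    adj <- rn[vapply(rn, function(i) {
      d <- abs(sweep(tc, 2, model@coords[i, ]))
      any(apply(d, 1, max) <= 1L)
    }, logical(1))]
    tArr <- if (length(adj)) suppressWarnings(min(map@times[adj, beat],
                                                  na.rm = TRUE)) else NaN
    if (!is.finite(tArr)) tArr <- NaN
    arrival[nm] <- tArr
    direction[nm] <- if (is.nan(tArr)) "none" else
      as.character(propagationDirection(map, model, routes[[nm]]$centerline,
                                        routes[[nm]]$labels, beat))
  }
  diffFS <- if (!is.nan(arrival["fast"]) && !is.nan(arrival["slow"]))
    unname(arrival["fast"] - arrival["slow"]) else NA_real_
  ord <- names(sort(arrival[!is.nan(arrival)]))
  structure(list(arrival = arrival, difference = diffFS, order = ord,
                 direction = direction, beat = beat),
            class = "PathwayReport")
}

#' Conduction-block statistics over an S1-S2 sweep
#'
#' A beat captures when at least \code{captureFraction} of the active
#' nodes activate within its window (from S2 onset to the end of the
#' branch run).
#'
#' @param run An \code{S1S2Run} from [runS1S2()].
#' @param model The [TissueModel-class].
#' @return data.frame with columns \code{s2}, \code{fractionActivated},
#'   \code{captured}.
#' @export
detectBlock <- function(run, model) {
  stopifnot(inherits(run, "S1S2Run"))
  n <- nActiveNodes(model)
  prot <- run$protocol
  rows <- lapply(names(run$branches), function(nm) {
    s2 <- as.numeric(nm)
    res <- run$branches[[nm]]
    s2on <- run$lastS1Onset + s2
    act <- firstActivation(res, n, c(s2on, res@tEnd))
    frac <- mean(!is.nan(act))
    data.frame(s2 = s2, fractionActivated = frac,
               captured = frac >= prot$captureFraction)
  })
  do.call(rbind, rows)
}

#' Smallest capturing S2 interval of a sweep
#'
#' @param blockTable Output of [detectBlock()].
#' @return The smallest S2 (ms) whose beat captured, or NA if none did
#'   (with the table attached as attribute \code{"diagnostics"}).
#' @export
findMinCapturingS2 <- function(blockTable) {
  cap <- blockTable$s2[blockTable$captured]
  if (length(cap) == 0L)
    return(structure(NA_real_, diagnostics = blockTable))
  min(cap)
}

#' Sustained pacing and the stimulus:activation ratio
#'
#' Delivers \code{nStim} fast-pacing stimuli at a fixed coupling interval
#' (optionally after conditioning from a checkpoint state) and counts
#' capturing beats; at intervals below the capture boundary the tissue
#' responds on alternate stimuli and the ratio approaches 2.
#'
#' @param model A [TissueModel-class].
#' @param intervalMs Pacing interval in ms.
#' @param nStim Number of stimuli (>= 10 recommended).
#' @param amplitude,duration Stimulus (default fast pacing 40 pA/pF, 4 ms).
#' @param siteLabel Stimulated label.
#' @param config A [solverConfig()].
#' @param initState,t0 Optional checkpoint to start from (e.g. the final
#'   state of a conditioning train).
#' @param firstOnset Time of the first pacing stimulus (ms); defaults to
#'   \code{t0}. When continuing from a conditioning train, set this to
#'   one pacing interval after the last conditioning beat so every
#'   coupling interval is a multiple of \code{intervalMs}.
#' @param captureFraction Capture criterion per beat.
#' @return List with \code{ratio} (stimuli per capturing beat),
#'   \code{captures} (logical per stimulus), \code{table} (per-beat
#'   activated fraction).
#' @export
paceTrain <- function(model, intervalMs, nStim = 12, amplitude = 40,
                      duration = 4, siteLabel = "sinus_node",
                      config = solverConfig(
                        dtMs = if (model@modelId == 0L) 0.02 else 0.05),
                      initState = NULL, t0 = 0, firstOnset = t0,
                      captureFraction = 0.9) {
  stopifnot(nStim >= 1, intervalMs > 0, firstOnset >= t0)
  site <- .resolveSite(model, siteLabel)
  onsets <- firstOnset + (seq_len(nStim) - 1) * intervalMs
  stims <- lapply(onsets, function(on)
    stimulusSpec(amplitude, duration, on, site))
  res <- runSimulation(model, stims,
                       duration = (firstOnset - t0) + nStim * intervalMs,
                       config = config, initState = initState, t0 = t0)
  n <- nActiveNodes(model)
  frac <- vapply(onsets, function(on) {
    act <- firstActivation(res, n, c(on, on + intervalMs))
    mean(!is.nan(act))
  }, numeric(1))
  captures <- frac >= captureFraction
  list(ratio = nStim / max(1L, sum(captures)), captures = captures,
       table = data.frame(onset = onsets, fractionActivated = frac,
                          captured = captures),
       result = res)
}
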