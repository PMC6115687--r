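---
title: "From image volumes to dual-pathway atrial activation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From image volumes to dual-pathway atrial activation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the design decisions behind
`atriasim`: what is modelled, which parameters matter, what the synthetic
data generator does and does not emulate, and the numerical choices that a
user changing defaults should understand.

## The problem

In hearts with an atrioventricular septal defect (AVSD) the compact AV
node is displaced posterior-inferiorly, to a position anterior to the
coronary sinus ostium. That displacement shortens the atrial conduction
route normally called the "slow" pathway and lengthens the "fast" pathway,
whose distal course runs through a septal muscle bundle and the common
valve annulus. The package reproduces, on synthetic geometry, the
computational chain used to study the electrophysiological consequences:

1. extract per-voxel myocyte orientation from a 3D image volume by
   eigen-analysis of the structure tensor;
2. build a tissue model with region-specific atrial cell types and
   anisotropic diffusion tensors aligned with the myocyte chains;
3. solve the monodomain equation
   \(\partial_t V = \nabla\!\cdot\!(\mathbf{D}\nabla V) - I_\mathrm{ion} + I_\mathrm{stim}\);
4. run S1–S2 pacing protocols and analyse activation maps: nodal arrival
   per pathway, conduction block, and the stimulus:activation ratio.

The original micro-CT dataset behind this modelling chain is not public,
so the package ships a parametric generator (`makeAvsdAtria()`) encoding
the dual-pathway topology, plus fiber phantoms with analytic ground truth
for validating the orientation stage end to end.

## Orientation from the structure tensor

The structure tensor is the Gaussian-window average of the outer product
of Gaussian-derivative gradients,
\(\mathbf{J} = G_{\sigma_w} * (\nabla I)(\nabla I)^{\mathsf T}\).
Intensity varies least *along* a myocyte chain, so the fiber direction is
the eigenvector of the smallest eigenvalue of \(\mathbf{J}\). With
eigenvalues \(\lambda_1 \ge \lambda_2 \ge \lambda_3\), coherence is
\((\lambda_2-\lambda_3)/(\lambda_1+\lambda_2+\lambda_3+\varepsilon)\)
(\(\varepsilon = 10^{-12}\times\) the mean trace): zero for isotropic
texture and for a degenerate smallest eigenpair. Orientation is axial
(\(f\) and \(-f\) are the same direction); a fixed sign convention
(nonnegative \(z\), ties broken by \(y\) then \(x\)) makes outputs
reproducible, and downsampling averages the outer products
\(ff^{\mathsf T}\) rather than the vectors so antipodal vectors do not
cancel.

Defaults: derivative scale 1 voxel, window scale 4 voxels. The literature
behind the method does not fix these scales; both are exposed in
`structureTensorParams()`. Modelling resolution is 0.15 mm, close to the
length of an atrial myocyte; scalar fields are block-averaged, labels
block-majority-voted (background loses ties to tissue).

## Cell models

The detailed ionic model is a Courtemanche-family human atrial
formulation: 21 state variables, Luo–Rudy-style sodium kinetics,
\(I_{to}\), \(I_{Kur}\), \(I_{Kr}\), \(I_{Ks}\), \(I_{K1}\), L-type
calcium current, NCX, NaK pump, SERCA uptake and ryanodine release. Its
parameter sets are frozen in JSON files under `extdata/cell_params/`:

* **RA** — working right-atrial myocardium (baseline set; APD90 near
  300 ms at slow rates, resting potential −81 mV, upstroke
  \(\dot V_{max}\approx 220\) mV/ms);
* **CT** — conduction-bundle variant with \(g_{CaL}\times 1.68\) and
  \(g_{to}\times 1.35\), the regional-heterogeneity multipliers used for
  crista-terminalis-type bundle tissue in the published lineage of this
  model family (longer APD and refractory period than RA);
* **RA_block** — the low-excitability block-zone variant:
  `applyBlockScaling()` multiplies \(g_{Na}\) and \(g_{CaL}\) by exactly
  0.5 and tags the set so the scaling cannot be applied twice. Which
  currents "sodium and calcium conductance" covers is an interpretation;
  the default is fast \(I_{Na}\) and \(I_{CaL}\) only.

A two-variable phenomenological excitable model (Mitchell–Schaeffer-style,
mapped to mV) is included for fast tests and geometry debugging. It never
stands in for the detailed model where refractoriness near 300 ms matters.

Stimuli are expressed in pA/pF and added directly to \(dV/dt\): the
standard protocol is 20 pA/pF for 2 ms, fast pacing 40 pA/pF for 4 ms.
Sinus-node cells are stimulus-driven CT-type cells (the protocols pace the
SN region directly; no autorhythmic kinetics are modelled).

## Tissue model and diffusion tensors

Labels map onto electrophysiological classes: conduction system and all
segmented bundles → CT; working myocardium → RA; block zone → RA_block;
background, fat, connective tissue and surgical patch → inert (no state,
no flux). Virtual suturing (`virtualSuture()`) assigns working-myocardium
characteristics to a dissection gap, restoring conduction across it.

Per node, \(\mathbf{D} = d_t\mathbf{I} + (d_l-d_t)\,ff^{\mathsf T}\) with
\(d_l : d_t = 8:1\) — read as a *coefficient* ratio, so conduction
velocity is anisotropic by about \(\sqrt 8\). The 8:1 ratio is applied to
the tensor eigenvalues; the largest-eigenvalue eigenvector equals \(f\)
exactly. CT bundles share the working-myocardium \(d_l\) by default
(`ctDlScale = 1`), since the calibration contract fixes only the RA
conduction velocity.

**Nodal tissue.** The compact AV node and the conduction axis receive
\(d_l \times 0.05\) (`nodalDlScale`), i.e. a nodal conduction velocity
near 15 cm/s. This encodes standard decremental nodal conduction and has a
methodological role: the pathway-arrival metric reads, per route, the
earliest activation of the route's voxels adjacent to the node region. If
the node conducted at bundle speed, the first wave to arrive would re-exit
through the node into the other routes' tips within a millisecond and the
metric could not resolve which route's own front arrived when. With a
slow node the region remains the *target* of the race rather than a
bypass, while still being able to activate and (slowly) export.

## Monodomain solver

Operator splitting per time step: a reaction substep (Rush–Larsen
exponential updates for gates, forward Euler for V and concentrations)
followed by an explicit diffusion substep. The anisotropic divergence term
uses a 7-point face stencil with harmonic-free face-averaged coefficients
plus centred cross-derivative terms; where a neighbour is missing
(boundary or inert voxel) the normal flux is dropped — zero-flux
boundaries, appropriate for an excised-tissue preparation — and
cross-derivatives fall back to one-sided differences. The one-sided
fallback matters: bundles are only a few voxels wide, and dropping
boundary cross-terms would bias conduction in obliquely oriented bundles
low by ~20%; with the fallback a 45°-oriented ribbon conducts within 2% of
a grid-aligned one.

Stability: explicit diffusion requires
\(\Delta t \le s\, h^2/(2\,\mathrm{tr}\,\mathbf{D}_{max})\) with safety
\(s = 0.9\); `runSimulation()` refuses a violating step and reports the
admissible one. Default steps: 0.005 ms for single-cell work, 0.02–0.025
ms for tissue (the exponential gate update tolerates this; halving the
step changes measured CV by well under 2%, which the property tests
check). Determinism is exact: identical inputs give bit-identical sampled
voltages, and runs are checkpointable through `finalState`/`t0`, which the
S1–S2 driver exploits to share one conditioning train across a whole S2
sweep.

**Calibration.** `calibrateDiffusion()` bisects \(d_l\) (in log space,
since CV \(\propto\sqrt d\)) on a 20 mm fiber-aligned RA strand at
h = 0.15 mm until the CV measured between the 25% and 75% probe points is
68.2 ± 0.1 cm/s, the working-myocardium target. The calibrated coefficient
(≈ 0.18 mm²/ms at the default steps) is a property of the discretization
and the cell model together; only the CV is the contract.

## The synthetic AVSD geometry

`makeAvsdAtria()` rasterizes a thin sheet in which a sinus-node disc and a
compact-node disc are joined by three label-disjoint routes forming a
closed circuit:

* **slow pathway** — straight, default 12 mm, with a transitional fan
  (default 2.5× width over 2.5 mm) spreading into the node, the way
  transitional cells fan toward the compact node;
* **fast pathway / septal bundle** — a circular arc above the chord,
  default 15 mm;
* **valve annulus** — a deeper arc below the chord, default 26 mm, the
  longest route.

Circular arcs are used deliberately: with 8:1 anisotropy a sharp elbow
costs a wavefront ~2.5 ms of cross-fiber transit per corner, whereas an
arc distributes the turning. Even so, curvature and the finite bundle
width make the effective route CV in a curved 0.6 mm ribbon about 10–12%
lower than the planar calibrated value. The default *fast* length is
chosen by the generator's design rule — at calibrated CV the sinus-beat
fast-minus-slow nodal arrival difference falls in the 5–10 ms window —
which with curved-bundle conduction gives 15 mm rather than the ~18 mm a
straight-line estimate would suggest. All lengths remain free parameters
(`avsdGeometrySpec()`), constrained to slow < fast < annulus.

Accessory structures: terminal crest and Bachmann's bundle stubs at the
SN, a conduction-axis stub at the node, a low-excitability block-zone slab
between the SN and the septal bundle (a conduction cul-de-sac, toggleable
via `includeBlockZone`), and small fat / connective-tissue / patch islands
that exercise the attenuation model's contrast ordering
(fat > working myocardium > nodal tissue > connective tissue).

Orientation vectors run along each bundle's local centerline tangent; a
rasterized route that fails to connect SN to node is an error, not a
warning.

## What the defaults reproduce

At the defaults (h = 0.15 mm, detailed cell model, calibrated \(d_l\)),
the package's own tests and acceptance script compute:

* a sinus-driven beat reaches the displaced node **via the slow pathway
  first**, the septal/fast route arriving ~7 ms later (within the 5–10 ms
  window) and the annulus last, all anterograde;
* with 8 conditioning beats at 400 ms cycle length, the smallest capturing
  S2 of the {250, 275, 300, 350, 400} ms sweep is **300 ms**: at 250 ms
  the premature stimulus fails at the sinus-node exit and the atria do not
  activate; at 275 ms activation is partial (the annulus route blocks);
* sustained pacing at 250 ms yields a **2:1** stimulus:activation ratio
  (alternate beats capture);
* the results above are unchanged with the block zone removed.

Problem sizes are modest by design — a ~2,000-node sheet geometry and
100–150-node strands — so the full suite re-runs from scratch in minutes;
the physics at these sizes is the same reaction–diffusion balance that
governs larger grids, and the convergence properties (dt, h refinement)
are asserted separately.

## Known limitations

* **The premature-beat arrival-order flip is not reproduced.** In AVSD
  patients and in patient-specific models, a premature beat at the capture
  boundary can activate the node preferentially via the fast pathway with
  retrograde conduction up the slow pathway — the desynchronized
  dual-pathway substrate of AVNRT. In this generator all routes share cell type, width and
  coupling, so a premature wave experiences the same restitution on every
  route and the sinus arrival order (slow first) is preserved at every
  capturing coupling interval. Design variants with a transitional-fan
  expansion at the slow pathway's nodal insertion (gradual 2.5×, abrupt
  2.5×, abrupt 4×) were evaluated as critical-expansion block substrates
  and none blocks the slow route at the boundary: below 300 ms the wave
  fails globally at the SN exit before route differences can matter, and
  at 300 ms the front is already too robust to fail at an expansion. A
  route-selective flip evidently requires substrate heterogeneity specific
  to the patient anatomy (insertion geometry, local refractoriness
  gradients) that a parametric phantom with uniform bundles deliberately
  does not invent. The test suite retains the corresponding expectation
  and it fails, recording the gap rather than hiding it.
* The capture boundary depends on the ionic formulation and the
  preparation: on a plain RA strand it falls at 275 ms rather than
  300 ms, and a differently parameterized descendant of the same
  Courtemanche family could shift refractoriness by one sweep member.
  The model interface isolates the parameter sets in JSON files precisely
  so an alternative set can be dropped in.
* The geometry is a flattened sheet, not a patient anatomy: path lengths
  and topology, not anatomical shape, drive the modelled results. Whole
  left-atrial structures (appendages, pulmonary veins) and interatrial
  conduction are out of scope.
* The phantom texture (band/periodic patterns plus Gaussian noise) is a
  validation surrogate: it has an analytically known least-variation
  direction but none of a real micro-CT's staining gradients, scanner
  artifacts or partial-volume mixtures, so passing orientation tests bound
  algorithmic error, not real-data error.
* Voxel size and derivative/window scales assume isotropic voxels;
  anisotropic volumes must be resampled upstream (`readVolume()` refuses
  them by default).
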