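Package: atriasim
Title: Myocyte-Orientation Extraction and Anisotropic Monodomain Simulation
    of Atrial Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain from a 3D image volume of
    atrial tissue to pacing-protocol analysis of electrical activation:
    synthetic fiber phantoms and a parametric atrioventricular-septal-defect
    (AVSD) atrial geometry; per-voxel myocyte-orientation estimation by
    eigen-analysis of the 3D structure tensor; assembly of a simulation-ready
    tissue model with region-specific atrial cell types and anisotropic
    diffusion tensors; an explicit operator-splitting monodomain solver with
    a detailed human atrial ionic model and a phenomenological fallback;
    conduction-velocity calibration; and S1-S2 pacing analysis (activation
    maps, isochrones, dual-pathway nodal arrival, conduction block and
    retrograde-conduction detection).
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    RNifti,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
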