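Package: alternansim
Title: Calcium Alternans Mapping and Infarct Border-Zone Fiber Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cardiac alternans from dual voltage/calcium
    optical-mapping movies and for simulating its arrhythmogenic consequences
    in a one-dimensional infarct border-zone fiber. Provides a synthetic
    dual-channel movie generator with known ground-truth alternans structure,
    a per-pixel normalized alternans magnitude (NAM) pipeline with phase maps,
    nodal-line detection, calcium transient duration (CaTD90) measures and
    region summaries, a phenomenological ventricular myocyte model with
    non-infarcted and border-zone phenotypes under graded beta-adrenergic
    stimulation, a monodomain cable integrator, and S1-S2 vulnerable-window
    protocols for conduction block and premature-ventricular-complex
    propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
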