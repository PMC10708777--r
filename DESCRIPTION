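Package: tartes
Title: Tail Artifact Removal in OCT Angiography Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based removal of tail (projection) artifacts from optical
    coherence tomography angiography (OCTA) volumes. Implements the TAR-TES
    layer-recursive transmittance-effect-subtraction corrector together with
    the mean-subtraction and step-down exponential filtering comparators, the
    standard preprocessing chain (Gaussian smoothing and deep-tissue
    noise-floor subtraction), a synthetic vessel phantom generator with exact
    ground-truth corrected angiograms built from the same transmittance
    forward model, and depth-profile metrics (residual fraction, peak shift,
    tail-energy ratio, weight sweeps) for quantitative comparison of the
    correctors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
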