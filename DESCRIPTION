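Package: qpid
Title: Quantitative Particle-Identification Autoradiography Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for quantitative particle-identification
    digital autoradiography with a Timepix3-class pixel detector and a
    coincident gamma scintillator.  Reads list-mode pixel-hit and gamma
    streams, clusters hits into ionization tracks, matches track-gamma
    coincidences, classifies tracks as alpha or beta by energy and cluster
    topology, reconstructs event-map and centroid images in activity or
    spectroscopic scaling, and provides the quantitative layer: spectral
    deconvolution of multi-isotope energy spectra, linearity and efficiency
    fits, decay correction, randoms-rate and signal-to-noise arithmetic,
    and bioequivalence ratios.  A synthetic-source simulator generates
    decay chains, track morphologies and gamma streams with the statistical
    structure the pipeline assumes, so every stage is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
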