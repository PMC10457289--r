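Package: pulsecount
Title: Electron Pulse Counting Simulation and Detector Characterisation for STEM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Software model of real-time electron pulse counting for scanning
    transmission electron microscopy (STEM) detectors. Provides parametric
    single-electron pulse-response kernels (scintillator and solid-state) with
    exponential-decay fitting, Poisson event and analog-trace simulation with
    ADC quantisation, an amplitude- and gradient-domain pulse discriminator
    with consecutive-sample noise suppression and dead time, raster-scan image
    formation producing simultaneous analog and counted images with
    directional spectrum diagnostics for fast-scan streaking, detection
    efficiency studies under pulse pile-up for segmented and monolithic
    detector geometries, and detector-map uniformity metrics (ellipticity,
    flatness, roundness, smoothness).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
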