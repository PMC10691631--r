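Package: fvcdose
Title: Simulation and Quality-Assurance Dosimetry for Fixed Virtual Cone Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale simulator and quality-assurance toolkit for the fixed
    virtual cone (fVC) radiosurgery technique, in which a fixed 0.5 cm x 0.5 cm
    high-definition MLC field is swept over many sine-weighted non-coplanar
    partial arcs to synthesize the spherical dose distribution of a 5 mm
    circular collimator. Provides an analytic beam model (error-function
    aperture fluence, tissue-maximum ratios, small-field output factors) for
    6 MV FFF and 10 MV FFF presets, arc-plan generation with
    sine-of-gantry-angle monitor-unit weighting, voxelized dose superposition
    in a water phantom, small-field dosimetric metrics (FWHM, equivalent
    square field size, isodose equivalent diameters, output-factor and
    leaf-shift sensitivity studies), a global gamma-index comparison with a
    brute-force oracle, and a synthetic diode-array measurement generator so
    the full patient-specific QA battery runs without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    grDevices,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
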