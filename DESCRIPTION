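Package: gawr
Title: Glottal Area Waveform Analysis and Spatial Resolution Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of the glottal area waveform (GAW)
    extracted from laryngeal high-speed videoendoscopy. Generates synthetic
    glottis image stacks with known ground truth, reduces spatial resolution by
    block averaging into recording triads, segments the glottis by seeded
    region growing on a regular grid, detects maximum-based oscillation cycles,
    computes a 50-measure catalogue of vibratory parameters (period, amplitude
    and energy perturbation, left-right symmetry, glottal dynamic
    characteristics and mechanical measures), and runs the repeated-measures
    statistical comparison of parameter values across resolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
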