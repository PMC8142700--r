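Package: glavenstats
Title: Image Statistics and Convergence-Model Analysis for Curved Transparent Objects
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing what drives the colour of curved transparent
    (glass) objects in calibrated images: monitor-calibrated conversions among
    linear RGB, CIE XYZ, CIELAB, LMS cone excitations and the MB-DKL opponent
    space; CIEDE2000 colour differences; region-ratio statistics between
    filtered and unfiltered image regions (ratio of mean cone excitations,
    ratio of standard deviations, and a robust ratio estimator); affine
    convergence-model fitting scored by the relative reduction in prediction
    error; colour vector-field interpolation and streamline tracing; bespoke
    per-object colour summaries (mean, white point, most saturated, most
    frequent, CIEDE2000 threshold maps); and a seeded synthetic-scene
    generator that emulates glass-object stimuli with ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
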