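Package: psdcount
Title: Particle Count Requirements for Precise Particle Size
    Distribution Percentiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how the number of particles measured by electron
    microscopy limits the precision of percentiles (D10-D90) of
    number-based particle size and shape distributions. Implements
    bootstrap subsampling to estimate the count-limited relative expanded
    uncertainty U_N of a percentile as a function of particle count N,
    log-log and monotone spline fits of the precision curve, inversion to
    the minimum particle count N_m for a target precision, power-law
    scaling of N_m with the normalized interquartile range (IQR%),
    polydispersity-based material categories with recommended counts, and
    a total measurement uncertainty budget (intermediate precision,
    trueness, calibration) whose piecewise log-log fit yields the
    breakpoint count N_opt beyond which measuring more particles is
    ineffective. Includes seeded synthetic particle-population generators
    with analytic quantile-precision oracles.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
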