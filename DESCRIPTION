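Package: repaintsim
Title: Simulation and Quantitative Analysis of Repeat DNA-PAINT Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of DNA-PAINT imager binding to
    docking motifs carrying N identical repeat domains, with imager-dependent
    diffuse background, non-specific binding and per-event photoinduced domain
    inactivation. Renders binding-event streams into noisy camera movies,
    localizes blinks by weighted 2D Gaussian fitting, and quantifies the
    resulting data: per-target event rates, non-specific event fractions,
    photoinduced site-loss statistics, qPAINT site counting from dark-time
    exponential-mixture CDF fits, Fourier Ring Correlation resolution curves
    and maps, polymer-tether fluorophore distributions convolved with the Airy
    point-spread function, and a generic Direct Forward Flux Sampling engine
    for rare-event rate estimation on pluggable stochastic models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
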