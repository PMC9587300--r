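Package: mucoswim
Title: Simulation and Analysis of Magnetic Microswimmer Propulsion in Mucus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing the propulsion of chemically
    coated magnetic microparticles driven through mucus by rotating magnetic
    fields. Provides triaxial rotating/static field waveform synthesis, a
    bistable spontaneous-symmetry-breaking propulsion simulator with
    step-out dynamics and spatially heterogeneous mucus mobility, a
    proportional heading controller for waypoint navigation, centroid
    tracking of (synthetic) microscopy frame stacks, and velocity-profile
    analysis with zero-intercept linear fits and standard-error aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
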