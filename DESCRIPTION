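Package: coce
Title: Quantitative Compression Optical Coherence Elastography with a
    Crack-Closure Stress-Strain Law
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative compression optical coherence
    elastography (C-OCE). Converts sequences of complex-valued OCT
    B-scans into phase-difference, incremental-strain and
    cumulative-strain maps; builds stress-strain curves using a
    pre-calibrated linear reference silicone as an optical stress
    sensor; fits a nonlinear constitutive law in which tissue
    nonlinearity arises from gradual closure of compliant crack-like
    interstitial pores; and derives tangent-modulus and
    nonlinearity-parameter elastograms at standardized stress levels.
    Includes an effective-medium toolbox relating pore aspect-ratio and
    closing-stress distributions to the stress-dependent modulus, and a
    seeded speckle-level phantom generator that simulates a
    silicone-over-tissue sample under stepwise uniaxial compression
    with full ground truth for every processing stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
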