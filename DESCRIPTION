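Package: iminokinetics
Title: Base-Pair Opening and Closing Kinetics of Duplex DNA from Imino
    Proton Exchange and Rotating-Frame Relaxation Dispersion NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits CLEANEX-PM water-imino proton exchange build-up curves
    and on-resonance imino 1H R1rho relaxation dispersion profiles of
    double-stranded DNA, normalizes the resulting exchange rates by
    pKa-derived intrinsic exchange factors for epigenetically modified
    cytosine (5-methyl- and 5-hydroxymethylcytosine), and combines both
    experiments into a semi-quantitative comparison of base-pair opening
    equilibria and closing rates across differently modified duplexes.
    Includes a numerical two-state magnetization-exchange simulator
    (coupled two-pool transfer and Bloch-McConnell propagation) that
    generates realistic synthetic studies and serves as an independent
    oracle for the closed-form models, plus helpers for UV melting
    temperature extraction and summaries of helical-parameter
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
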