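Package: csfdyn
Title: Cerebrospinal Fluid Dynamics and Choroid Plexus Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cerebrospinal fluid (CSF) clearance
    physiology in the developing brain. Implements the Marmarou
    lumped-parameter model of CSF dynamics for constant-rate infusion
    tests (forward simulation with cardiac/respiratory pulsation,
    zero-phase low-pass filtering, and bounded nonlinear least-squares
    estimation of outflow resistance and intracranial compliance),
    apical:basal polarity scoring of organelles from traced epithelial
    geometry with Kolmogorov-Smirnov group comparison, cell-swelling
    volumetrics under high-potassium challenge, Seahorse-style
    oxygen-consumption ATP extraction, developmental CSF ion summaries
    with Welch and Sidak statistics, and seeded synthetic-data
    generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
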