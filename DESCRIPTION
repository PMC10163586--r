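Package: animfa
Title: Adaptive-Network SIS Epidemics in the Plane
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the adaptive NIMFA (aNIMFA) planar model of SIS
    epidemics on adaptive contact networks, in which the link density of
    the contact network co-evolves with disease prevalence through
    user-specified link-breaking and link-creation functional responses.
    Provides trajectory simulation with forward-invariance safeguards,
    disease-free and endemic equilibria with Jacobian-based stability
    classification, the basic reproduction number by next-generation
    splitting and by threshold detection, limit-cycle exclusion via the
    Bendixson-Dulac criterion, quadratic-Lyapunov region-of-attraction
    estimation, basin and separatrix computation, and geometric
    singular-perturbation (slow network) analysis including the
    entry-exit map.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
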