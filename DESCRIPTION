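Package: trajmetrics
Title: Conformational Metrics and Nonequilibrium Free-Energy Estimates for MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis of molecular-dynamics trajectories of small GTPase/GEF
    complexes: weighted Kabsch superposition, mass-weighted RMSD time series,
    RMSF and Debye-Waller (B-factor) profiles, a four-Calpha pseudo-dihedral
    metric for helix-helix orientation with circular-statistics summaries, and
    Crooks-Gaussian-Intersection (CGI) estimation of binding free-energy
    differences from bidirectional nonequilibrium work samples, with a Bennett
    acceptance-ratio cross-check and bootstrap errors. Includes seeded synthetic
    generators (ideal helices, fluctuating trajectories, von Mises angle
    ensembles, Crooks-consistent work samples) so every stage is testable
    without archived trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
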