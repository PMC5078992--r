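Package: sptdiff
Title: Single-Particle Tracking Diffusion Analysis with Step-Size CDF
    Mixture Fitting
Version: 0.1.0
Authors@R:
    person("T.", "Keller", email = "tkeller@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-particle tracking (sptPALM)
    data for membrane proteins on rod-shaped bacterial cells. Provides a
    Monte Carlo generator of Brownian tracks on a cylindrical membrane with
    two-state fast/slow switching, TIRF visibility truncation, projection to
    the image plane and localization noise; ensemble mean-squared
    displacement (MSD) estimation with bootstrap uncertainty and permutation
    tests between conditions; and simultaneous multi-lag fitting of the
    step-size cumulative distribution function to one- and two-species
    diffusion models to recover the mobile fraction. A small command-line
    pipeline ties the stages together into reproducible, seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
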