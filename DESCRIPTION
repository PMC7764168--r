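Package: filmrelease
Title: Fickian Release Kinetics of Bioactive Compounds from Biopolymer Films
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the controlled release of a bioactive
    compound (such as cinnamon essential oil) from thin biopolymer films
    into a contacting solvent. Implements the plane-sheet series solution
    of Fick's second law for one-way release, least-squares estimation of
    the diffusion coefficient from cumulative-release curves with RMSE
    goodness-of-fit and bootstrap intervals, series-resistance composition
    and decomposition of layered-film diffusivities, swelling-ratio
    analysis of film mass series, an Einstein mean-squared-displacement
    random-walk check of the diffusion coefficient, one-way ANOVA with
    Tukey compact-letter grouping of fitted coefficients, and a synthetic
    release-curve generator for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    jsonlite
Config/testthat/edition: 3
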