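Package: riverbaci
Title: BACI Analysis of Detritus-Supplementation Experiments in Rivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing large-scale
    Before-After-Control-Impact (BACI) field experiments in which channel
    retentiveness is manipulated to boost benthic detritus in rivers.
    Provides a synthetic-data generator emulating a multi-river staked-site
    experiment, line-intercept retentiveness indices (Linear Coverage Index,
    Trapping Efficiency, effective retentiveness), a three-factor
    repeated-measures BACI ANOVA with a priori treatment contrasts and
    percentage effect sizes, bio-equivalence ratio tests against reference
    sites with Fieller confidence intervals, and permutational community
    analyses (Bray-Curtis, PERMANOVA with design-appropriate permutation,
    pairwise tests, NMDS, SIMPER, centroid trajectories), plus an
    end-to-end pipeline with reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
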