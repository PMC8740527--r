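Package: omrex
Title: Analysis of Dissolved Organic Matter Remineralization Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of seawater dissolved-organic-matter (DOM)
    remineralization incubations: bacterioplankton biomass from cell-image
    dimensions via biovolume-to-carbon power laws, biomass-corrected dissolved
    organic carbon (DOC*) removal and bacterial production rate fitting with
    resolvability gates, bacterial growth efficiency (BGE) with propagated
    uncertainty, total hydrolyzable amino acid degradation indicators
    (degradation index, mol% GABA + beta-alanine), untargeted MS1 feature
    z-score change analysis with process-blank filtering, and 16S amplicon
    sequence variant (ASV) responder, diversity and indicator statistics.
    Includes a synthetic-data generator that emulates the statistical
    structure of dilution-incubation studies so every stage of the pipeline
    is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
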