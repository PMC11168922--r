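Package: consgap
Title: Conservation Gap Analysis for Threatened Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for global conservation-gap analysis of
    threatened species. Reclassifies Red List threat codes into six broad
    threat categories and applies major-threat filters on scope, severity
    and timing; computes area of habitat (AOH) by refining range geometries
    with fractional land-cover and elevation rasters on a planar equal-area
    grid; derives protected-area overlap, species-specific representation
    thresholds and Species Protection Scores, and a binary
    meaningful-habitat-protection determination with a point-occurrence
    fallback for zero-AOH species; decides per-species intervention status
    through a multi-source evidence cascade (Red List tabular and text
    flags, CITES/CMS/EU listings, island invasive-eradication records);
    filters genuine Red List status changes and cross-tabulates uplists and
    downlists against intervention presence; and aggregates results by
    taxon and country with binomial generalized linear models and
    likelihood-ratio inference. Ships a synthetic-world generator with
    planted ground truth so the full pipeline is testable without any
    proprietary data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
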