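Package: regenarray
Title: Multi-Tissue Regeneration Expression Analysis for Two-Channel Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for two-channel (Cy5/Cy3) microarray time
    courses of regenerating tissues. Provides a probe-level synthetic-data
    generator with planted ground truth, spot quality control, intensity-
    dependent (Lowess) ratio normalization, geometric-mean replicate
    aggregation, tiered fold-change differential-expression calling with
    summary tables, hierarchical clustering of tissue/time profiles with
    heatmap and Newick export, class-discriminant RadViz feature selection
    and spring-force projection, EASE-score (penalized hypergeometric) term
    enrichment with redundancy removal, and Pfaffl-method qRT-PCR
    concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ape,
    cluster,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
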