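Package: geoindicate
Title: Microbial Indicator Species for Mineral Exploration Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving mineral-deposit indicator species from 16S
    rRNA OTU tables and mapping them as spatial anomaly surfaces. Implements
    low-count filtering, rarefaction, alpha diversity (observed OTUs, Chao1,
    inverse Simpson), UPGMA clustering of community profiles, LEfSe-style
    indicator-species analysis (Kruskal-Wallis screening plus bootstrapped
    linear-discriminant effect sizes), indicator curation and cross-site
    transfer, response ratios, mean-normalized summed anomaly scores for
    microbial and geochemical (pathfinder element) variables, and a
    label-randomization null. Includes synthetic generators for amendment
    incubation experiments and gridded field surveys over buried
    mineralization, so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
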