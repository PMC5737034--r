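Package: rarebiome
Title: Rare-Biosphere Partitioning, Habitat Specialization and Neutral
    Assembly Analysis for Amplicon OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the community-level analysis of
    rarefied 16S rRNA OTU tables from structured sampling designs (habitats
    crossed with seasons). Partitions taxa into abundant, conditionally rare
    and rare categories with MultiCoLA cutoff-sensitivity profiling;
    classifies habitat generalists and specialists by Levins niche breadth
    and identifies strict habitat specialists by indicator species analysis
    (IndVal) with permutation tests; computes alpha-diversity estimators,
    analytic rarefaction curves and dissimilarity-variability summaries;
    wraps NMDS, ANOSIM, Mantel correlations, RDA with VIF filtering and
    forward selection, three-block variation partitioning and distance-based
    RDA along taxonomic ranks; and fits Sloan's neutral community model to
    occurrence frequency versus mean relative abundance with Wilson score
    envelopes. Includes a synthetic metacommunity generator with known
    ground truth for end-to-end validation, and a pipeline runner driven by
    a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
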