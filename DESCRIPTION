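Package: alleleminer
Title: Association Mapping and Favorable-Allele Mining in Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for marker-trait association mapping
    and favorable-allele mining in inbred germplasm panels genotyped with
    multi-allelic markers (microsatellites/SSRs). Covers per-locus diversity
    statistics (gene diversity, polymorphism information content), model-based
    population-structure selection via the Evanno delta-k statistic with a
    lightweight admixture EM, Loiselle pairwise kinship, multi-allelic linkage
    disequilibrium r-squared with background-percentile and logarithmic decay
    fitting, multi-environment phenotype ANOVA with variance components and
    broad-sense heritability, a Q+K mixed linear model marker scan (EMMA-style
    REML with P3D marker tests) under Bonferroni and multi-environment
    stability filtering, per-allele phenotypic effect estimation with
    favorable-allele calls, and founder-to-modern allele transmission
    classification across cultivar era groups. A seeded synthetic-panel
    generator produces genotypes, maps, phenotypes and a truth record with the
    statistical structure the analysis assumes, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
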