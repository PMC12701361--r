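Package: screentier
Title: Integrated Phenotypic and Proteomic Perturbation-Screen Analytics for Target Tiering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for gene-knockdown validation screens in
    cellular models. Calls phenotype hits from multi-batch assay readouts with
    batch random-effect models, computes per-protein differential abundance
    from knockdown proteomes (one-way ANOVA with Tukey HSD contrasts), runs
    preranked gene-set enrichment with a permutation null, scores per-biodomain
    concordance or reversal of a reference disease signature (Kendall tau-b on
    zero-filled enrichment scores and Pearson correlation of protein effects),
    correlates assay effect sizes with term enrichment across knockdowns, and
    tiers candidate therapeutic targets. Includes a synthetic-data generator
    with known ground truth for end-to-end calibration and power assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
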