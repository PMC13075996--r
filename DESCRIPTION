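Package: pcitnet
Title: Microbial Co-Association Networks and Minimal Predictor Selection
    for Livestock Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds partial-correlation-and-information-theory (PCIT)
    co-association networks over amplicon sequence variants (ASVs) and
    continuous animal phenotypes (feed efficiency, methane yield,
    acetate:propionate ratio), and selects minimal microbial predictor
    panels by all-subsets regression. Includes cumulative sum scaling
    (CSS) and centred log-ratio (CLR) abundance transforms, the RV
    configuration-correlation coefficient, Chao1 and Bray-Curtis
    diversity with PCoA and a permutation PERMANOVA, hypergeometric
    family enrichment of phenotype-connected ASVs, random-subset
    baselines and k-fold cross-validation, plus a seeded synthetic count
    generator with planted direct and mediated microbe-phenotype effects
    so every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
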