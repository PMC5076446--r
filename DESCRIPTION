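Package: casteGSEA
Title: Caste- and Age-Biased Expression Analysis with Signed-P Gene Set
    Enrichment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-expression and enrichment analysis for factorial
    caste-by-age RNA-seq designs in social insects. Provides a negative
    binomial GLM with TMM normalisation and trended/tagwise dispersion
    shrinkage, signed-P ranked gene lists, a running-sum Gene Set
    Enrichment Analysis with a resampling null distribution, two-tailed
    Kolmogorov-Smirnov GO-term enrichment with local false discovery rate
    calibration, reciprocal-best-hit gene identification from tabular
    similarity-search output, and a negative binomial count simulator that
    emulates the full study design for calibration and power testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
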