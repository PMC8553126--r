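Package: leafgwas
Title: Multivariate Linear Mixed Model GWAS of Leaf Shape in Clonally
    Replicated F1 Tree Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of leaf shape in
    outbred F1 tree pedigrees grown as clonal replicates in randomized
    complete block designs. Implements image-based leaf morphometrics
    (contour extraction, orientation normalization, regular polar radii and
    classic size traits), F1 segregation-type classification with Mendelian
    and missingness filters, windowed r-squared LD pruning, restricted
    maximum likelihood estimation of genetic and residual covariance
    matrices on a full-sib clone kinship, the multivariate F-test genome
    scan with genomic control and Bonferroni thresholds on independent
    tests, and a synthetic-data generator (Mendelian F1 crosses with
    Haldane recombination, block-design phenotypes, parametric leaf
    silhouettes) so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
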