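Package: mosaicpop
Title: Fine-Scale Population Structure, Haplotype Painting, and Admixture
    Dating from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for fine-scale population-structure and
    admixture analysis of diploid SNP genotype data.  Implements
    Weir-Cockerham FST, runs-of-homozygosity scanning, genotype and
    coancestry PCA, Patterson f3/f4/f4-ratio statistics with weighted
    block-jackknife standard errors, a deterministic Li-Stephens
    haplotype painter producing chunk-count and chunk-length coancestry
    matrices, total-variation-distance (TVD) cluster refinement and
    heterogeneity statistics, constrained non-negative least-squares
    ancestry profiles, and weighted-LD exponential-decay admixture
    dating.  A forward simulator (Balding-Nichols sources, single-pulse
    mosaic admixture, Dirichlet copying vectors) provides data with
    known truth so every stage can be validated end to end.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
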