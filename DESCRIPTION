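Package: radclone
Title: Clonality Detection and Population Structure from RAD-Seq SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clonal lineages in reduced-representation (RAD-Seq)
    SNP genotype data through the conservation of heterozygous-locus
    positions between sample pairs, with technical-replicate calibration of
    the clonality threshold. Also provides the surrounding population-genetic
    workflow: VCF input and genotype-level filtering, per-population
    diversity statistics (expected heterozygosity, nucleotide diversity,
    inbreeding coefficient) and Weir-Cockerham Fst, identity-by-state
    distances with PCA, classical MDS and UPGMA clustering, a from-scratch
    admixture model fitted by EM with masked-entry cross-validation for
    choosing the number of ancestral populations, gene-flow-based group and
    subgroup classification, and a genotype simulator (Balding-Nichols
    populations, admixture, clonal lineages, allele dropout, missingness)
    with truth tables for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
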