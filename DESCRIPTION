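Package: hapmeth
Title: Haplotype-Dose DNA Methylation Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how a multi-SNP haplotype,
    coded as 0-2 copies per individual, shapes array-based DNA methylation
    and downstream gene expression. Provides EM estimation of haplotype
    frequencies from unphased genotypes with posterior-mean copy numbers,
    beta-value preprocessing (k-nearest-neighbour imputation, SVD screening
    of technical components, plate residualization), an epigenome-scale
    allele-dose association scan with Benjamini-Hochberg false discovery
    rate control against a fixed number of comparisons, CpG sequence-context
    utilities (CpG-creating/removing alleles, CpG island detection,
    island/shore/shelf classification, probe-SNP interference flags), a
    windowed regional co-methylation statistic with a gene-permutation null,
    methylation-expression integration, and a synthetic two-cohort generator
    for testing every stage without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
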