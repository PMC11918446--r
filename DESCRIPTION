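Package: hgcta
Title: Haplotype-Based Partitioning of Maternal and Fetal Genetic Variance in
    Mother-Child Duos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions the phenotypic variance of pregnancy-related outcomes
    into components attributable to the maternal transmitted (m1), maternal
    non-transmitted (m2) and paternal transmitted (p1) haplotypes of
    mother-child duos (the H-GCTA design), alongside the conventional
    single-GRM design and the quadrant-based M-GCTA design. Provides phased-VCF
    duo resolution, genotype- and haplotype-based genetic relatedness matrices
    with alpha-scaling and LD-based SNP weighting, GCTA-format GRM input and
    output, multi-component average-information REML with restricted and
    unrestricted modes, and a phenotype simulator covering maternal, fetal,
    correlated joint maternal-fetal and parent-of-origin (imprinting)
    architectures with closed-form expected variance fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
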