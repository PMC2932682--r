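Package: outbredtools
Title: Genetic Characterization and Haplotype-Based QTL Mapping of
    Outbred Mouse Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies inbreeding, genetic diversity, linkage
    disequilibrium and population structure in closed outbred mouse
    colonies from diploid biallelic SNP genotypes; reconstructs each
    genome as a probabilistic mosaic of inbred founder haplotypes with a
    hidden Markov model; maps quantitative trait loci within and across
    colonies using single-marker, conditional and founder-dosage scans
    with region-wide permutation thresholds and a shared-founder-effect
    partial F test; and estimates the fraction of colony variants absent
    from an inbred-strain catalogue. A forward-in-time breeding-scheme
    simulator generates founder panels, colonies, phenotypes with planted
    QTLs and variant tables so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    vcfR,
    withr,
    ape,
    cluster,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
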