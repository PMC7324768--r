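Package: tetramap
Title: Bulked-Segregant QTL-Seq and Tetrad-Based Fine Mapping for Haploid Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping a qualitative trait in
    a haploid cross, modelled on bulked-segregant analysis of Pyropia
    gametophytes. Simulates meiosis into ordered tetrads and chimeric blades,
    samples phenotype bulks into pooled allele depths, filters pooled variant
    calls, computes the SNP-index and delta(SNP-index) statistic over sliding
    windows with simulated null confidence intervals, calls and intersects
    candidate regions, performs a single-marker LOD scan with permutation
    thresholds, narrows intervals with recombinant genotypes, and prioritizes
    candidate genes by variant consequence and differential expression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
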