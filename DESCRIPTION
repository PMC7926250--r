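Package: xidyn
Title: Allele-Specific Histone-Mark Accumulation Dynamics on the Inactive X Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the kinetics of repressive histone-mark accumulation
    (H4K20me1, H3K27me3) on the Xist-coated inactive X chromosome from
    allele-specific ChIP-seq-style fragment tables and from live-cell mintbody
    imaging. Provides a synthetic-data generator with known ground truth
    (diploid toy genome with SNPs, sigmoidal allelic accumulation, planted
    chromosome-specific microsatellites, two-channel movies), allele assignment
    and windowed counting, TMM normalization on autosomal peak counts,
    four-parameter log-logistic fitting with ED50/IC35 extraction, window and
    gene classification, metagene profiles, a chromosome-specific sgRNA
    repeat-target search, and Xist-domain enrichment quantification for
    time-lapse movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    EBImage,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    minpack.lm,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
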