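Package: hapase
Title: Haplotype-Resolved Allele-Specific Expression, Methylation and
    Chromatin Contact Analysis at Rearranged Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the allele-specific consequences of an
    enhancer-hijacking translocation at a diploid locus: barcode-based
    (linked-read) haplotype phasing by greedy minimum error correction,
    barcode recruitment and local unitig assembly across rearrangement
    breakpoints, attribution of an inserted cassette to its source within a
    near-identical paralog family, allele-specific read counting with exact
    one-tailed binomial imbalance tests, haplotype-resolved bisulfite CpG
    methylation honouring conversion-strand informativeness, anchor-pair
    chromatin contact quantification with multi-mapping read rescue, and
    single-representative-locus FPKM expression summaries. A deterministic
    two-haplotype locus simulator generates all five assay read types with
    known ground truth, so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
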