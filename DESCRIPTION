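Package: m6atrans
Title: DNA 6mA Methylation and DNA-to-RNA Genotype Transmission Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of how DNA N6-methyladenosine (6mA) methylation relates
    to DNA variants, RNA variants and the transmission of genotypes from DNA
    to RNA. Provides readers for SMRT base-modification GFF calls, gene
    annotation (GFF3/GTF) and single-sample VCFs; depth filtering and
    strand-aware per-gene 6mA density summaries; per-gene variation ratios
    and methylated-variation overlap statistics; classification of paired
    DNA/RNA genotypes into the six transmit types; logistic and linear
    association models on per-gene feature tables; imprinting-gene
    contrasts; and a seeded synthetic-study generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
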