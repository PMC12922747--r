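Package: starrscreen
Title: Design and Analysis of STARR-Seq Variant Reporter Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for massively parallel reporter screens of
    regulatory variants (SNP-STARR-seq and Methyl-STARR-seq). Designs 120-bp
    oligo reporter libraries around common SNPs (minor-allele-frequency
    filtering, LD-proxy expansion, enhancer localization) and around CpG
    windows at H3K27ac peak summits; quantifies oligo counts by insert
    matching; normalizes with median-of-ratios size factors; scores enhancer
    activity as EAS = normalized(RNA + 1)/normalized(DNA); calls preferentially
    active variants with a tangent-line knee-point threshold on ranked log2
    fold changes combined with a replicate-level t test; and integrates calls
    with peak, expression, distance and motif-disruption evidence to
    prioritize context-specific regulatory variants. Includes a full synthetic
    data generator (genome, SNP panel with phased haplotypes, peak sets,
    methylation probe tables, negative-binomial count matrices with planted
    effects) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
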