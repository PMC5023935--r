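Package: wesconcord
Title: Concordance of Clinical Sanger Variants with Whole-Exome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for evaluating the concordance between variants
    reported by clinical Sanger sequencing and whole-exome sequencing (WES)
    calls in the same patients. Provides variant normalization (minimal,
    left-aligned allele representation), HGVS c.-to-genomic coordinate
    resolution, region stratification relative to gene models (coding,
    near-intronic, deep-intronic), per-gene coverage QC with a
    fraction-over-threshold exclusion rule, zygosity-aware matching of a
    clinical truth table against unfiltered VCF calls, adjudication of
    discordances against confirmatory re-sequencing, stratified concordance
    tables with false-negative and false-positive rates, and a seeded
    synthetic-study generator (gene models, reference FASTA, truth tables,
    depth tracks, per-patient VCFs, confirmatory tables) including a
    deterministic benchmark cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
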