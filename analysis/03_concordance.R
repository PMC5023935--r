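#!/usr/bin/env Rscript
# Step 3 — the concordance analysis.
#
# Matches every Sanger-reported truth variant against its patient's
# unfiltered WES calls at the normalized allele level, stratifies by region
# (coding / intronic within 20 bp of an exon / deeper intronic), adjudicates
# discordances against the confirmatory re-sequencing table, and writes the
# stratified concordance table with WES false-negative and Sanger
# false-positive rates over the adequately covered coding variants.

suppressMessages(library(wesconcord))

cohort_dir <- "scratch/cohort"
if (!dir.exists(cohort_dir)) stop("run analysis/01_simulate.R first")

patients <- sub("[.]vcf$", "", list.files(file.path(cohort_dir, "vcf")))
vcfs <- setNames(file.path(cohort_dir, "vcf", paste0(patients, ".vcf")), patients)
depths <- setNames(file.path(cohort_dir, "depth", paste0(patients, ".bedgraph")),
                   patients)

res <- run_concordance(
  truth_path = file.path(cohort_dir, "truth.tsv"),
  vcf_paths = vcfs, depth_paths = depths,
  models_path = file.path(cohort_dir, "genes.tsv"),
  reference_path = file.path(cohort_dir, "reference.fa"),
  confirmatory_path = file.path(cohort_dir, "confirmatory.tsv"),
  out_dir = "results"
)

cat(readLines("results/summary.txt"), sep = "\n")
cat("\nper-variant records -> results/records.tsv\n")
cat("table -> results/concordance_table.tsv, results/concordance.json\n")
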