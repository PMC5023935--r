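#' Per-gene coverage QC across a cohort
#'
#' Evaluates every gene's footprint coverage in the depth track of each
#' patient carrying at least one of its truth variants, then flags genes that
#' are consistently poorly covered: a gene is excluded when its median
#' carrier-patient fraction of footprint bases above `depth_threshold` falls
#' below `min_fraction`.
#'
#' @param tracks_by_patient Named list of `depth_track`s.
#' @param models Named list of `gene_model`s.
#' @param truth Truth-table data.frame (defines which patients carry which
#'   genes); when `NULL`, every gene is evaluated in every track.
#' @param depth_threshold Depth that must be exceeded (default 20).
#' @param min_fraction Minimum adequately covered fraction (default 0.75).
#' @param reference Optional `DNAStringSet` for per-gene footprint GC content.
#' @return A list with `per_patient` (one row per gene x carrier),
#'   `per_gene` (gene, carriers, median fraction, excluded, gc_fraction) and
#'   `excluded_genes` (character vector).
#' @export
compute_gene_coverage <- function(tracks_by_patient, models, truth = NULL,
                                  depth_threshold = 20L, min_fraction = 0.75,
                                  reference = NULL) {
  gene_gc <- function(m) {
    if (is.null(reference)) return(NA_real_)
    fp <- gene_footprint(m)
    seqs <- vapply(seq_len(nrow(fp)), function(i) {
      ref_base_at(reference, m$chrom, fp$start0[i] + 1L, fp$end0[i] - fp$start0[i])
    }, character(1L))
    gc_content(paste0(seqs, collapse = ""))
  }
  per_patient <- list()
  per_gene <- list()
  for (g in names(models)) {
    m <- models[[g]]
    carriers <- if (is.null(truth)) names(tracks_by_patient)
                else sort(unique(truth$patient_id[truth$gene == g]))
    carriers <- intersect(carriers, names(tracks_by_patient))
    if (length(carriers) == 0L) next
    gc <- gene_gc(m)
    stats <- do.call(rbind, lapply(carriers, function(p) {
      s <- gene_coverage_fraction(tracks_by_patient[[p]], m,
                                  depth_threshold = depth_threshold,
                                  min_fraction = min_fraction,
                                  gc_fraction = gc)
      cbind(patient_id = p, s)
    }))
    per_patient[[g]] <- stats
    med <- stats::median(stats$fraction_over_threshold)
    per_gene[[g]] <- data.frame(
      gene = g, n_carriers = length(carriers),
      footprint_bases = stats$footprint_bases[1L],
      median_fraction_over_threshold = med,
      excluded = med < min_fraction, gc_fraction = gc,
      stringsAsFactors = FALSE
    )
  }
  per_patient <- do.call(rbind, per_patient)
  per_gene <- do.call(rbind, per_gene)
  rownames(per_patient) <- rownames(per_gene) <- NULL
  list(per_patient = per_patient, per_gene = per_gene,
       excluded_genes = sort(per_gene$gene[per_gene$excluded]))
}

#' Run the full concordance analysis on in-memory cohort objects
#'
#' The end-to-end analysis: per-gene coverage QC decides the excluded genes;
#' every truth variant is normalized and matched against its patient's calls;
#' discordances are adjudicated against the confirmatory table when one is
#' supplied; and the stratified concordance table is assembled.
#'
#' @param models,reference,truth,calls_by_patient,tracks_by_patient Cohort
#'   objects (see [generate_cohort()] for their shapes).
#' @param confirmatory Optional confirmatory-sequencing data.frame.
#' @param depth_threshold,min_fraction Coverage-QC thresholds (20x, 0.75).
#' @param low_depth_threshold Depth below which a variant is flagged (10).
#' @param near_max Near/deep intronic boundary in bp (20).
#' @return A list with `records`, `table`, `coverage`, `excluded_genes`,
#'   `wes_false_negative_rate`, `sanger_false_positive_rate`, `thresholds`.
#' @export
analyze_cohort <- function(models, reference, truth, calls_by_patient,
                           tracks_by_patient, confirmatory = NULL,
                           depth_threshold = 20L, min_fraction = 0.75,
                           low_depth_threshold = 10L, near_max = 20L) {
  coverage <- compute_gene_coverage(tracks_by_patient, models, truth,
                                    depth_threshold = depth_threshold,
                                    min_fraction = min_fraction,
                                    reference = reference)
  records <- match_cohort(truth, calls_by_patient, tracks_by_patient, models,
                          reference, excluded_genes = coverage$excluded_genes,
                          low_depth_threshold = low_depth_threshold,
                          near_max = near_max)
  records <- adjudicate(records, confirmatory)
  tab <- concordance_table(records)
  list(records = records, table = tab, coverage = coverage,
       excluded_genes = coverage$excluded_genes,
       wes_false_negative_rate = attr(tab, "wes_false_negative_rate"),
       sanger_false_positive_rate = attr(tab, "sanger_false_positive_rate"),
       thresholds = list(depth_threshold = depth_threshold,
                         min_fraction = min_fraction,
                         low_depth_threshold = low_depth_threshold,
                         near_max = near_max))
}

concordance_json <- function(result) {
  tab <- result$table
  strata <- lapply(seq_len(nrow(tab)), function(i) {
    as.list(tab[i, c("total", "concordant", "discordant_base",
                     "discordant_zygosity", "missing", "indeterminate",
                     "rate_percent")])
  })
  names(strata) <- tab$stratum
  c(strata, list(
    excluded_genes = result$excluded_genes,
    n_genes = nrow(result$coverage$per_gene),
    wes_false_negative_rate = result$wes_false_negative_rate,
    sanger_false_positive_rate = result$sanger_false_positive_rate,
    rate_caveat = attr(tab, "rate_caveat"),
    thresholds = result$thresholds
  ))
}

summary_text <- function(result) {
  tab <- result$table
  pretty <- c(coding = "Coding", intronic_near = "Intronic (<=20 bp)",
              intronic_deep = "Intronic (>20 bp)",
              noncoding_total = "Noncoding (all)", overall = "Overall",
              excluded_genes = "Excluded genes")
  lines <- c(
    "Clinical Sanger variants compared to WES variants",
    sprintf("%-20s %8s %12s %8s", "Stratum", "Total", "Concordant", "Rate(%)"),
    vapply(seq_len(nrow(tab)), function(i) {
      sprintf("%-20s %8d %12d %8.1f", pretty[[tab$stratum[i]]], tab$total[i],
              tab$concordant[i], tab$rate_percent[i])
    }, character(1L))
  )
  if (!is.na(result$wes_false_negative_rate)) {
    lines <- c(lines, "",
               sprintf("WES false-negative rate (coding): %.1f%%",
                       result$wes_false_negative_rate),
               sprintf("Sanger false-positive rate (coding): %.1f%%",
                       result$sanger_false_positive_rate),
               attr(tab, "rate_caveat"))
  }
  lines
}

#' Run the concordance pipeline from files and write reports
#'
#' File-driven entry point: reads the gene models, reference, truth table,
#' per-patient VCFs and depth tracks (named by patient id), and the optional
#' confirmatory table; runs [analyze_cohort()]; writes under `out_dir`:
#' `records.tsv` (per-variant verdicts), `concordance_table.tsv`,
#' `concordance.json`, `gene_coverage.tsv`, `rejects.tsv`, `summary.txt` and
#' `run_log.txt` (every threshold used). Every number in the rendered reports
#' is recomputable from `records.tsv`.
#'
#' @param truth_path,models_path,reference_path,confirmatory_path File paths
#'   (`confirmatory_path` may be `NULL`).
#' @param vcf_paths,depth_paths Named character vectors (patient id -> path).
#' @param out_dir Output directory, created if needed.
#' @param depth_threshold,min_fraction,low_depth_threshold,near_max Thresholds
#'   as in [analyze_cohort()].
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_concordance <- function(truth_path, vcf_paths, depth_paths, models_path,
                            reference_path, confirmatory_path = NULL,
                            out_dir, depth_threshold = 20L, min_fraction = 0.75,
                            low_depth_threshold = 10L, near_max = 20L) {
  models <- read_gene_models(models_path)
  reference <- read_reference(reference_path)
  tt <- read_truth_table(truth_path, models)
  if (nrow(tt$variants) == 0L) warning("empty truth table: reporting zero counts")
  calls_by_patient <- lapply(vcf_paths, read_vcf)
  names(calls_by_patient) <- names(vcf_paths)
  tracks_by_patient <- lapply(depth_paths, read_depth_track)
  names(tracks_by_patient) <- names(depth_paths)
  confirmatory <- if (!is.null(confirmatory_path)) {
    utils::read.delim(confirmatory_path, stringsAsFactors = FALSE,
                      colClasses = c(pos = "integer"))
  }
  result <- analyze_cohort(models, reference, tt$variants, calls_by_patient,
                           tracks_by_patient, confirmatory,
                           depth_threshold = depth_threshold,
                           min_fraction = min_fraction,
                           low_depth_threshold = low_depth_threshold,
                           near_max = near_max)
  result$rejects <- tt$rejects

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$records, file.path(out_dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$table, file.path(out_dir, "concordance_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(concordance_json(result),
                       file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  utils::write.table(result$coverage$per_gene,
                     file.path(out_dir, "gene_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tt$rejects, file.path(out_dir, "rejects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(summary_text(result), file.path(out_dir, "summary.txt"))
  writeLines(c("thresholds used:",
               paste0("  depth_threshold=", depth_threshold),
               paste0("  min_fraction=", min_fraction),
               paste0("  low_depth_threshold=", low_depth_threshold),
               paste0("  near_max=", near_max),
               paste0("  truth=", truth_path),
               paste0("  models=", models_path),
               paste0("  reference=", reference_path),
               paste0("  confirmatory=", if (is.null(confirmatory_path)) "(none)" else confirmatory_path)),
             file.path(out_dir, "run_log.txt"))
  invisible(result)
}

#' Run the coverage QC pipeline from files and write reports
#'
#' Computes the per-gene coverage report and an exceedance summary (fractions
#' of region bases with depth over 10 and over 20) over the exonic region set
#' of the supplied gene models.
#'
#' @param depth_paths Named character vector (patient id -> depth-track path).
#' @param models_path,reference_path File paths (`reference_path` optional).
#' @param truth_path Optional truth table restricting each gene's evaluation
#'   to its carrier patients.
#' @param out_dir Output directory.
#' @param depth_threshold,min_fraction Coverage-QC thresholds.
#' @return A list with `coverage` and `exceedance` (per patient), invisibly.
#' @export
run_coverage <- function(depth_paths, models_path, reference_path = NULL,
                         truth_path = NULL, out_dir,
                         depth_threshold = 20L, min_fraction = 0.75) {
  models <- read_gene_models(models_path)
  reference <- if (!is.null(reference_path)) read_reference(reference_path)
  truth <- if (!is.null(truth_path)) read_truth_table(truth_path, models)$variants
  tracks <- lapply(depth_paths, read_depth_track)
  names(tracks) <- names(depth_paths)
  coverage <- compute_gene_coverage(tracks, models, truth,
                                    depth_threshold = depth_threshold,
                                    min_fraction = min_fraction,
                                    reference = reference)
  exons <- do.call(rbind, lapply(models, function(m) {
    data.frame(chrom = m$chrom, start0 = m$exon_starts, end0 = m$exon_ends,
               stringsAsFactors = FALSE)
  }))
  exceedance <- do.call(rbind, lapply(names(tracks), function(p) {
    s <- coverage_summary(tracks[[p]], exons)
    data.frame(patient_id = p, fraction_over_10 = s$fraction_over_10,
               fraction_over_20 = s$fraction_over_20, stringsAsFactors = FALSE)
  }))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(coverage$per_gene, file.path(out_dir, "gene_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(coverage$per_patient,
                     file.path(out_dir, "gene_coverage_per_patient.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(exceedance, file.path(out_dir, "exceedance_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(coverage = coverage, exceedance = exceedance))
}
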