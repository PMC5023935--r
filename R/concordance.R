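#' Percentage rounded half-up to one decimal
#'
#' Concordance and error rates are reported as percentages rounded half-up to
#' one decimal place (so 97.35 prints as 97.4, never 97.3).
#'
#' @param numerator,denominator Counts.
#' @return Percentage, or `NA` when the denominator is zero.
#' @export
rate_percent <- function(numerator, denominator) {
  if (is.na(denominator) || denominator == 0) return(NA_real_)
  floor(numerator / denominator * 1000 + 0.5) / 10
}

normalize_calls <- function(calls, reference) {
  if (nrow(calls) == 0L) {
    calls$norm_pos <- integer(0); calls$norm_ref <- character(0)
    calls$norm_alt <- character(0)
    return(calls)
  }
  norm <- lapply(seq_len(nrow(calls)), function(i) {
    normalize_allele(calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i], reference)
  })
  calls$norm_pos <- vapply(norm, `[[`, integer(1L), "pos")
  calls$norm_ref <- vapply(norm, `[[`, character(1L), "ref")
  calls$norm_alt <- vapply(norm, `[[`, character(1L), "alt")
  calls
}

#' Match one truth variant against a patient's normalized calls
#'
#' Classification follows the normalized-allele equivalence rule: a call whose
#' normalized position and alleles equal the truth's is `concordant` when the
#' zygosity also agrees and `discordant_zygosity` otherwise; a call at the
#' same normalized position with a different alternate is `discordant_base`;
#' no call at the position is `missing`. Calls elsewhere are never pulled in.
#' Site depth comes from the matched call's DP when present, else from the
#' depth track at the truth position.
#'
#' @param truth One-row data.frame (a truth-table row).
#' @param calls Patient's calls, already passed through the normalizer (with
#'   `norm_pos`, `norm_ref`, `norm_alt` columns).
#' @param track The patient's `depth_track`.
#' @param reference A `DNAStringSet`.
#' @param low_depth_threshold Depth below which a variant is flagged low-depth
#'   (default 10, i.e. flagged when depth < 10).
#' @return A one-row data.frame with `status`, matched-call columns,
#'   `site_depth`, `low_depth`.
#' @export
match_variant <- function(truth, calls, track, reference, low_depth_threshold = 10L) {
  tn <- normalize_allele(truth$chrom, truth$pos, truth$ref, truth$alt, reference)
  at_pos <- calls[calls$chrom == tn$chrom & calls$norm_pos == tn$pos &
                    calls$zygosity != "missing", , drop = FALSE]
  same_allele <- at_pos[at_pos$norm_ref == tn$ref & at_pos$norm_alt == tn$alt, , drop = FALSE]
  if (nrow(same_allele) > 0L) {
    call <- same_allele[1L, ]
    status <- if (identical(call$zygosity, truth$zygosity)) "concordant" else "discordant_zygosity"
  } else if (nrow(at_pos) > 0L) {
    call <- at_pos[1L, ]
    status <- "discordant_base"
  } else {
    call <- NULL
    status <- "missing"
  }
  depth <- if (!is.null(call) && !is.na(call$site_depth)) {
    as.integer(call$site_depth)
  } else {
    position_depth(track, tn$chrom, tn$pos)
  }
  data.frame(
    status = status,
    norm_pos = tn$pos, norm_ref = tn$ref, norm_alt = tn$alt,
    call_alt = if (is.null(call)) NA_character_ else call$norm_alt,
    call_zygosity = if (is.null(call)) NA_character_ else call$zygosity,
    site_depth = depth,
    low_depth = depth < low_depth_threshold,
    stringsAsFactors = FALSE
  )
}

#' Match a whole cohort of truth variants
#'
#' Runs [match_variant()] per patient, attaches the region label and stratum
#' from the gene models, and the gene-exclusion flag.
#'
#' @param truth Truth-table data.frame (`patient_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `zygosity`, ...).
#' @param calls_by_patient Named list (by patient id) of call data.frames as
#'   returned by [read_vcf()].
#' @param tracks_by_patient Named list (by patient id) of `depth_track`s.
#' @param models Named list of `gene_model`s.
#' @param reference A `DNAStringSet`.
#' @param excluded_genes Character vector of genes excluded by coverage QC.
#' @param low_depth_threshold Depth below which a variant is flagged (default 10).
#' @param near_max Near/deep intronic boundary in bp (default 20).
#' @return A data.frame of concordance records: the truth columns plus
#'   `region_category`, `distance_to_exon`, `stratum`, `status`, matched-call
#'   columns, `site_depth`, `low_depth`, `gene_excluded`, `resolution`
#'   (initialised to `"unresolved"`).
#' @export
match_cohort <- function(truth, calls_by_patient, tracks_by_patient, models,
                         reference, excluded_genes = character(0),
                         low_depth_threshold = 10L, near_max = 20L) {
  norm_cache <- lapply(calls_by_patient, normalize_calls, reference = reference)
  empty_track <- depth_track(data.frame(chrom = character(0), start0 = integer(0),
                                        end0 = integer(0), depth = integer(0)))
  if (nrow(truth) == 0L) {
    return(data.frame(
      patient_id = character(0), gene = character(0), chrom = character(0),
      pos = integer(0), ref = character(0), alt = character(0),
      zygosity = character(0), region_category = character(0),
      distance_to_exon = integer(0), stratum = character(0),
      status = character(0), norm_pos = integer(0), norm_ref = character(0),
      norm_alt = character(0), call_alt = character(0),
      call_zygosity = character(0), site_depth = integer(0),
      low_depth = logical(0), gene_excluded = logical(0),
      resolution = character(0), stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, , drop = FALSE]
    m <- models[[tr$gene]]
    if (is.null(m)) stop("no gene model for gene '", tr$gene, "'")
    lab <- classify_position(m, tr$pos, near_max = near_max)
    calls <- norm_cache[[tr$patient_id]]
    if (is.null(calls)) calls <- normalize_calls(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), zygosity = character(0),
                 site_depth = integer(0), stringsAsFactors = FALSE), reference)
    track <- tracks_by_patient[[tr$patient_id]]
    if (is.null(track)) track <- empty_track
    verdict <- match_variant(tr, calls, track, reference, low_depth_threshold)
    cbind(tr[, c("patient_id", "gene", "chrom", "pos", "ref", "alt", "zygosity")],
          data.frame(region_category = lab$category,
                     distance_to_exon = lab$distance_to_exon,
                     stratum = region_stratum(lab, near_max),
                     stringsAsFactors = FALSE),
          verdict)
  })
  out <- do.call(rbind, rows)
  out$gene_excluded <- out$gene %in% excluded_genes
  out$resolution <- "unresolved"
  rownames(out) <- NULL
  out
}

#' Adjudicate discordant records against confirmatory re-sequencing
#'
#' The confirmatory table is keyed by (`patient_id`, `chrom`, `pos`) on the
#' normalized truth position and reports the re-sequenced allele
#' (`observed_allele`; equal to `observed_ref` when the site is wild-type)
#' and `observed_zygosity`. Resolutions: a `missing` record whose confirmatory
#' allele supports the truth allele is `sanger_correct` (a WES false
#' negative); one shown wild-type is `wes_correct` (a Sanger false positive);
#' a `discordant_base` matching neither reported allele is `both_incorrect`;
#' zygosity discordances resolve toward whichever zygosity the confirmatory
#' call shows. Records without a confirmatory row stay `unresolved`;
#' confirmatory rows matching no record raise a warning.
#'
#' @param records Concordance records from [match_cohort()].
#' @param confirmatory Data.frame with `patient_id`, `chrom`, `pos`,
#'   `observed_ref`, `observed_allele`, `observed_zygosity`; or `NULL`.
#' @return `records` with the `resolution` column filled in.
#' @export
adjudicate <- function(records, confirmatory = NULL) {
  if (is.null(confirmatory) || nrow(confirmatory) == 0L) return(records)
  rec_key <- paste(records$patient_id, records$chrom, records$norm_pos, sep = ":")
  conf_key <- paste(confirmatory$patient_id, confirmatory$chrom, confirmatory$pos, sep = ":")
  unmatched <- setdiff(conf_key, rec_key)
  if (length(unmatched)) {
    warning("confirmatory rows matching no record: ", paste(unmatched, collapse = ", "))
  }
  idx <- match(rec_key, conf_key)
  for (i in which(!is.na(idx))) {
    cf <- confirmatory[idx[i], ]
    obs_is_ref <- identical(toupper(cf$observed_allele), toupper(cf$observed_ref))
    records$resolution[i] <- switch(records$status[i],
      missing = {
        if (identical(toupper(cf$observed_allele), records$norm_alt[i])) "sanger_correct"
        else if (obs_is_ref) "wes_correct"
        else "both_incorrect"
      },
      discordant_base = {
        if (identical(toupper(cf$observed_allele), records$norm_alt[i])) "sanger_correct"
        else if (!is.na(records$call_alt[i]) &&
                 identical(toupper(cf$observed_allele), records$call_alt[i])) "wes_correct"
        else "both_incorrect"
      },
      discordant_zygosity = {
        if (identical(cf$observed_zygosity, records$zygosity[i])) "sanger_correct"
        else if (!is.na(records$call_zygosity[i]) &&
                 identical(cf$observed_zygosity, records$call_zygosity[i])) "wes_correct"
        else "both_incorrect"
      },
      # concordant records are not re-adjudicated
      records$resolution[i]
    )
  }
  records
}

count_stratum <- function(recs) {
  indeterminate <- recs$status == "discordant_base" & recs$resolution == "both_incorrect"
  data.frame(
    total = nrow(recs),
    concordant = sum(recs$status == "concordant"),
    discordant_base = sum(recs$status == "discordant_base" & !indeterminate),
    discordant_zygosity = sum(recs$status == "discordant_zygosity"),
    missing = sum(recs$status == "missing"),
    indeterminate = sum(indeterminate)
  )
}

#' Stratified concordance table
#'
#' Builds the per-stratum table: `coding`, `intronic_near`, `intronic_deep`
#' (records in adequately covered genes), `noncoding_total` (the two intronic
#' strata combined), `overall` (all records in adequately covered genes), and
#' `excluded_genes` (all records in genes failing coverage QC, reported only
#' there). The rate is concordant/total as a percentage; a `discordant_base`
#' record adjudicated `both_incorrect` is displayed as indeterminate — kept in
#' the stratum total but never in the concordance numerator. When any record
#' has been adjudicated, scalar WES false-negative and Sanger false-positive
#' rates over included coding variants are attached as attributes
#' `wes_false_negative_rate` and `sanger_false_positive_rate` (percent), with
#' the caveat that these are not false positives/negatives in the traditional
#' clinically-relevant sense, but miscalls of polymorphisms and variants of
#' unknown significance.
#'
#' @param records Concordance records, adjudicated or not.
#' @param excluded_genes Character vector of genes excluded by coverage QC
#'   (defaults to the genes already flagged on the records).
#' @return A data.frame with one row per stratum and columns `stratum`,
#'   `total`, `concordant`, `discordant_base`, `discordant_zygosity`,
#'   `missing`, `indeterminate`, `rate_percent`.
#' @export
concordance_table <- function(records, excluded_genes = NULL) {
  if (!is.null(excluded_genes)) {
    records$gene_excluded <- records$gene %in% excluded_genes
  }
  inc <- records[!records$gene_excluded, , drop = FALSE]
  exc <- records[records$gene_excluded, , drop = FALSE]
  strata <- list(
    coding = inc[inc$stratum == "coding", , drop = FALSE],
    intronic_near = inc[inc$stratum == "intronic_near", , drop = FALSE],
    intronic_deep = inc[inc$stratum == "intronic_deep", , drop = FALSE],
    noncoding_total = inc[inc$stratum != "coding", , drop = FALSE],
    overall = inc,
    excluded_genes = exc
  )
  tab <- do.call(rbind, lapply(strata, count_stratum))
  tab <- cbind(stratum = names(strata), tab)
  rownames(tab) <- NULL
  tab$rate_percent <- vapply(seq_len(nrow(tab)), function(i) {
    rate_percent(tab$concordant[i], tab$total[i])
  }, numeric(1L))

  adjudicated <- any(records$resolution != "unresolved")
  n_coding <- tab$total[tab$stratum == "coding"]
  if (adjudicated) {
    fn <- sum(inc$stratum == "coding" & inc$status == "missing" &
                inc$resolution == "sanger_correct")
    fp <- sum(inc$stratum == "coding" & inc$status == "missing" &
                inc$resolution == "wes_correct")
    attr(tab, "wes_false_negative_rate") <- rate_percent(fn, n_coding)
    attr(tab, "sanger_false_positive_rate") <- rate_percent(fp, n_coding)
    attr(tab, "fn_count") <- fn
    attr(tab, "fp_count") <- fp
  } else {
    attr(tab, "wes_false_negative_rate") <- NA_real_
    attr(tab, "sanger_false_positive_rate") <- NA_real_
    attr(tab, "fn_count") <- NA_integer_
    attr(tab, "fp_count") <- NA_integer_
  }
  attr(tab, "rate_caveat") <- paste(
    "False-negative/false-positive rates here refer to polymorphisms and",
    "variants of unknown significance, not to clinically relevant results;",
    "this is not the traditional diagnostic definition.")
  tab
}
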