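# Independent oracles: deliberately naive re-implementations used only to
# check the package's fast paths.

# per-base region classification from the raw interval definitions
oracle_classify <- function(model, pos) {
  p0 <- pos - 1L
  exonic <- unlist(mapply(seq.int, model$exon_starts, model$exon_ends - 1L,
                          SIMPLIFY = FALSE))
  if (p0 %in% exonic) {
    cat_ <- if (!is.na(model$cds_start) && p0 >= model$cds_start && p0 < model$cds_end)
      "coding" else "utr"
    return(list(category = cat_, distance_to_exon = 0L))
  }
  d <- min(abs(p0 - exonic))
  if (p0 < min(exonic) || p0 > max(exonic)) {
    return(list(category = "outside_transcript", distance_to_exon = d))
  }
  list(category = if (d <= 20L) "intronic_near" else "intronic_deep",
       distance_to_exon = d)
}

# exhaustive c.-to-g. map for every exonic position, built from first
# principles: exonic positions in transcript order, split by the CDS bounds
oracle_c_to_g_map <- function(model) {
  g <- unlist(mapply(seq.int, model$exon_starts, model$exon_ends - 1L,
                     SIMPLIFY = FALSE))
  if (model$strand == "-") g <- rev(g)
  in_cds <- g >= model$cds_start & g < model$cds_end
  cds <- g[in_cds]
  before <- g[seq_len(which(in_cds)[1L] - 1L)]
  after_idx <- which(in_cds)[sum(in_cds)]
  after <- if (after_idx < length(g)) g[(after_idx + 1L):length(g)] else integer(0)
  labels <- c(paste0("-", rev(seq_along(before))), as.character(seq_along(cds)),
              if (length(after)) paste0("*", seq_along(after)))
  stats::setNames(c(before, cds, after) + 1L, paste0("c.", labels))
}

# apply an edit to a reference string; returns the edited sequence
apply_variant <- function(refstr, pos, ref, alt) {
  stopifnot(substring(refstr, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substring(refstr, 1L, pos - 1L), alt,
         substring(refstr, pos + nchar(ref)))
}

# enumerate every (pos, ref, alt) representation (allele lengths <= max_len)
# that produces the same edited sequence as the canonical variant
equivalent_representations <- function(refstr, pos, ref, alt, max_len = 6L) {
  target <- apply_variant(refstr, pos, ref, alt)
  out <- list()
  for (p in seq_len(nchar(refstr))) {
    for (reflen in 1:max_len) {
      if (p + reflen - 1L > nchar(refstr)) next
      prefix <- substring(refstr, 1L, p - 1L)
      suffix <- substring(refstr, p + reflen)
      altlen <- nchar(target) - nchar(prefix) - nchar(suffix)
      if (altlen < 1L || altlen > max_len) next
      if (substring(target, 1L, p - 1L) != prefix) next
      if (altlen + p - 1L + nchar(suffix) != nchar(target)) next
      if (substring(target, p + altlen) != suffix) next
      cand_ref <- substring(refstr, p, p + reflen - 1L)
      cand_alt <- substring(target, p, p + altlen - 1L)
      if (cand_ref == cand_alt) next
      if (apply_variant(refstr, p, cand_ref, cand_alt) == target) {
        out[[length(out) + 1L]] <- list(pos = p, ref = cand_ref, alt = cand_alt)
      }
    }
  }
  out
}

# per-base loop over the footprint, expanding the track interval by interval
oracle_coverage_fraction <- function(track, model, thr = 20L) {
  fp <- gene_footprint(model)
  bases <- unlist(mapply(seq.int, fp$start0, fp$end0 - 1L, SIMPLIFY = FALSE))
  depth_at <- vapply(bases, function(b) {
    d <- track[[model$chrom]]
    if (is.null(d)) return(0L)
    hit <- which(d$start0 <= b & b < d$end0)
    if (length(hit)) as.integer(d$depth[hit[1L]]) else 0L
  }, integer(1L))
  sum(depth_at > thr) / length(bases)
}

# direct transcription of the site-calling rules
oracle_caller <- function(ref_reads, alt_reads) {
  total <- ref_reads + alt_reads
  if (total < 3) return("no_call")
  frac <- alt_reads / total
  if (frac < 0.20) return("ref")
  if (frac >= 0.80) return("hom")
  "het"
}

# naive quadratic matcher + table: compares every truth row to every call of
# the same patient, then aggregates counts per stratum by brute force
oracle_concordance_table <- function(truth, calls_by_patient, models,
                                     reference, excluded_genes = character(0)) {
  statuses <- character(nrow(truth))
  strata <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tn <- normalize_allele(truth$chrom[i], truth$pos[i], truth$ref[i],
                           truth$alt[i], reference)
    lab <- oracle_classify(models[[truth$gene[i]]], truth$pos[i])
    strata[i] <- if (lab$category == "coding") "coding"
      else if (lab$distance_to_exon <= 20L) "intronic_near" else "intronic_deep"
    calls <- calls_by_patient[[truth$patient_id[i]]]
    status <- "missing"
    if (!is.null(calls) && nrow(calls)) {
      for (j in seq_len(nrow(calls))) {
        cn <- normalize_allele(calls$chrom[j], calls$pos[j], calls$ref[j],
                               calls$alt[j], reference)
        if (cn$chrom == tn$chrom && cn$pos == tn$pos) {
          if (cn$ref == tn$ref && cn$alt == tn$alt) {
            status <- if (identical(calls$zygosity[j], truth$zygosity[i]))
              "concordant" else "discordant_zygosity"
            break
          } else if (status == "missing") {
            status <- "discordant_base"
          }
        }
      }
    }
    statuses[i] <- status
  }
  excl <- truth$gene %in% excluded_genes
  count_block <- function(sel) {
    c(total = sum(sel), concordant = sum(sel & statuses == "concordant"),
      discordant_base = sum(sel & statuses == "discordant_base"),
      discordant_zygosity = sum(sel & statuses == "discordant_zygosity"),
      missing = sum(sel & statuses == "missing"))
  }
  rbind(coding = count_block(!excl & strata == "coding"),
        intronic_near = count_block(!excl & strata == "intronic_near"),
        intronic_deep = count_block(!excl & strata == "intronic_deep"),
        noncoding_total = count_block(!excl & strata != "coding"),
        overall = count_block(!excl),
        excluded_genes = count_block(excl))
}
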