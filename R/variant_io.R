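#' Read a reference genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that keys records by
#' the first word of each FASTA header.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A `DNAStringSet` named by sequence id.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
  seqs
}

ref_base_at <- function(reference, chrom, start1, len) {
  if (!chrom %in% names(reference)) stop("chromosome '", chrom, "' not in reference")
  n <- length(reference[[chrom]])  # XString length = sequence length
  if (start1 < 1L || start1 + len - 1L > n) stop("position outside chromosome '", chrom, "'")
  as.character(Biostrings::subseq(reference[[chrom]], start1, start1 + len - 1L))
}

#' Normalize a variant to its minimal, left-aligned representation
#'
#' Trims the shared suffix, then the shared prefix (keeping one anchor base
#' for indels), then left-aligns indels by repeated left-shift against the
#' reference while an equivalent representation exists. Idempotent; SNVs pass
#' through unchanged. This is the equivalence engine used to compare
#' Sanger-reported and VCF-reported alleles.
#'
#' @param chrom Chromosome.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate allele strings.
#' @param reference A `DNAStringSet` as from [read_reference()].
#' @return A list `(chrom, pos, ref, alt)` in normalized form.
#' @export
normalize_allele <- function(chrom, pos, ref, alt, reference) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt)) stop("ref and alt are identical at ", chrom, ":", pos)
  observed <- ref_base_at(reference, chrom, pos, nchar(ref))
  if (observed != ref) {
    stop("reference mismatch at ", chrom, ":", pos, ": allele says '", ref,
         "', reference has '", observed, "'")
  }
  repeat {
    # trim shared last base; if one allele empties, extend left from reference
    while (nchar(ref) >= 1L && nchar(alt) >= 1L &&
           substring(ref, nchar(ref)) == substring(alt, nchar(alt)) &&
           !(nchar(ref) == 1L && nchar(alt) == 1L)) {
      ref <- substring(ref, 1L, nchar(ref) - 1L)
      alt <- substring(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) stop("cannot left-extend past the chromosome start at ", chrom)
        pos <- pos - 1L
        b <- ref_base_at(reference, chrom, pos, 1L)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    }
    break
  }
  # trim shared leading bases, keeping one anchor base for indels
  min_keep <- if (nchar(ref) == nchar(alt)) 1L else 2L
  while (nchar(ref) >= min_keep && nchar(alt) >= min_keep &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L) &&
         (nchar(ref) > 1L && nchar(alt) > 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

normalized_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Read a clinical truth table of Sanger-reported variants
#'
#' The truth table is a TSV dialect defined by this package: mandatory header
#' columns `patient_id`, `gene`, `chrom`, `pos`, `ref`, `alt`, `zygosity`
#' (`het`/`hom`), optional `hgvs_c`, `dbsnp_id`, `source_test`; `#` lines are
#' comments. Rows with an empty `pos` but a present `hgvs_c` are resolved via
#' [hgvs_c_to_genomic()] against the supplied gene models. Unresolvable rows
#' are collected into a rejects table, never silently dropped.
#'
#' @param path Path to the TSV.
#' @param models Named list of `gene_model` objects (needed only for rows
#'   lacking a genomic position).
#' @return A list with `variants` (data.frame, one row per resolved input row)
#'   and `rejects` (data.frame with `row`, `patient_id`, `gene`, `reason`).
#' @export
read_truth_table <- function(path, models = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  mandatory <- c("patient_id", "gene", "chrom", "pos", "ref", "alt", "zygosity")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("truth table missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("hgvs_c", "dbsnp_id", "source_test")) {
    if (!opt %in% names(df)) df[[opt]] <- rep(NA_character_, nrow(df))
  }
  df$pos[df$pos == ""] <- NA_character_
  df$hgvs_c[!is.na(df$hgvs_c) & df$hgvs_c == ""] <- NA_character_

  rejects <- data.frame(row = integer(0), patient_id = character(0),
                        gene = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(df))
  pos_out <- suppressWarnings(as.integer(df$pos))
  for (i in seq_len(nrow(df))) {
    if (!is.na(pos_out[i])) next
    if (is.na(df$hgvs_c[i])) {
      rejects <- rbind(rejects, data.frame(row = i, patient_id = df$patient_id[i],
                                           gene = df$gene[i],
                                           reason = "no genomic position and no hgvs_c",
                                           stringsAsFactors = FALSE))
      keep[i] <- FALSE
      next
    }
    m <- models[[df$gene[i]]]
    if (is.null(m)) {
      rejects <- rbind(rejects, data.frame(row = i, patient_id = df$patient_id[i],
                                           gene = df$gene[i],
                                           reason = "no gene model for hgvs_c resolution",
                                           stringsAsFactors = FALSE))
      keep[i] <- FALSE
      next
    }
    g <- tryCatch(hgvs_c_to_genomic(m, df$hgvs_c[i]), error = function(e) e)
    if (inherits(g, "error")) {
      rejects <- rbind(rejects, data.frame(row = i, patient_id = df$patient_id[i],
                                           gene = df$gene[i],
                                           reason = conditionMessage(g),
                                           stringsAsFactors = FALSE))
      keep[i] <- FALSE
    } else {
      pos_out[i] <- g
    }
  }
  bad_zyg <- keep & !df$zygosity %in% c("het", "hom")
  if (any(bad_zyg)) {
    for (i in which(bad_zyg)) {
      rejects <- rbind(rejects, data.frame(row = i, patient_id = df$patient_id[i],
                                           gene = df$gene[i],
                                           reason = paste0("invalid zygosity '", df$zygosity[i], "'"),
                                           stringsAsFactors = FALSE))
    }
    keep <- keep & !bad_zyg
  }
  variants <- data.frame(
    patient_id = df$patient_id, gene = df$gene, chrom = df$chrom,
    pos = pos_out, ref = toupper(df$ref), alt = toupper(df$alt),
    zygosity = df$zygosity, hgvs_c = df$hgvs_c, dbsnp_id = df$dbsnp_id,
    source_test = df$source_test, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, rejects = rejects)
}

#' Write a truth table in the package's TSV dialect
#'
#' @param variants Data.frame as produced by [read_truth_table()]`$variants`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(variants, path) {
  df <- variants
  df$pos[is.na(df$pos)] <- ""
  for (col in c("hgvs_c", "dbsnp_id", "source_test")) df[[col]][is.na(df[[col]])] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

gt_zygosity <- function(gt, allele_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == ".")) return("missing")
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a)) return("missing")
  hits <- sum(a == allele_index)
  if (hits == 0L) return("missing")
  if (hits == length(a)) {
    if (length(a) == 1L) "hemi" else "hom"
  } else "het"
}

#' Read called variants from a VCF
#'
#' Reads a VCF 4.x file via [vcfR::read.vcfR()], selects one sample, splits
#' multi-allelic records into one row per alternate allele, and derives
#' zygosity from the GT field alone (`0/1` het, `1/1` hom, `1/2` het for each
#' alternate, `./.` missing; phased separators treated like unphased). Site
#' depth comes from FORMAT `DP` when present, else INFO `DP`, else `NA` (to be
#' filled from a depth track at lookup time). The FILTER column is ignored:
#' the comparison is made against the unfiltered call set.
#'
#' @param path Path to the VCF.
#' @param sample Sample name; defaults to the first sample column.
#' @return A data.frame of calls: `chrom`, `pos`, `ref`, `alt`, `zygosity`,
#'   `site_depth`, `qual`, `sample`.
#' @export
read_vcf <- function(path, sample = NULL) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to read VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1L]
  if (is.null(sample)) sample <- samples[1L]
  if (!sample %in% samples) stop("sample '", sample, "' not in VCF (has: ",
                                 paste(samples, collapse = ", "), ")")
  gt_field <- vcfR::extract.gt(v, element = "GT")[, sample]
  dp_field <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[, sample],
    error = function(e) rep(NA_real_, n))
  info_dp <- tryCatch(
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP"))),
    error = function(e) rep(NA_real_, n))
  if (length(info_dp) != n) info_dp <- rep(NA_real_, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    dp <- dp_field[i]
    if (is.na(dp)) dp <- info_dp[i]
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    sub <- lapply(seq_along(alts), function(a) {
      data.frame(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                 ref = toupper(fix[i, "REF"]), alt = toupper(alts[a]),
                 zygosity = gt_zygosity(gt_field[i], a),
                 site_depth = as.integer(dp), qual = qual,
                 sample = sample, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write calls as a minimal single-sample VCF
#'
#' Emits a VCF 4.2 file with GT:DP per record; used by the synthetic-study
#' generator and for round-trip testing. Calls with zygosity `het` are written
#' `0/1`, `hom` as `1/1`, `hemi` as `1`.
#'
#' @param calls Data.frame with `chrom`, `pos`, `ref`, `alt`, `zygosity`,
#'   `site_depth` and optional `qual`.
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @param contigs Optional character vector of contig names for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE", contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  if (!is.null(contigs)) header <- c(header, paste0("##contig=<ID=", contigs, ">"))
  header <- c(header, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", sample, sep = "\t"))
  if (nrow(calls)) {
    ord <- order(calls$chrom, calls$pos)
    calls <- calls[ord, , drop = FALSE]
    gt <- c(het = "0/1", hom = "1/1", hemi = "1")[calls$zygosity]
    qual <- if ("qual" %in% names(calls)) ifelse(is.na(calls$qual), ".", calls$qual) else "."
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, qual, ".", ".",
                  "GT:DP", paste0(gt, ":", calls$site_depth), sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
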