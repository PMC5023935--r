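#' Construct a gene model
#'
#' A gene model carries the exon structure of a single transcript, its strand,
#' and optional CDS bounds. Exons are stored in genomic order as 0-based,
#' half-open intervals; all user-facing variant positions elsewhere in the
#' package are 1-based (VCF convention).
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   bounds, sorted by start and pairwise disjoint.
#' @param cds_start,cds_end 0-based half-open CDS bounds within the exon
#'   union's span, or `NA` for a noncoding transcript.
#' @param flank_pad Flank, in bp, added to each exon when computing the
#'   coverage footprint (default 20).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, exon_starts, exon_ends,
                       cds_start = NA, cds_end = NA, flank_pad = 20L) {
  m <- structure(
    list(
      gene = as.character(gene),
      chrom = as.character(chrom),
      strand = as.character(strand),
      exon_starts = as.integer(exon_starts),
      exon_ends = as.integer(exon_ends),
      cds_start = if (is.na(cds_start)) NA_integer_ else as.integer(cds_start),
      cds_end = if (is.na(cds_end)) NA_integer_ else as.integer(cds_end),
      flank_pad = as.integer(flank_pad)
    ),
    class = "gene_model"
  )
  validate_gene_model(m)
  m
}

#' Validate a gene model's structural invariants
#'
#' @param m A `gene_model`.
#' @return `m`, invisibly; throws on violation.
#' @export
validate_gene_model <- function(m) {
  if (!inherits(m, "gene_model")) stop("not a gene_model")
  ns <- length(m$exon_starts)
  if (ns == 0L || ns != length(m$exon_ends)) {
    stop("gene_model '", m$gene, "': exon start/end vectors empty or unequal")
  }
  if (!m$strand %in% c("+", "-")) {
    stop("gene_model '", m$gene, "': strand must be '+' or '-'")
  }
  if (any(m$exon_ends <= m$exon_starts)) {
    stop("gene_model '", m$gene, "': empty or inverted exon")
  }
  if (is.unsorted(m$exon_starts, strictly = TRUE)) {
    stop("gene_model '", m$gene, "': exons not sorted by start")
  }
  if (ns > 1L && any(m$exon_starts[-1L] < m$exon_ends[-ns])) {
    stop("gene_model '", m$gene, "': overlapping exons")
  }
  if (min(m$exon_starts) - m$flank_pad < 0L) {
    stop("gene_model '", m$gene, "': footprint would reach negative coordinates")
  }
  has_cds <- !is.na(m$cds_start) || !is.na(m$cds_end)
  if (has_cds) {
    if (is.na(m$cds_start) || is.na(m$cds_end) || m$cds_end <= m$cds_start) {
      stop("gene_model '", m$gene, "': invalid CDS bounds")
    }
    if (m$cds_start < min(m$exon_starts) || m$cds_end > max(m$exon_ends)) {
      stop("gene_model '", m$gene, "': CDS outside the exon span")
    }
  }
  invisible(m)
}

#' Coverage footprint of a gene model
#'
#' The footprint is the union of exons, each widened by `flank_pad` bp, merged
#' into disjoint intervals. This is the base set over which per-gene coverage
#' fractions are computed.
#'
#' @param model A `gene_model`.
#' @return A data.frame with 0-based half-open columns `start0`, `end0`.
#' @export
gene_footprint <- function(model) {
  validate_gene_model(model)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = model$exon_starts - model$flank_pad + 1L,  # to 1-based closed
    end = model$exon_ends + model$flank_pad
  ))
  data.frame(start0 = IRanges::start(ir) - 1L, end0 = IRanges::end(ir))
}

#' Classify a genomic position relative to a gene model
#'
#' Positions are labelled `coding` (exonic, inside the CDS), `utr` (exonic,
#' outside the CDS), `intronic_near` (first to twentieth intronic base from
#' the closer flanking exon), `intronic_deep` (further than 20 bp), or
#' `outside_transcript` (before the first or after the last exon, with the
#' distance measured from the transcript edge). Distances follow the HGVS
#' convention: the first intronic base on either side of an exon has
#' distance 1; exonic positions have distance 0.
#'
#' @param model A `gene_model`.
#' @param pos 1-based genomic position (scalar).
#' @param near_max Largest distance, in bp, still counted as "near" (default 20).
#' @return A list with `category` and `distance_to_exon`.
#' @export
classify_position <- function(model, pos, near_max = 20L) {
  validate_gene_model(model)
  if (length(pos) != 1L || is.na(pos) || pos < 1) stop("pos must be a positive scalar")
  p0 <- as.integer(pos) - 1L
  starts <- model$exon_starts
  ends <- model$exon_ends
  in_exon <- which(p0 >= starts & p0 < ends)
  if (length(in_exon) == 1L) {
    coding <- !is.na(model$cds_start) && p0 >= model$cds_start && p0 < model$cds_end
    return(list(category = if (coding) "coding" else "utr",
                distance_to_exon = 0L))
  }
  if (p0 < starts[1L]) {
    return(list(category = "outside_transcript",
                distance_to_exon = starts[1L] - p0))
  }
  n <- length(ends)
  if (p0 >= ends[n]) {
    return(list(category = "outside_transcript",
                distance_to_exon = p0 - ends[n] + 1L))
  }
  # intronic: between the exon ending at or before p0 and the next exon
  i <- max(which(ends <= p0))
  d_left <- p0 - ends[i] + 1L
  d_right <- starts[i + 1L] - p0
  d <- min(d_left, d_right)
  list(category = if (d <= near_max) "intronic_near" else "intronic_deep",
       distance_to_exon = d)
}

#' Reporting stratum of a region label
#'
#' Maps a region label to the strata used in the concordance table: `coding`
#' stays `coding`; every noncoding label (`utr`, intronic, outside the
#' transcript) is binned by distance into `intronic_near` (<= `near_max` bp)
#' or `intronic_deep` (> `near_max` bp). Exonic UTR positions have distance 0
#' and therefore fall in the near bin.
#'
#' @param label A list as returned by [classify_position()].
#' @param near_max Bin boundary in bp (default 20).
#' @return One of `"coding"`, `"intronic_near"`, `"intronic_deep"`.
#' @export
region_stratum <- function(label, near_max = 20L) {
  if (label$category == "coding") return("coding")
  if (label$distance_to_exon <= near_max) "intronic_near" else "intronic_deep"
}

# ---- HGVS c. <-> genomic ---------------------------------------------------

# Exonic genomic positions (0-based) in transcript orientation, split into
# 5'UTR / coding / 3'UTR blocks. Requires CDS bounds.
tx_blocks <- function(model) {
  if (is.na(model$cds_start)) stop("gene_model '", model$gene, "': no CDS; c. numbering undefined")
  g <- unlist(mapply(function(s, e) seq.int(s, e - 1L), model$exon_starts,
                     model$exon_ends, SIMPLIFY = FALSE), use.names = FALSE)
  if (model$strand == "-") g <- rev(g)
  in_cds <- g >= model$cds_start & g < model$cds_end
  cds_idx <- which(in_cds)
  list(utr5 = g[seq_len(cds_idx[1L] - 1L)],
       cds = g[cds_idx],
       utr3 = if (cds_idx[length(cds_idx)] < length(g))
         g[(cds_idx[length(cds_idx)] + 1L):length(g)] else integer(0))
}

parse_hgvs_c <- function(cdna_string) {
  m <- regexec("^c\\.(\\*?-?[0-9]+)([+-][0-9]+)?$", cdna_string)
  parts <- regmatches(cdna_string, m)[[1L]]
  if (length(parts) == 0L) stop("cannot parse HGVS c. string: '", cdna_string, "'")
  anchor <- parts[2L]
  offset <- if (parts[3L] == "") 0L else as.integer(parts[3L])
  if (startsWith(anchor, "*")) {
    list(zone = "utr3", n = as.integer(substring(anchor, 2L)), offset = offset)
  } else {
    n <- as.integer(anchor)
    if (n < 0L) list(zone = "utr5", n = -n, offset = offset)
    else if (n == 0L) stop("cannot parse HGVS c. string: '", cdna_string, "': position 0 does not exist")
    else list(zone = "cds", n = n, offset = offset)
  }
}

#' Resolve an HGVS c. position to a genomic coordinate
#'
#' Walks the coding positions of the transcript in transcript orientation
#' (strand-aware). Supports coding positions (`c.76`), intronic offsets from
#' the adjacent exon boundary (`c.76+9`, `c.77-3`), 5'UTR (`c.-30`) and 3'UTR
#' (`c.*12`) numbering. UTR numbering beyond the transcribed UTR continues
#' genomically past the transcript edge, so positions upstream of the first
#' exon or downstream of the last one are representable.
#'
#' @param model A `gene_model` with CDS bounds.
#' @param cdna_string An HGVS c. position string.
#' @return 1-based genomic coordinate.
#' @export
hgvs_c_to_genomic <- function(model, cdna_string) {
  validate_gene_model(model)
  p <- parse_hgvs_c(cdna_string)
  bl <- tx_blocks(model)
  sgn <- if (model$strand == "+") 1L else -1L   # genomic step per transcript step

  anchor_g <- switch(p$zone,
    cds = {
      if (p$n > length(bl$cds)) stop("'", cdna_string, "': coding position beyond CDS length ", length(bl$cds))
      bl$cds[p$n]
    },
    utr5 = {
      k <- p$n
      if (k <= length(bl$utr5)) bl$utr5[length(bl$utr5) - k + 1L]
      else {
        # continue genomically upstream of the transcript start
        first_g <- if (length(bl$utr5)) bl$utr5[1L] else bl$cds[1L]
        extra <- k - length(bl$utr5)
        tx_start_edge <- if (model$strand == "+") min(model$exon_starts) else max(model$exon_ends) - 1L
        if (first_g != tx_start_edge) first_g <- tx_start_edge  # defensive; equal by construction
        g <- tx_start_edge - sgn * extra
        if (g < 0L) stop("'", cdna_string, "': walks past the chromosome start")
        return(g + 1L)
      }
    },
    utr3 = {
      k <- p$n
      if (k <= length(bl$utr3)) bl$utr3[k]
      else {
        last_g <- if (length(bl$utr3)) bl$utr3[length(bl$utr3)] else bl$cds[length(bl$cds)]
        tx_end_edge <- if (model$strand == "+") max(model$exon_ends) - 1L else min(model$exon_starts)
        extra <- k - length(bl$utr3)
        g <- tx_end_edge + sgn * extra
        if (g < 0L) stop("'", cdna_string, "': walks past the chromosome start")
        return(g + 1L)
      }
    }
  )

  if (p$offset == 0L) return(anchor_g + 1L)

  # intronic offset: anchor must sit on an exon boundary facing the offset
  g <- anchor_g + sgn * p$offset
  if (g < 0L) stop("'", cdna_string, "': walks past the chromosome start")
  # the offset must land outside every exon (an intron, or past the
  # transcript edge when the anchor exon is terminal)
  if (any(g >= model$exon_starts & g < model$exon_ends)) {
    stop("'", cdna_string, "': intronic offset lands inside an exon")
  }
  # validate the anchor faces the right way
  if (p$offset > 0L) {
    boundary <- if (model$strand == "+") (anchor_g + 1L) %in% model$exon_ends
                else anchor_g %in% model$exon_starts
    if (!boundary) stop("'", cdna_string, "': '+' offset from a non-boundary base")
  } else {
    boundary <- if (model$strand == "+") anchor_g %in% model$exon_starts
                else (anchor_g + 1L) %in% model$exon_ends
    if (!boundary) stop("'", cdna_string, "': '-' offset from a non-boundary base")
  }
  g + 1L
}

#' Express a genomic coordinate in HGVS c. notation
#'
#' Inverse of [hgvs_c_to_genomic()]: exonic positions map to `c.N`, `c.-N` or
#' `c.*N`; intronic positions are anchored to the closer exon boundary in
#' transcript orientation (`c.N+d` / `c.N-d`), with ties assigned to the
#' upstream exon's `+` side; positions beyond the transcript edges continue
#' the UTR numbering.
#'
#' @param model A `gene_model` with CDS bounds.
#' @param pos 1-based genomic coordinate.
#' @return An HGVS c. position string.
#' @export
genomic_to_hgvs_c <- function(model, pos) {
  validate_gene_model(model)
  bl <- tx_blocks(model)
  p0 <- as.integer(pos) - 1L
  sgn <- if (model$strand == "+") 1L else -1L

  label_of <- function(g) {
    i <- match(g, bl$cds)
    if (!is.na(i)) return(as.character(i))
    i <- match(g, bl$utr5)
    if (!is.na(i)) return(paste0("-", length(bl$utr5) - i + 1L))
    i <- match(g, bl$utr3)
    if (!is.na(i)) return(paste0("*", i))
    NA_character_
  }

  lab <- label_of(p0)
  if (!is.na(lab)) return(paste0("c.", lab))

  cls <- classify_position(model, pos)
  if (cls$category == "outside_transcript") {
    tx_start_edge <- if (model$strand == "+") min(model$exon_starts) else max(model$exon_ends) - 1L
    upstream <- (model$strand == "+" && p0 < tx_start_edge) ||
                (model$strand == "-" && p0 > tx_start_edge)
    if (upstream) {
      d <- abs(p0 - tx_start_edge)
      return(paste0("c.-", length(bl$utr5) + d))
    }
    tx_end_edge <- if (model$strand == "+") max(model$exon_ends) - 1L else min(model$exon_starts)
    d <- abs(p0 - tx_end_edge)
    return(paste0("c.*", length(bl$utr3) + d))
  }

  # intronic: find the flanking exon boundaries in genomic coordinates
  i <- max(which(model$exon_ends <= p0))
  left_g <- model$exon_ends[i] - 1L       # last base of the genomic-left exon
  right_g <- model$exon_starts[i + 1L]    # first base of the genomic-right exon
  d_left <- p0 - left_g
  d_right <- right_g - p0
  if (model$strand == "+") {
    if (d_left <= d_right) paste0("c.", label_of(left_g), "+", d_left)
    else paste0("c.", label_of(right_g), "-", d_right)
  } else {
    # transcript-upstream exon is the genomic-right one
    if (d_right <= d_left) paste0("c.", label_of(right_g), "+", d_right)
    else paste0("c.", label_of(left_g), "-", d_left)
  }
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from the
#' denominator.
#'
#' @param sequence A nucleotide string (alphabet ACGTN, case-insensitive).
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("unexpected characters in sequence: ", paste(bad, collapse = ", "))
  denom <- sum(ch != "N")
  if (denom == 0L) stop("sequence contains only N bases")
  sum(ch %in% c("G", "C")) / denom
}

# ---- readers ---------------------------------------------------------------

#' Read gene models from the package's TSV dialect
#'
#' Columns: `gene`, `chrom`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated 0-based half-open bounds), `cds_start`, `cds_end`
#' (0-based; empty/NA for noncoding transcripts), optional `flank_pad`.
#' Lines starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return A named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("gene", "chrom", "strand", "exon_starts", "exon_ends",
              "cds_start", "cds_end")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("gene model table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  parse_int_list <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    gene_model(
      gene = r$gene, chrom = r$chrom, strand = r$strand,
      exon_starts = parse_int_list(r$exon_starts),
      exon_ends = parse_int_list(r$exon_ends),
      cds_start = if (is.na(r$cds_start) || r$cds_start == "") NA else as.integer(r$cds_start),
      cds_end = if (is.na(r$cds_end) || r$cds_end == "") NA else as.integer(r$cds_end),
      flank_pad = if ("flank_pad" %in% names(df) && !is.na(r$flank_pad) && r$flank_pad != "")
        as.integer(r$flank_pad) else 20L
    )
  })
  names(out) <- df$gene
  out
}

#' Write gene models in the package's TSV dialect
#'
#' @param models Named list of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- vapply(models, function(m) {
    paste(m$gene, m$chrom, m$strand,
          paste(m$exon_starts, collapse = ","),
          paste(m$exon_ends, collapse = ","),
          if (is.na(m$cds_start)) "" else m$cds_start,
          if (is.na(m$cds_end)) "" else m$cds_end,
          m$flank_pad, sep = "\t")
  }, character(1L))
  writeLines(c(paste("gene", "chrom", "strand", "exon_starts", "exon_ends",
                     "cds_start", "cds_end", "flank_pad", sep = "\t"), rows), path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Block starts/sizes become exons; `thickStart`/`thickEnd` become the CDS
#' (absent thick region, i.e. `thickStart == thickEnd`, means noncoding).
#'
#' @param path Path to a BED12 file.
#' @param flank_pad Flank in bp for the coverage footprint (default 20).
#' @return A named list of `gene_model` objects.
#' @export
read_gene_models_bed12 <- function(path, flank_pad = 20L) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    blocks <- S4Vectors::mcols(g)$blocks[[1L]]
    ex <- IRanges::shift(blocks, GenomicRanges::start(g) - 1L)
    thick <- S4Vectors::mcols(g)$thick   # IRanges, one row per record
    has_cds <- IRanges::width(thick)[1L] > 0L
    gene_model(
      gene = S4Vectors::mcols(g)$name,
      chrom = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(GenomicRanges::strand(g)),
      exon_starts = IRanges::start(ex) - 1L,
      exon_ends = IRanges::end(ex),
      cds_start = if (has_cds) IRanges::start(thick)[1L] - 1L else NA,
      cds_end = if (has_cds) IRanges::end(thick)[1L] else NA,
      flank_pad = flank_pad
    )
  })
  names(out) <- vapply(out, `[[`, character(1L), "gene")
  out
}
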