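# Small in-code fixtures shared across tests.

# single-exon plus-strand gene: exon [100, 200), fully coding
toy_single_exon <- function() {
  gene_model("TOY1", "chrT", "+", exon_starts = 100L, exon_ends = 200L,
             cds_start = 100L, cds_end = 200L)
}

# two-exon minus-strand transcript with printed bounds: exons [100,130) and
# [200,240); CDS [110,230) leaves exonic UTRs on both ends
toy_two_exon_minus <- function() {
  gene_model("TOY2", "chrT", "-", exon_starts = c(100L, 200L),
             exon_ends = c(130L, 240L), cds_start = 110L, cds_end = 230L)
}

# a reference spanning any toy model: deterministic base pattern
toy_reference <- function(n = 600L, chrom = "chrT", pattern = c("A", "C", "G", "T")) {
  s <- paste0(rep_len(pattern, n), collapse = "")
  ref <- Biostrings::DNAStringSet(s)
  names(ref) <- chrom
  ref
}

reference_from_chars <- function(chars, chrom = "chrT") {
  ref <- Biostrings::DNAStringSet(paste0(chars, collapse = ""))
  names(ref) <- chrom
  ref
}

# random valid gene model for fuzzing (both strands, 2-5 exons)
random_model <- function(strand = sample(c("+", "-"), 1L)) {
  n_ex <- sample(2:5, 1L)
  widths <- sample(30:80, n_ex, replace = TRUE)
  gaps <- sample(45:200, n_ex - 1L, replace = TRUE)
  starts <- integer(n_ex)
  starts[1L] <- sample(40:120, 1L)
  for (i in seq_len(n_ex - 1L)) starts[i + 1L] <- starts[i] + widths[i] + gaps[i]
  ends <- starts + widths
  exonic <- unlist(mapply(seq.int, starts, ends - 1L, SIMPLIFY = FALSE))
  utr5 <- sample(3:10, 1L); utr3 <- sample(3:10, 1L)
  cds_start <- exonic[utr5 + 1L]
  cds_end <- exonic[length(exonic) - utr3] + 1L
  gene_model("FUZZ", "chrT", strand, starts, ends, cds_start, cds_end)
}
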