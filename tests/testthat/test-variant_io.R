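test_that("SNVs pass through normalization unchanged", {
  ref <- toy_reference()
  # pattern ACGT repeating: 1-based pos 100 is a T (100 %% 4 == 0)
  n <- normalize_allele("chrT", 100L, "T", "G", ref)
  expect_equal(n, list(chrom = "chrT", pos = 100L, ref = "T", alt = "G"))
  expect_error(normalize_allele("chrT", 100L, "A", "G", ref), "reference mismatch")
  expect_error(normalize_allele("chrT", 100L, "T", "T", ref), "identical")
})

test_that("homopolymer deletions left-align to the first possible position", {
  # context: positions 1..12 = G A C T T T T T G A C T
  chars <- strsplit("GACTTTTTGACT", "")[[1L]]
  ref <- reference_from_chars(chars)
  # a deletion of one T written at the right end of the run
  n <- normalize_allele("chrT", 7L, "TT", "T", ref)
  expect_equal(n, list(chrom = "chrT", pos = 3L, ref = "CT", alt = "C"))
  # all brute-force-enumerated equivalent representations normalize identically
  refstr <- paste0(chars, collapse = "")
  reps <- equivalent_representations(refstr, 3L, "CT", "C")
  expect_gt(length(reps), 2L)
  normed <- unique(lapply(reps, function(r) {
    normalize_allele("chrT", r$pos, r$ref, r$alt, ref)
  }))
  expect_length(normed, 1L)
  expect_equal(normed[[1L]], n)
})

test_that("fuzzed indel representations normalize to one identical allele", {
  set.seed(301)
  for (rep in 1:40) {
    chars <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    refstr <- paste0(chars, collapse = "")
    ref <- reference_from_chars(chars)
    pos <- sample(10:40, 1L)
    is_del <- runif(1L) < 0.5
    len <- sample(1:4, 1L)
    if (is_del) {
      v <- list(pos = pos, ref = substring(refstr, pos, pos + len), alt = substring(refstr, pos, pos))
    } else {
      ins <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      anchor <- substring(refstr, pos, pos)
      v <- list(pos = pos, ref = anchor, alt = paste0(anchor, ins))
    }
    if (v$ref == v$alt) next
    reps <- equivalent_representations(refstr, v$pos, v$ref, v$alt)
    normed <- unique(lapply(reps, function(r) {
      normalize_allele("chrT", r$pos, r$ref, r$alt, ref)
    }))
    expect_length(normed, 1L)
    # idempotence
    n1 <- normed[[1L]]
    expect_equal(normalize_allele(n1$chrom, n1$pos, n1$ref, n1$alt, ref), n1)
  }
})

test_that("truth tables read, resolve HGVS rows, and collect rejects", {
  models <- list(TOY2 = toy_two_exon_minus())
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# clinical truth table",
    paste("patient_id", "gene", "chrom", "pos", "ref", "alt", "zygosity", "hgvs_c", sep = "\t"),
    paste("P1", "TOY2", "chrT", "205", "A", "G", "het", "", sep = "\t"),
    paste("P1", "TOY2", "chrT", "120", "C", "T", "hom", "", sep = "\t"),
    paste("P2", "TOY2", "chrT", "", "A", "C", "het", "c.30+2", sep = "\t")
  ), path)
  tt <- read_truth_table(path, models)
  expect_equal(nrow(tt$variants), 3L)
  expect_equal(nrow(tt$rejects), 0L)
  # resolved coordinate equals the exhaustive enumeration oracle
  map <- oracle_c_to_g_map(models$TOY2)
  expect_equal(tt$variants$pos[3L], unname(map[["c.30"]]) - 2L)

  # rejects: no position and no hgvs; bad zygosity; unknown gene
  writeLines(c(
    paste("patient_id", "gene", "chrom", "pos", "ref", "alt", "zygosity", "hgvs_c", sep = "\t"),
    paste("P1", "TOY2", "chrT", "", "A", "G", "het", "", sep = "\t"),
    paste("P1", "TOY2", "chrT", "205", "A", "G", "heterozygote", "", sep = "\t"),
    paste("P1", "NOGENE", "chrT", "", "A", "G", "het", "c.5", sep = "\t"),
    paste("P1", "TOY2", "chrT", "120", "C", "T", "hom", "", sep = "\t")
  ), path)
  tt2 <- read_truth_table(path, models)
  expect_equal(nrow(tt2$variants), 1L)
  expect_equal(nrow(tt2$rejects), 3L)
  expect_match(tt2$rejects$reason[1L], "no genomic position")

  writeLines("patient_id\tgene\tchrom", path)
  expect_error(read_truth_table(path), "missing mandatory column.*pos")
})

test_that("VCF reading derives zygosity and depth, splitting multi-allelics", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", ".", ".", "GT:DP", "0/1:42", sep = "\t"),
    paste("chr1", "200", ".", "C", "G,T", ".", ".", ".", "GT:DP", "1/2:30", sep = "\t"),
    paste("chr1", "300", ".", "T", "A", ".", ".", ".", "GT:DP", "0|1:25", sep = "\t"),
    paste("chr1", "400", ".", "G", "C", ".", ".", ".", "GT:DP", "1/1:50", sep = "\t"),
    paste("chr1", "500", ".", "G", "A", ".", ".", ".", "GT:DP", "./.:10", sep = "\t")
  ), path)
  calls <- read_vcf(path)
  expect_equal(nrow(calls), 6L)  # the 1/2 record splits in two
  one <- calls[calls$pos == 100L, ]
  expect_equal(one$zygosity, "het")
  expect_equal(one$site_depth, 42L)
  multi <- calls[calls$pos == 200L, ]
  expect_equal(sort(multi$alt), c("G", "T"))
  expect_equal(multi$zygosity, c("het", "het"))
  expect_equal(calls$zygosity[calls$pos == 300L], "het")   # phased == unphased
  expect_equal(calls$zygosity[calls$pos == 400L], "hom")
  expect_equal(calls$zygosity[calls$pos == 500L], "missing")
  expect_error(read_vcf(path, sample = "S9"), "not in VCF")
})

test_that("writing calls to VCF and re-reading reproduces normalized alleles", {
  set.seed(99)
  chars <- sample(c("A", "C", "G", "T"), 80, replace = TRUE)
  ref <- reference_from_chars(chars, "chrS1")
  calls <- data.frame(
    chrom = "chrS1", pos = c(10L, 25L, 40L), ref = c(substring(paste0(chars, collapse = ""), 10, 10),
                                                     substring(paste0(chars, collapse = ""), 25, 27),
                                                     substring(paste0(chars, collapse = ""), 40, 40)),
    alt = NA_character_, zygosity = c("het", "het", "hom"),
    site_depth = c(31L, 44L, 52L), qual = c(50, 60, 70),
    stringsAsFactors = FALSE
  )
  calls$alt <- c("G", substring(calls$ref[2L], 1L, 1L), "T")
  calls <- calls[calls$ref != calls$alt, ]
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, sample = "P01", contigs = "chrS1")
  back <- read_vcf(path, sample = "P01")
  key <- function(df) {
    norm <- lapply(seq_len(nrow(df)), function(i) {
      normalize_allele(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], ref)
    })
    sort(vapply(norm, function(n) paste(n$chrom, n$pos, n$ref, n$alt), character(1L)))
  }
  expect_equal(key(back), key(calls))
  expect_equal(sort(back$site_depth), sort(calls$site_depth))
  expect_equal(sort(back$zygosity), sort(calls$zygosity))
})
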