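# a tiny one-gene cohort shared by several blocks
tiny_cohort <- function() {
  chars <- rep_len(c("A", "C", "G", "T"), 600L)
  ref <- reference_from_chars(chars, "chrT")
  model <- gene_model("TOY", "chrT", "+", c(100L, 300L), c(200L, 400L),
                      cds_start = 110L, cds_end = 390L)
  list(ref = ref, models = list(TOY = model),
       track = depth_track(data.frame(chrom = "chrT", start0 = 80L,
                                      end0 = 420L, depth = 45L)))
}

call_row <- function(pos, ref, alt, zyg, dp = 40L) {
  data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt, zygosity = zyg,
             site_depth = dp, qual = 50, stringsAsFactors = FALSE)
}

truth_row <- function(pos, ref, alt, zyg, gene = "TOY", patient = "P1") {
  data.frame(patient_id = patient, gene = gene, chrom = "chrT", pos = pos,
             ref = ref, alt = alt, zygosity = zyg, stringsAsFactors = FALSE)
}

base_at <- function(pos) rep_len(c("A", "C", "G", "T"), 600L)[pos]

test_that("matching classifies concordant, zygosity and missing correctly", {
  tc <- tiny_cohort()
  b <- base_at(150L)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1L]
  calls <- normalize_calls(rbind(call_row(150L, b, alt, "het", dp = 42L)), tc$ref)

  # same allele, same zygosity
  v <- match_variant(truth_row(150L, b, alt, "het"), calls, tc$track, tc$ref)
  expect_equal(v$status, "concordant")
  expect_equal(v$site_depth, 42L)
  expect_false(v$low_depth)

  # same allele, truth hom vs call het
  v2 <- match_variant(truth_row(150L, b, alt, "hom"), calls, tc$track, tc$ref)
  expect_equal(v2$status, "discordant_zygosity")

  # no call at the position: missing, depth from the track, well covered
  v3 <- match_variant(truth_row(154L, base_at(154L),
                                setdiff(c("A", "C", "G", "T"), base_at(154L))[1L],
                                "het"), calls, tc$track, tc$ref)
  expect_equal(v3$status, "missing")
  expect_equal(v3$site_depth, 45L)
  expect_false(v3$low_depth)

  # call at the same position with a different alternate
  other <- setdiff(c("A", "C", "G", "T"), c(b, alt))[1L]
  v4 <- match_variant(truth_row(150L, b, other, "het"), calls, tc$track, tc$ref)
  expect_equal(v4$status, "discordant_base")
})

test_that("indel truth and VCF representations match through normalization", {
  chars <- strsplit("GACTTTTTGACTGACAGTACGTACGTACGT", "")[[1L]]
  ref <- reference_from_chars(chars, "chrT")
  model <- gene_model("TOY", "chrT", "+", 1L, 30L, cds_start = 1L, cds_end = 30L,
                      flank_pad = 0L)
  track <- depth_track(data.frame(chrom = "chrT", start0 = 0L, end0 = 30L, depth = 50L))
  # truth written right-shifted in the homopolymer; VCF left-aligned
  truth <- truth_row(7L, "TT", "T", "het")
  calls <- normalize_calls(call_row(3L, "CT", "C", "het"), ref)
  v <- match_variant(truth, calls, track, ref)
  expect_equal(v$status, "concordant")
})

test_that("adjudication resolves each discordance type", {
  tc <- tiny_cohort()
  b150 <- base_at(150L); alt150 <- setdiff(c("A", "C", "G", "T"), b150)[1L]
  b162 <- base_at(162L); alt162 <- setdiff(c("A", "C", "G", "T"), b162)[1L]
  b174 <- base_at(174L); alt174 <- setdiff(c("A", "C", "G", "T"), b174)[1L]
  b186 <- base_at(186L); alt186 <- setdiff(c("A", "C", "G", "T"), b186)[1L]
  truth <- rbind(
    truth_row(150L, b150, alt150, "het"),   # missing, confirmed present -> FN
    truth_row(162L, b162, alt162, "het"),   # missing, confirmed wild-type -> FP
    truth_row(174L, b174, alt174, "hom"),   # zygosity flip, confirmation sides with WES
    truth_row(186L, b186, alt186, "het")    # discordant base, both wrong
  )
  wrong186 <- setdiff(c("A", "C", "G", "T"), c(b186, alt186))[1L]
  calls <- rbind(call_row(174L, b174, alt174, "het"),
                 call_row(186L, b186, wrong186, "het"))
  records <- match_cohort(truth, list(P1 = calls), list(P1 = tc$track),
                          tc$models, tc$ref)
  expect_equal(records$status,
               c("missing", "missing", "discordant_zygosity", "discordant_base"))
  confirmatory <- data.frame(
    patient_id = "P1", chrom = "chrT", pos = c(150L, 162L, 174L, 186L),
    observed_ref = c(b150, b162, b174, b186),
    observed_allele = c(alt150, b162, alt174, b186),
    observed_zygosity = c("het", "ref", "het", "ref"),
    stringsAsFactors = FALSE
  )
  adj <- adjudicate(records, confirmatory)
  expect_equal(adj$resolution,
               c("sanger_correct", "wes_correct", "wes_correct", "both_incorrect"))
  # records without confirmatory rows stay unresolved
  adj2 <- adjudicate(records, confirmatory[1L, ])
  expect_equal(adj2$resolution[2:4], rep("unresolved", 3L))
  # confirmatory rows matching no record warn
  stray <- confirmatory[1L, ]; stray$pos <- 999L
  expect_warning(adjudicate(records, stray), "matching no record")

  tab <- concordance_table(adj)
  expect_equal(attr(tab, "fn_count"), 1L)
  expect_equal(attr(tab, "fp_count"), 1L)
  expect_equal(tab$indeterminate[tab$stratum == "coding"], 1L)
  expect_equal(tab$total[tab$stratum == "coding"], 4L)
})

test_that("a single concordant record yields rate 100 in its stratum", {
  tc <- tiny_cohort()
  b <- base_at(150L); alt <- setdiff(c("A", "C", "G", "T"), b)[1L]
  records <- match_cohort(truth_row(150L, b, alt, "het"),
                          list(P1 = call_row(150L, b, alt, "het")),
                          list(P1 = tc$track), tc$models, tc$ref)
  tab <- concordance_table(records)
  expect_equal(tab$rate_percent[tab$stratum == "coding"], 100)
  expect_equal(tab$rate_percent[tab$stratum == "overall"], 100)
  expect_true(is.na(tab$rate_percent[tab$stratum == "intronic_near"]))
  expect_true(is.na(attr(tab, "wes_false_negative_rate")))
})

test_that("percentages round half-up to one decimal", {
  expect_equal(rate_percent(146, 150), 97.3)
  expect_equal(rate_percent(44, 58), 75.9)
  expect_equal(rate_percent(48, 52), 92.3)
  expect_equal(rate_percent(79, 131), 60.3)
  expect_equal(rate_percent(9, 51), 17.6)
  expect_equal(rate_percent(1, 150), 0.7)
  expect_equal(rate_percent(0, 1), 0.0)
  expect_equal(rate_percent(1, 16), 6.3)    # 6.25 rounds up
  expect_equal(rate_percent(1, 800), 0.1)   # 0.125 rounds up
  expect_true(is.na(rate_percent(1, 0)))
})

test_that("table counts are conserved and order-invariant", {
  cfg <- sim_config(seed = 31L, n_patients = 3L, p_missing = 0.15,
                    p_discordant_base = 0.05, p_zygosity_flip = 0.1)
  b <- generate_cohort(cfg)
  records <- match_cohort(b$truth, b$calls_by_patient, b$tracks_by_patient,
                          b$models, b$reference)
  tab <- concordance_table(records)
  counted <- tab$concordant + tab$discordant_base + tab$discordant_zygosity +
    tab$missing + tab$indeterminate
  expect_equal(counted, tab$total)
  expect_equal(tab$total[tab$stratum == "overall"] +
                 tab$total[tab$stratum == "excluded_genes"], nrow(b$truth))
  inc <- tab[tab$stratum %in% c("coding", "intronic_near", "intronic_deep"), ]
  expect_equal(sum(inc$total), tab$total[tab$stratum == "overall"])
  expect_equal(sum(inc$concordant), tab$concordant[tab$stratum == "overall"])

  # permuting truth rows and each patient's calls changes nothing
  set.seed(8)
  truth_perm <- b$truth[sample(nrow(b$truth)), ]
  calls_perm <- lapply(b$calls_by_patient, function(d) d[sample(nrow(d)), ])
  records2 <- match_cohort(truth_perm, calls_perm, b$tracks_by_patient,
                           b$models, b$reference)
  tab2 <- concordance_table(records2)
  expect_equal(tab2, tab, ignore_attr = TRUE)
})

test_that("the table equals a naive quadratic matcher on fuzzed cohorts", {
  for (seed in c(101L, 202L)) {
    cfg <- sim_config(seed = seed, n_patients = 4L,
                      variants_per_patient = c(coding = 8L, intronic_near = 4L,
                                               intronic_deep = 4L),
                      p_missing = 0.12, p_discordant_base = 0.06,
                      p_zygosity_flip = 0.08, p_indel = 0.2)
    b <- generate_cohort(cfg)
    expect_lte(nrow(b$truth), 200L)
    records <- match_cohort(b$truth, b$calls_by_patient, b$tracks_by_patient,
                            b$models, b$reference)
    tab <- concordance_table(records)
    want <- oracle_concordance_table(b$truth, b$calls_by_patient, b$models,
                                     b$reference)
    got <- as.matrix(tab[, c("total", "concordant", "discordant_base",
                             "discordant_zygosity", "missing")])
    # no adjudication here, so indeterminate is empty and the five counts
    # partition every stratum
    rownames(got) <- tab$stratum
    expect_equal(got, want[rownames(got), , drop = FALSE], ignore_attr = TRUE)
  }
})
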