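test_that("toy caller applies the read-count and allele-fraction rules", {
  expect_equal(toy_site_caller(2L, 0L), "no_call")   # below three reads
  expect_equal(toy_site_caller(8L, 2L), "het")       # 20% boundary is inclusive
  expect_equal(toy_site_caller(9L, 1L), "ref")
  expect_equal(toy_site_caller(0L, 5L), "hom")
  expect_equal(toy_site_caller(1L, 4L), "hom")       # 0.8 boundary
  expect_equal(toy_site_caller(5L, 5L), "het")
  expect_error(toy_site_caller(-1L, 4L), "non-negative")
  # exhaustive agreement with a direct rule transcription, small totals
  for (r in 0:15) for (a in 0:15) {
    expect_equal(toy_site_caller(r, a), oracle_caller(r, a),
                 info = paste(r, a))
  }
})

test_that("configs validate probabilities and capacity; YAML round-trips", {
  expect_error(sim_config(p_missing = 0.7, p_discordant_base = 0.5), "jointly")
  expect_error(sim_config(p_missing = -0.1), "in \\[0, 1\\]")
  expect_error(sim_config(n_patients = 40L), "infeasible")
  y <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 12", "n_patients: 2", "p_missing: 0.1",
    "variants_per_patient:", "  coding: 4", "  intronic_near: 2", "  intronic_deep: 2",
    "genes:",
    "- {gene: G1, n_exons: 4, exon_len: 300, intron_len: 400, gc_target: 0.4, mean_depth: 48, low_cov_fraction: 0}",
    "- {gene: G2, n_exons: 4, exon_len: 300, intron_len: 400, gc_target: 0.55, mean_depth: 30, low_cov_fraction: 0.3}"
  ), y)
  cfg <- read_sim_config(y)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 12L)
  expect_equal(cfg$genes$gene, c("G1", "G2"))
})

test_that("identical seeds give byte-identical bundles; different seeds differ", {
  cfg <- sim_config(seed = 9L, n_patients = 2L, p_missing = 0.1, p_zygosity_flip = 0.1)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  other <- generate_cohort(sim_config(seed = 10L, n_patients = 2L,
                                      p_missing = 0.1, p_zygosity_flip = 0.1))
  mine <- generate_cohort(cfg)
  expect_false(identical(mine$truth$pos, other$truth$pos))
})

test_that("a zero-probability config yields 100% concordance everywhere", {
  b <- generate_cohort(sim_config(seed = 3L, n_patients = 2L))
  res <- analyze_cohort(b$models, b$reference, b$truth, b$calls_by_patient,
                        b$tracks_by_patient)
  tab <- res$table
  inc <- tab[tab$total > 0 & tab$stratum != "excluded_genes", ]
  expect_true(all(inc$rate_percent == 100))
  expect_equal(length(res$excluded_genes), 0L)
})

test_that("planting exactly k zygosity flips reports exactly k discordances", {
  cfg <- sim_config(seed = 21L, n_patients = 3L, p_zygosity_flip = 0.25)
  b <- generate_cohort(cfg)
  k <- sum(b$manifest$variants$fate == "zygosity_flip")
  expect_gt(k, 0L)
  records <- match_cohort(b$truth, b$calls_by_patient, b$tracks_by_patient,
                          b$models, b$reference)
  tab <- concordance_table(records)
  expect_equal(tab$discordant_zygosity[tab$stratum == "overall"], k)
})

test_that("a gene designed with 30% low coverage is excluded by coverage QC", {
  genes <- data.frame(gene = c("OKGENE", "LOWGENE"),
                      n_exons = 4L, exon_len = 300L, intron_len = 400L,
                      gc_target = c(0.40, 0.55), mean_depth = c(48L, 30L),
                      low_cov_fraction = c(0, 0.30), stringsAsFactors = FALSE)
  b <- generate_cohort(sim_config(seed = 4L, n_patients = 2L, genes = genes))
  cov <- compute_gene_coverage(b$tracks_by_patient, b$models, b$truth,
                               reference = b$reference)
  expect_equal(cov$excluded_genes, "LOWGENE")
  low <- cov$per_gene[cov$per_gene$gene == "LOWGENE", ]
  expect_lt(low$median_fraction_over_threshold, 0.75)
  expect_equal(b$manifest$designed_excluded_genes, "LOWGENE")
  # the high-GC design couples to the low-coverage gene
  expect_gt(cov$per_gene$gc_fraction[cov$per_gene$gene == "LOWGENE"], 0.45)
})

test_that("no emitted VCF record violates the caller's thresholds", {
  cfg <- sim_config(seed = 17L, n_patients = 3L, p_missing = 0.1,
                    p_zygosity_flip = 0.1, p_discordant_base = 0.05)
  d <- file.path(tempdir(), "sim_caller")
  unlink(d, recursive = TRUE)
  b <- generate_study(cfg, d)
  for (p in names(b$calls_by_patient)) {
    calls <- read_vcf(file.path(d, "vcf", paste0(p, ".vcf")), sample = p)
    expect_true(all(calls$site_depth >= cfg$min_reads))
    for (i in seq_len(nrow(calls))) {
      dp <- calls$site_depth[i]
      alt_reads <- if (calls$zygosity[i] == "hom") dp else dp %/% 2L
      expect_equal(toy_site_caller(dp - alt_reads, alt_reads,
                                   cfg$min_reads, cfg$min_allele_fraction),
                   calls$zygosity[i])
    }
  }
})

test_that("pipeline output recovers the manifest's planted truth exactly", {
  cfg <- sim_config(seed = 23L, n_patients = 4L, p_missing = 0.15,
                    p_discordant_base = 0.08, p_zygosity_flip = 0.1, p_indel = 0.2)
  b <- generate_cohort(cfg)
  res <- analyze_cohort(b$models, b$reference, b$truth, b$calls_by_patient,
                        b$tracks_by_patient, b$confirmatory)
  planted <- b$manifest$variants
  expected_status <- c(concordant = "concordant", missing = "missing",
                       discordant_base = "discordant_base",
                       zygosity_flip = "discordant_zygosity")[planted$fate]
  # records come back in truth order, which is plan order
  expect_equal(res$records$status, unname(expected_status))
  expect_equal(res$records$stratum, planted$stratum)
  # planted confirmations resolve the way they were planted
  expect_equal(res$records$resolution[planted$confirm == "sanger"],
               rep("sanger_correct", sum(planted$confirm == "sanger")))
  expect_equal(res$records$resolution[planted$confirm == "wes"],
               rep("wes_correct", sum(planted$confirm == "wes")))
})

test_that("every emitted fixture file parses with the corresponding reader", {
  d <- file.path(tempdir(), "fixture_parse")
  unlink(d, recursive = TRUE)
  b <- build_paper_fixture(d)
  models <- read_gene_models(file.path(d, "genes.tsv"))
  expect_length(models, 51L)
  ref <- read_reference(file.path(d, "reference.fa"))
  expect_length(ref, 51L)
  tt <- read_truth_table(file.path(d, "truth.tsv"), models)
  expect_equal(nrow(tt$variants), 391L)
  expect_equal(nrow(tt$rejects), 0L)
  expect_equal(length(unique(tt$variants$patient_id)), 26L)
  conf <- read.delim(file.path(d, "confirmatory.tsv"))
  expect_equal(nrow(conf), 9L)  # 4 missing coding + 4 zygosity + 1 base
  one_vcf <- read_vcf(file.path(d, "vcf", "P05.vcf"), sample = "P05")
  expect_gt(nrow(one_vcf), 0L)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(length(manifest$designed_excluded_genes), 9L)
})
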