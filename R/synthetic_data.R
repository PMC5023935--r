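#' Toy site-level genotype caller
#'
#' Transcribes the site-calling rules used by the synthetic generator: a
#' position needs at least `min_reads` total reads to be called at all; an
#' alternate-allele fraction below `min_allele_fraction` is called reference;
#' a fraction of at least `hom_fraction` is called homozygous alternate;
#' anything in between is heterozygous. The 20% floor is inclusive (a fraction
#' of exactly 0.20 supports the alternate); the 0.80 homozygous boundary is
#' symmetric to it by design.
#'
#' @param ref_reads,alt_reads Non-negative read counts.
#' @param min_reads Minimum total reads for a call (default 3).
#' @param min_allele_fraction Minimum alternate fraction (default 0.20).
#' @param hom_fraction Alternate fraction at or above which the site is called
#'   homozygous (default 0.80).
#' @return One of `"no_call"`, `"ref"`, `"het"`, `"hom"`.
#' @export
toy_site_caller <- function(ref_reads, alt_reads, min_reads = 3L,
                            min_allele_fraction = 0.20, hom_fraction = 0.80) {
  if (ref_reads < 0 || alt_reads < 0) stop("read counts must be non-negative")
  total <- ref_reads + alt_reads
  if (total < min_reads) return("no_call")
  af <- alt_reads / total
  if (af < min_allele_fraction) return("ref")
  if (af >= hom_fraction) return("hom")
  "het"
}

#' Simulation configuration
#'
#' Bundles everything that determines a synthetic cohort: the seed, the
#' patients, the gene panel (geometry, GC target and coverage profile per
#' gene), per-stratum variant counts per patient, per-stratum event
#' probabilities and the toy caller's thresholds. The seed fully determines
#' all outputs.
#'
#' @param seed Integer seed.
#' @param n_patients Number of patients.
#' @param genes Data.frame with columns `gene`, `n_exons`, `exon_len`,
#'   `intron_len`, `gc_target`, `mean_depth`, `low_cov_fraction` (fraction of
#'   the footprint left below the coverage threshold; above 0.25 the gene is
#'   designed to fail the 75% rule). Defaults to a small two-gene panel.
#' @param variants_per_patient Named integer vector with entries `coding`,
#'   `intronic_near`, `intronic_deep`.
#' @param p_missing,p_discordant_base,p_zygosity_flip Per-variant event
#'   probabilities (scalars, applied to every stratum); must jointly be <= 1.
#' @param p_hom Probability a truth variant is homozygous.
#' @param p_indel Probability a planted variant is a small indel.
#' @param min_reads,min_allele_fraction Toy caller thresholds.
#' @param mean_depth Default site depth for well-covered positions.
#' @param flank_pad Footprint flank in bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_patients = 2L, genes = NULL,
                       variants_per_patient = c(coding = 6L, intronic_near = 3L,
                                                intronic_deep = 3L),
                       p_missing = 0, p_discordant_base = 0, p_zygosity_flip = 0,
                       p_hom = 0.25, p_indel = 0.1,
                       min_reads = 3L, min_allele_fraction = 0.20,
                       mean_depth = 48L, flank_pad = 20L) {
  if (is.null(genes)) {
    genes <- data.frame(
      gene = c("GENEA", "GENEB"),
      n_exons = 4L, exon_len = 300L, intron_len = 400L,
      gc_target = c(0.40, 0.45), mean_depth = mean_depth,
      low_cov_fraction = 0, stringsAsFactors = FALSE
    )
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients), genes = genes,
    variants_per_patient = variants_per_patient,
    p_missing = p_missing, p_discordant_base = p_discordant_base,
    p_zygosity_flip = p_zygosity_flip, p_hom = p_hom, p_indel = p_indel,
    min_reads = as.integer(min_reads), min_allele_fraction = min_allele_fraction,
    mean_depth = as.integer(mean_depth), flank_pad = as.integer(flank_pad)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_missing, cfg$p_discordant_base, cfg$p_zygosity_flip)
  if (any(probs < 0 | probs > 1)) stop("event probabilities must be in [0, 1]")
  if (sum(probs) > 1) stop("event probabilities jointly exceed 1")
  if (cfg$n_patients < 1L) stop("need at least one patient")
  needed <- c("gene", "n_exons", "exon_len", "intron_len", "gc_target",
              "mean_depth", "low_cov_fraction")
  miss <- setdiff(needed, names(cfg$genes))
  if (length(miss)) stop("gene panel missing column(s): ", paste(miss, collapse = ", "))
  # capacity: enough coding slots for what will be planted
  n_coding <- cfg$variants_per_patient[["coding"]] * cfg$n_patients
  capacity <- sum(floor((cfg$genes$n_exons * cfg$genes$exon_len - 212) / 12))
  if (n_coding > capacity) {
    stop("infeasible config: ", n_coding, " coding variants exceed ",
         capacity, " available footprint slots")
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' The YAML schema mirrors the [sim_config()] arguments; `genes` is a list of
#' per-gene mappings.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  genes <- if (!is.null(y$genes)) do.call(rbind, lapply(y$genes, as.data.frame)) else NULL
  args <- y[setdiff(names(y), "genes")]
  if (!is.null(y$variants_per_patient)) {
    args$variants_per_patient <- unlist(y$variants_per_patient)
  }
  do.call(sim_config, c(args, list(genes = genes)))
}

# ---- gene / reference construction -----------------------------------------

build_models_from_spec <- function(genes_spec, flank_pad = 20L, utr_len = 100L) {
  models <- lapply(seq_len(nrow(genes_spec)), function(i) {
    g <- genes_spec[i, ]
    margin <- 200L
    starts <- margin + (seq_len(g$n_exons) - 1L) * (g$exon_len + g$intron_len)
    ends <- starts + g$exon_len
    # CDS bounds: trim utr_len exonic bases off each end of the exon union
    exonic <- unlist(mapply(seq.int, starts, ends - 1L, SIMPLIFY = FALSE))
    stopifnot(length(exonic) > 2L * utr_len + 12L)
    cds_start <- exonic[utr_len + 1L]
    cds_end <- exonic[length(exonic) - utr_len] + 1L
    gene_model(gene = g$gene, chrom = paste0("chrS", i),
               strand = if (i %% 2L == 1L) "+" else "-",
               exon_starts = starts, exon_ends = ends,
               cds_start = cds_start, cds_end = cds_end, flank_pad = flank_pad)
  })
  names(models) <- genes_spec$gene
  models
}

synth_ref_chars <- function(model, gc_target) {
  n <- max(model$exon_ends) + 300L
  p_gc <- gc_target / 2
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc_target) / 2, (1 - gc_target) / 2, p_gc, p_gc))
}

# Slot machinery: deterministic, collision-free variant positions per gene.
# Coding slots walk the CDS every 12 exonic bases; intronic slots alternate
# intron and side at increasing distances. Indels consume the next compatible
# slot (left side of an intron, or an exonic anchor with room before the exon
# end) because their edited homopolymer run extends to higher coordinates.
make_slot_allocator <- function(model) {
  exonic <- unlist(mapply(seq.int, model$exon_starts, model$exon_ends - 1L,
                          SIMPLIFY = FALSE))
  cds_pos <- exonic[exonic >= model$cds_start & exonic < model$cds_end]
  coding_slots <- cds_pos[seq(7L, length(cds_pos), by = 12L)]
  n_introns <- length(model$exon_starts) - 1L
  intron_slot <- function(k, d0, step) {
    level <- (k - 1L) %/% (2L * n_introns)
    within <- (k - 1L) %% (2L * n_introns)
    intron <- within %/% 2L + 1L
    left <- within %% 2L == 0L
    d <- d0 + step * level
    pos0 <- if (left) model$exon_ends[intron] + d - 1L
            else model$exon_starts[intron + 1L] - d
    list(pos0 = pos0, left = left, d = d)
  }
  cursors <- new.env(parent = emptyenv())
  assign("coding", 0L, cursors); assign("near", 0L, cursors)
  assign("deep", 0L, cursors)
  take <- function(kind, runlen = 0L) {
    repeat {
      k <- get(kind, cursors) + 1L
      assign(kind, k, cursors)
      if (kind == "coding") {
        if (k > length(coding_slots)) stop("gene '", model$gene, "': out of coding slots")
        pos0 <- coding_slots[k]
        if (runlen == 0L) return(pos0)
        ex <- which(pos0 >= model$exon_starts & pos0 < model$exon_ends)
        if (pos0 + runlen + 1L < model$exon_ends[ex]) return(pos0)
      } else {
        d0 <- if (kind == "near") 3L else 30L
        step <- if (kind == "near") 5L else 10L
        dmax <- if (kind == "near") 18L else 170L
        s <- intron_slot(k, d0, step)
        if (s$d > dmax) stop("gene '", model$gene, "': out of ", kind, " slots")
        if (runlen == 0L) return(s$pos0)
        if (s$left && s$d + runlen <= dmax) return(s$pos0)
      }
    }
  }
  take
}

# Plant an indel's homopolymer context into the reference and return both the
# normalized and a deliberately right-shifted (non-normalized) representation.
plant_indel <- function(refchars, pos0, type, len) {
  p1 <- pos0 + 1L  # 1-based anchor index
  runlen <- if (type == "del") len + 2L else 2L
  refchars[p1] <- "T"
  refchars[(p1 + 1L):(p1 + runlen)] <- "A"
  refchars[p1 + runlen + 1L] <- "G"
  if (type == "del") {
    norm <- list(pos = p1, ref = paste0("T", strrep("A", len)), alt = "T")
    shifted <- list(pos = p1 + 1L, ref = strrep("A", len + 1L), alt = "A")
  } else {
    norm <- list(pos = p1, ref = "T", alt = "TA")
    shifted <- list(pos = p1 + 1L, ref = "A", alt = "AA")
  }
  list(refchars = refchars, norm = norm, shifted = shifted)
}

next_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]

# ---- cohort realization -----------------------------------------------------

# plan: one row per truth variant with columns
#   patient_id, gene, stratum (coding/intronic_near/intronic_deep/upstream),
#   type (snv/del/ins), indel_len, fate (concordant/missing/zygosity_flip/
#   discordant_base), zygosity, wes_zygosity, low_depth, confirm
#   (none/sanger/wes/reference), use_hgvs
realize_cohort <- function(genes_spec, plan, seed, min_reads = 3L,
                           min_allele_fraction = 0.20, mean_depth = 48L,
                           flank_pad = 20L, depth_threshold = 20L,
                           extra_calls_per_patient = 2L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  models <- build_models_from_spec(genes_spec, flank_pad = flank_pad)
  refchars <- lapply(seq_len(nrow(genes_spec)), function(i) {
    synth_ref_chars(models[[i]], genes_spec$gc_target[i])
  })
  names(refchars) <- vapply(models, `[[`, character(1L), "chrom")
  allocators <- lapply(models, make_slot_allocator)

  n <- nrow(plan)
  pos <- integer(n); ref <- character(n); alt <- character(n)
  norm_pos <- integer(n); norm_ref <- character(n); norm_alt <- character(n)

  for (i in seq_len(n)) {
    g <- plan$gene[i]
    m <- models[[g]]
    ch <- m$chrom
    if (plan$stratum[i] == "upstream") {
      pos0 <- if (m$strand == "+") m$exon_starts[1L] - plan$upstream_dist[i]
              else max(m$exon_ends) - 1L + plan$upstream_dist[i]
      b <- refchars[[ch]][pos0 + 1L]
      pos[i] <- pos0 + 1L; ref[i] <- b; alt[i] <- next_base(b)
      norm_pos[i] <- pos[i]; norm_ref[i] <- ref[i]; norm_alt[i] <- alt[i]
      next
    }
    kind <- switch(plan$stratum[i], coding = "coding",
                   intronic_near = "near", intronic_deep = "deep")
    if (plan$type[i] == "snv") {
      pos0 <- allocators[[g]](kind, 0L)
      b <- refchars[[ch]][pos0 + 1L]
      pos[i] <- pos0 + 1L; ref[i] <- b; alt[i] <- next_base(b)
      norm_pos[i] <- pos[i]; norm_ref[i] <- ref[i]; norm_alt[i] <- alt[i]
    } else {
      len <- plan$indel_len[i]
      runlen <- if (plan$type[i] == "del") len + 2L else 2L
      pos0 <- allocators[[g]](kind, runlen)
      planted <- plant_indel(refchars[[ch]], pos0, plan$type[i], len)
      refchars[[ch]] <- planted$refchars
      pos[i] <- planted$shifted$pos; ref[i] <- planted$shifted$ref
      alt[i] <- planted$shifted$alt
      norm_pos[i] <- planted$norm$pos; norm_ref[i] <- planted$norm$ref
      norm_alt[i] <- planted$norm$alt
    }
  }

  reference <- Biostrings::DNAStringSet(vapply(refchars, paste0, character(1L),
                                               collapse = ""))
  names(reference) <- names(refchars)

  gene_of <- setNames(genes_spec$gene, genes_spec$gene)
  chrom_of <- vapply(models, `[[`, character(1L), "chrom")

  truth <- data.frame(
    patient_id = plan$patient_id, gene = plan$gene,
    chrom = chrom_of[plan$gene], pos = pos, ref = ref, alt = alt,
    zygosity = plan$zygosity,
    hgvs_c = vapply(seq_len(n), function(i) {
      genomic_to_hgvs_c(models[[plan$gene[i]]], pos[i])
    }, character(1L)),
    dbsnp_id = ifelse(seq_len(n) %% 3L == 0L,
                      paste0("rs", 500000L + seq_len(n)), ""),
    source_test = "clinical_sanger",
    stringsAsFactors = FALSE
  )

  # depth per variant site: planted, deterministic
  site_dp <- integer(n)
  for (i in seq_len(n)) {
    site_dp[i] <- if (isTRUE(plan$low_depth[i])) 7L
      else if (plan$fate[i] == "missing" && plan$stratum[i] == "coding")
        30L + (i * 7L) %% 31L                      # 30..60 at the missed calls
      else mean_depth - 6L + (i * 5L) %% 13L       # around the cohort mean
  }

  # per-patient calls
  patients <- sort(unique(plan$patient_id))
  calls_by_patient <- lapply(patients, function(p) {
    idx <- which(plan$patient_id == p & plan$fate != "missing")
    rows <- lapply(idx, function(i) {
      fate <- plan$fate[i]
      zyg <- if (fate == "zygosity_flip") plan$wes_zygosity[i] else plan$zygosity[i]
      dp <- site_dp[i]
      a_alt <- if (zyg == "hom") dp else dp %/% 2L
      a_ref <- dp - a_alt
      called <- toy_site_caller(a_ref, a_alt, min_reads, min_allele_fraction)
      stopifnot(identical(called, zyg))
      if (fate == "discordant_base") {
        wrong <- next_base(norm_alt[i])
        if (wrong == norm_ref[i]) wrong <- next_base(wrong)
        data.frame(chrom = chrom_of[plan$gene[i]], pos = norm_pos[i],
                   ref = norm_ref[i], alt = wrong, zygosity = zyg,
                   site_depth = dp, qual = 50, stringsAsFactors = FALSE)
      } else {
        data.frame(chrom = chrom_of[plan$gene[i]], pos = norm_pos[i],
                   ref = norm_ref[i], alt = norm_alt[i], zygosity = zyg,
                   site_depth = dp, qual = 50, stringsAsFactors = FALSE)
      }
    })
    # benign extra calls outside every slot region (distance 200 into intron 1)
    extra <- lapply(seq_len(min(extra_calls_per_patient, length(models))), function(k) {
      m <- models[[k]]
      pos0 <- m$exon_ends[1L] + 200L + k
      b <- refchars[[m$chrom]][pos0 + 1L]
      data.frame(chrom = m$chrom, pos = pos0 + 1L, ref = b, alt = next_base(b),
                 zygosity = "het", site_depth = mean_depth, qual = 50,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, extra))
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(calls_by_patient) <- patients

  # per-patient depth tracks: exon footprints at the gene's profile depth,
  # intron interiors at a modest depth, per-variant overrides planted on top
  tracks_by_patient <- lapply(patients, function(p) {
    pieces <- lapply(seq_len(nrow(genes_spec)), function(gi) {
      g <- genes_spec[gi, ]
      m <- models[[gi]]
      span_end <- max(m$exon_ends) + 200L
      depth_vec <- integer(span_end)           # index = 0-based pos + 1
      first <- min(m$exon_starts) - flank_pad
      last <- max(m$exon_ends) + flank_pad
      low <- g$low_cov_fraction > 0.25
      depth_vec[(first + 1L):last] <- if (low) 5L else 15L  # intron interior
      fp <- gene_footprint(m)
      for (r in seq_len(nrow(fp))) {
        s <- fp$start0[r]; e <- fp$end0[r]
        if (g$low_cov_fraction > 0) {
          n_low <- as.integer(round((e - s) * g$low_cov_fraction))
          if (n_low > 0L) depth_vec[(e - n_low + 1L):e] <- 6L
          if (e - n_low > s) depth_vec[(s + 1L):(e - n_low)] <- g$mean_depth
        } else {
          depth_vec[(s + 1L):e] <- g$mean_depth
        }
      }
      own <- which(plan$patient_id == p & plan$gene == g$gene)
      for (i in own) {
        if (isTRUE(plan$low_depth[i])) depth_vec[pos[i]] <- 7L
        else if (plan$fate[i] == "missing" && plan$stratum[i] == "coding")
          depth_vec[pos[i]] <- site_dp[i]
      }
      r <- rle(depth_vec)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values > 0L
      data.frame(chrom = m$chrom, start0 = starts[keep], end0 = ends[keep],
                 depth = r$values[keep], stringsAsFactors = FALSE)
    })
    depth_track(do.call(rbind, pieces))
  })
  names(tracks_by_patient) <- patients

  conf_idx <- which(plan$confirm != "none")
  confirmatory <- if (length(conf_idx)) {
    do.call(rbind, lapply(conf_idx, function(i) {
      kind <- plan$confirm[i]
      obs_ref <- norm_ref[i]
      obs_allele <- switch(kind,
        sanger = norm_alt[i],
        wes = if (plan$fate[i] == "zygosity_flip") norm_alt[i] else obs_ref,
        reference = obs_ref)
      obs_zyg <- switch(kind,
        sanger = plan$zygosity[i],
        wes = if (plan$fate[i] == "zygosity_flip") plan$wes_zygosity[i] else "ref",
        reference = "ref")
      data.frame(patient_id = plan$patient_id[i], chrom = chrom_of[plan$gene[i]],
                 pos = norm_pos[i], observed_ref = obs_ref,
                 observed_allele = obs_allele, observed_zygosity = obs_zyg,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(patient_id = character(0), chrom = character(0), pos = integer(0),
               observed_ref = character(0), observed_allele = character(0),
               observed_zygosity = character(0), stringsAsFactors = FALSE)
  }

  manifest <- list(
    seed = seed,
    n_patients = length(patients),
    genes = genes_spec,
    designed_excluded_genes = sort(genes_spec$gene[genes_spec$low_cov_fraction > 0.25]),
    thresholds = list(min_reads = min_reads, min_allele_fraction = min_allele_fraction,
                      depth_threshold = depth_threshold, min_fraction = 0.75,
                      low_depth = 10L, flank_pad = flank_pad, near_max = 20L),
    variants = cbind(plan, data.frame(pos = pos, ref = ref, alt = alt,
                                      norm_pos = norm_pos, norm_ref = norm_ref,
                                      norm_alt = norm_alt,
                                      site_depth = site_dp,
                                      stringsAsFactors = FALSE))
  )

  list(models = models, genes_spec = genes_spec, reference = reference,
       truth = truth, calls_by_patient = calls_by_patient,
       tracks_by_patient = tracks_by_patient, confirmatory = confirmatory,
       manifest = manifest, plan = plan)
}

# ---- random cohorts ---------------------------------------------------------

#' Generate a synthetic cohort in memory
#'
#' Draws a per-variant plan from the configuration's probabilities (each
#' variant's fate is planted — concordant, missing from WES, discordant base
#' or zygosity flip — and the generated VCFs, depth tracks and confirmatory
#' table are constructed to be exactly consistent with it), then realizes
#' gene models, reference, truth table, per-patient calls and depth tracks.
#'
#' @param config A `sim_config`.
#' @return A bundle list with `models`, `reference`, `truth`,
#'   `calls_by_patient`, `tracks_by_patient`, `confirmatory`, `manifest`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  strata <- c("coding", "intronic_near", "intronic_deep")
  rows <- list()
  gi <- 0L
  for (p in patients) {
    for (s in strata) {
      k <- config$variants_per_patient[[s]]
      if (k == 0L) next
      for (j in seq_len(k)) {
        gi <- gi + 1L
        gene <- config$genes$gene[(gi - 1L) %% nrow(config$genes) + 1L]
        fate <- sample(c("concordant", "missing", "discordant_base", "zygosity_flip"),
                       1L, prob = c(1 - config$p_missing - config$p_discordant_base -
                                      config$p_zygosity_flip,
                                    config$p_missing, config$p_discordant_base,
                                    config$p_zygosity_flip))
        zyg <- if (stats::runif(1L) < config$p_hom) "hom" else "het"
        is_indel <- s != "coding" && stats::runif(1L) < config$p_indel &&
          fate == "concordant"
        type <- if (!is_indel) "snv" else if (stats::runif(1L) < 0.5) "del" else "ins"
        rows[[gi]] <- data.frame(
          patient_id = p, gene = gene, stratum = s, type = type,
          indel_len = if (type == "del") sample(1:2, 1L) else 1L,
          fate = fate, zygosity = zyg,
          wes_zygosity = if (fate == "zygosity_flip") {
            if (zyg == "het") "hom" else "het"
          } else NA_character_,
          low_depth = FALSE,
          confirm = switch(fate, concordant = "none", missing = "sanger",
                           discordant_base = "reference",
                           zygosity_flip = if (stats::runif(1L) < 0.5) "sanger" else "wes"),
          use_hgvs = FALSE, upstream_dist = NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  plan <- do.call(rbind, rows)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  realize_cohort(config$genes, plan, seed = config$seed + 1L,
                 min_reads = config$min_reads,
                 min_allele_fraction = config$min_allele_fraction,
                 mean_depth = config$mean_depth, flank_pad = config$flank_pad)
}

#' Write a cohort bundle to a directory
#'
#' Emits `genes.tsv`, `reference.fa`, `truth.tsv`, `confirmatory.tsv`,
#' `depth/<patient>.bedgraph`, `vcf/<patient>.vcf` and `manifest.json`. Every
#' file parses with the corresponding package reader. Writing is
#' deterministic: identical bundles give byte-identical directories.
#'
#' @param bundle A bundle from [generate_cohort()] or [build_paper_fixture()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "vcf"), showWarnings = FALSE)
  write_gene_models(bundle$models, file.path(out_dir, "genes.tsv"))
  Biostrings::writeXStringSet(bundle$reference, file.path(out_dir, "reference.fa"))
  truth_out <- bundle$truth
  blank <- which(bundle$plan$use_hgvs)
  if (length(blank)) truth_out$pos[blank] <- NA_integer_
  write_truth_table(truth_out, file.path(out_dir, "truth.tsv"))
  utils::write.table(bundle$confirmatory, file.path(out_dir, "confirmatory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (p in names(bundle$calls_by_patient)) {
    write_vcf(bundle$calls_by_patient[[p]], file.path(out_dir, "vcf", paste0(p, ".vcf")),
              sample = p, contigs = names(bundle$reference))
    write_depth_track(bundle$tracks_by_patient[[p]],
                      file.path(out_dir, "depth", paste0(p, ".bedgraph")))
  }
  manifest <- bundle$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' Generate a complete synthetic study on disk
#'
#' @param config A `sim_config` (or path to a YAML config).
#' @param out_dir Output directory.
#' @return The bundle, invisibly; files are written under `out_dir`.
#' @export
generate_study <- function(config, out_dir) {
  if (is.character(config)) config <- read_sim_config(config)
  bundle <- generate_cohort(config)
  write_bundle(bundle, out_dir)
  invisible(bundle)
}
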