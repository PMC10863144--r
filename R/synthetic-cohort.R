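# Synthetic cohort generator.
#
# Emulates the study design the downstream analysis assumes: per patient a
# relapsed tumor (PZ), two serial xenograft generations (P1, P2) and a 3D
# tumor-sphere culture grown from P2 (P2_3D). Tumor variant tables carry
# exemplars passing and failing every filtration rule; planted actionable
# lesions, drift events (variant loss, VAF scaling) and planted expression
# outliers are recorded in a truth ledger so parameter-recovery tests can
# compare pipeline output against the generating truth.

STAGES <- c("PZ", "P1", "P2", "P2_3D")

#' Simulation configuration
#'
#' All knobs of the synthetic cohort, validated up front. Defaults are the
#' study conditions the package is tested under; see the methods vignette
#' for the rationale behind each value.
#'
#' @param seed RNG seed (integer).
#' @param n_patients number of patients, each with a full PZ/P1/P2/P2_3D
#'   lineage.
#' @param n_background_variants_per_tumor background somatic calls per
#'   tumor, spanning passing and failing exemplars of every rule.
#' @param planted_actionable_snvs_per_tumor actionable SNV/INDELs planted
#'   per tumor (0 or more).
#' @param planted_cnv_probability probability that a tumor carries one
#'   planted actionable CNV.
#' @param planted_outlier_genes_per_sample over-expression outlier genes
#'   planted per patient (in every sample of the lineage).
#' @param hypermutator_flag_probability probability a tumor is a
#'   hypermutator (receives enough extra missense calls to cross the TMB
#'   actionability threshold).
#' @param germline_carrier_probability probability a patient carries a
#'   pathogenic germline variant in a predisposition gene.
#' @param p1_variant_loss_rate expected share of PZ variants absent at P1.
#' @param p2_additional_loss_rate additional loss from P1 to P2.
#' @param p3d_additional_loss_rate additional loss from P2 to the 3D model.
#' @param pdx_gain_rate share of the origin variant count arising newly at
#'   each xenograft generation.
#' @param vaf_inflation_p1 multiplicative VAF factor at P1 (tumor-cell
#'   enrichment in the xenograft; clipped to 1).
#' @param vaf_inflation_p2 multiplicative VAF factor from P1 to P2.
#' @param vaf_deflation_3d multiplicative VAF factor from P2 to the 3D
#'   model (< 1: stromal/clonal dilution in culture).
#' @param vaf_jitter_sd Gaussian jitter added to drifted VAFs.
#' @param subthreshold_vaf_fraction share of background variants below the
#'   5% VAF gate (exercises the VAF filter).
#' @param beta_shape1,beta_shape2 Beta parameters of the clonal background
#'   VAF distribution (truncated below at 0.05).
#' @param n_genes_expression genes in the expression matrix (>= 50).
#' @param outlier_fold_change fold change applied to planted outlier genes
#'   (1 disables planting).
#' @param panel_length_bp,exome_length_bp targeted-region lengths used for
#'   TMB (defaults: 3,040,053 and 38,289,292 bp).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 5L,
                              n_background_variants_per_tumor = 200L,
                              planted_actionable_snvs_per_tumor = 2L,
                              planted_cnv_probability = 0.4,
                              planted_outlier_genes_per_sample = 1L,
                              hypermutator_flag_probability = 1 / 19,
                              germline_carrier_probability = 2 / 17,
                              p1_variant_loss_rate = 0.2,
                              p2_additional_loss_rate = 0.05,
                              p3d_additional_loss_rate = 0.3,
                              pdx_gain_rate = 0.02,
                              vaf_inflation_p1 = 1.3,
                              vaf_inflation_p2 = 1.05,
                              vaf_deflation_3d = 0.7,
                              vaf_jitter_sd = 0.02,
                              subthreshold_vaf_fraction = 0.15,
                              beta_shape1 = 2,
                              beta_shape2 = 5,
                              n_genes_expression = 500L,
                              outlier_fold_change = 16,
                              panel_length_bp = 3040053L,
                              exome_length_bp = 38289292L) {
  config <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_background_variants_per_tumor = as.integer(n_background_variants_per_tumor),
                 planted_actionable_snvs_per_tumor = as.integer(planted_actionable_snvs_per_tumor),
                 planted_cnv_probability = planted_cnv_probability,
                 planted_outlier_genes_per_sample = as.integer(planted_outlier_genes_per_sample),
                 hypermutator_flag_probability = hypermutator_flag_probability,
                 germline_carrier_probability = germline_carrier_probability,
                 p1_variant_loss_rate = p1_variant_loss_rate,
                 p2_additional_loss_rate = p2_additional_loss_rate,
                 p3d_additional_loss_rate = p3d_additional_loss_rate,
                 pdx_gain_rate = pdx_gain_rate,
                 vaf_inflation_p1 = vaf_inflation_p1,
                 vaf_inflation_p2 = vaf_inflation_p2,
                 vaf_deflation_3d = vaf_deflation_3d,
                 vaf_jitter_sd = vaf_jitter_sd,
                 subthreshold_vaf_fraction = subthreshold_vaf_fraction,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 n_genes_expression = as.integer(n_genes_expression),
                 outlier_fold_change = outlier_fold_change,
                 panel_length_bp = as.integer(panel_length_bp),
                 exome_length_bp = as.integer(exome_length_bp))
  rates <- c("planted_cnv_probability", "hypermutator_flag_probability",
             "germline_carrier_probability", "p1_variant_loss_rate",
             "p2_additional_loss_rate", "p3d_additional_loss_rate",
             "pdx_gain_rate", "subthreshold_vaf_fraction")
  for (f in rates)
    if (!is.numeric(config[[f]]) || is.na(config[[f]]) ||
        config[[f]] < 0 || config[[f]] > 1)
      stop_config("field '", f, "' must be a rate in [0, 1]")
  positive <- c("vaf_inflation_p1", "vaf_inflation_p2", "vaf_deflation_3d",
                "beta_shape1", "beta_shape2", "outlier_fold_change")
  for (f in positive)
    if (!is.numeric(config[[f]]) || is.na(config[[f]]) || config[[f]] <= 0)
      stop_config("field '", f, "' must be positive")
  counts <- c("n_patients", "n_background_variants_per_tumor",
              "planted_actionable_snvs_per_tumor",
              "planted_outlier_genes_per_sample",
              "panel_length_bp", "exome_length_bp", "n_genes_expression")
  for (f in counts)
    if (is.na(config[[f]]) || config[[f]] < 0)
      stop_config("field '", f, "' must be a non-negative count")
  if (config$n_patients < 1) stop_config("field 'n_patients' must be >= 1")
  if (config$panel_length_bp <= 0 || config$exome_length_bp <= 0)
    stop_config("field 'panel_length_bp'/'exome_length_bp' must be positive")
  if (config$n_genes_expression < 50)
    stop_config("field 'n_genes_expression' must be >= 50")
  if (config$vaf_jitter_sd < 0) stop_config("field 'vaf_jitter_sd' must be >= 0")
  structure(config, class = "simulation_config")
}

# ---- synthetic genome geometry -------------------------------------------
# Disjoint position pools keep variant keys collision-free by construction:
#   chr1 target sub-intervals double as segmental duplications,
#   chr2..chr4 targets host background calls, gaps on chr2 are off-target,
#   chr5 targets host variants gained in xenograft passages,
#   chr6 targets host planted lesions and hypermutator extras.

synthetic_regions <- function() {
  interval_block <- function(chrom, n = 60, width = 2000) {
    start <- 100000L + (seq_len(n) - 1L) * 10000L
    data.frame(chrom = chrom, start = start, end = start + width,
               stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, lapply(paste0("chr", 1:6), interval_block))
  segdups <- interval_block("chr1", n = 20, width = 2000)
  segdups$start <- segdups$start + 500L
  segdups$end <- segdups$start + 500L
  gaps <- data.frame(chrom = "chr2",
                     start = 100000L + (seq_len(60) - 1L) * 10000L + 5000L,
                     end = 100000L + (seq_len(60) - 1L) * 10000L + 6000L,
                     stringsAsFactors = FALSE)
  list(targets = targets, segdups = segdups,
       pools = list(
         background = targets[targets$chrom %in% c("chr2", "chr3", "chr4"), ],
         segdup = segdups,
         off_target = gaps,
         gain = targets[targets$chrom == "chr5", ],
         planted = targets[targets$chrom == "chr6", ]))
}

# n distinct 1-based positions from a pool of 0-based half-open intervals
sample_pool_positions <- function(pool, n) {
  widths <- pool$end - pool$start
  total <- sum(widths)
  if (n > total) stop_config("position pool exhausted")
  idx <- sample.int(total, n)
  cum <- cumsum(widths)
  iv <- findInterval(idx - 1L, c(0L, cum), rightmost.closed = FALSE)
  offset <- idx - c(0L, cum)[iv]
  data.frame(chrom = pool$chrom[iv], pos = pool$start[iv] + offset,
             stringsAsFactors = FALSE)
}

rtruncbeta <- function(n, shape1, shape2, lower) {
  qbeta(runif(n, pbeta(lower, shape1, shape2), 1), shape1, shape2)
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

# depth/alt-read pair consistent with a target VAF; returns adjusted VAF
reads_for_vaf <- function(vaf, depth) {
  alt <- pmax(1L, as.integer(round(vaf * depth)))
  list(alt = alt, depth = depth, vaf = alt / depth)
}

# Background somatic calls for one tumor. Each call is assigned a category
# that violates exactly one filtration rule (or none), so every rule has
# passing and failing exemplars and the somatic cascade's behaviour is
# fully exercised.
r_background_variants <- function(n, config, pools) {
  probs <- c(pass = 1 - 0.05 - 0.05 - 0.10 - 0.06 - 0.08 - 0.05 -
               config$subthreshold_vaf_fraction,
             caller_fail = 0.05, segdup = 0.05, common = 0.10,
             off_target = 0.06, synonymous = 0.08, low_support = 0.05,
             low_vaf = config$subthreshold_vaf_fraction)
  if (probs[["pass"]] <= 0)
    stop_config("field 'subthreshold_vaf_fraction' leaves no passing variants")
  category <- sample(names(probs), n, replace = TRUE, prob = probs)

  v <- data.frame(chrom = NA_character_, pos = NA_integer_,
                  stringsAsFactors = FALSE)[rep(1, n), ]
  for (pool_name in c("background", "segdup", "off_target")) {
    sel <- switch(pool_name,
                  background = !(category %in% c("segdup", "off_target")),
                  segdup = category == "segdup",
                  off_target = category == "off_target")
    if (any(sel)) {
      pos <- sample_pool_positions(pools[[pool_name]], sum(sel))
      v$chrom[sel] <- pos$chrom
      v$pos[sel] <- pos$pos
    }
  }
  v <- cbind(v, random_alleles(n))
  rownames(v) <- NULL

  nonsyn <- c("missense", "stopgain", "frameshift", "inframe_indel",
              "splice", "other_exonic")
  v$consequence <- ifelse(category == "synonymous", "synonymous",
                          sample(nonsyn, n, replace = TRUE,
                                 prob = c(0.6, 0.08, 0.08, 0.08, 0.08, 0.08)))
  v$gene <- sprintf("BG%03d", sample.int(400, n, replace = TRUE))
  v$caller_pass <- category != "caller_fail"
  v$in_segdup <- category == "segdup"
  v$on_target <- category != "off_target"

  pop_kind <- sample(c("absent", "very_rare", "rare"), n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.2))
  v$popmax_af <- ifelse(pop_kind == "absent", NA_real_,
                        ifelse(pop_kind == "very_rare", runif(n, 0, 0.0009),
                               runif(n, 0.0011, 0.009)))
  v$popmax_af[category == "common"] <- runif(sum(category == "common"),
                                             0.011, 0.2)
  v$in_cosmic <- runif(n) < 0.15
  v$cadd_phred <- ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 40))
  v$cancervar_score <- ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 1))
  v$clinvar_class <- sample(c("VUS", "Benign", "Likely_benign", NA),
                            n, replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2))
  v$intervar_class <- sample(c("VUS", "Benign", NA), n, replace = TRUE)
  v$hotspot <- FALSE

  # reads last: the VAF law depends on the category
  vaf <- rtruncbeta(n, config$beta_shape1, config$beta_shape2, 0.06)
  depth <- sample(150:400, n, replace = TRUE)
  low_vaf <- category == "low_vaf"
  vaf[low_vaf] <- runif(sum(low_vaf), 0.01, 0.045)
  rd <- reads_for_vaf(vaf, depth)
  low_sup <- category == "low_support"
  rd$alt[low_sup] <- sample(1:7, sum(low_sup), replace = TRUE)
  rd$depth[low_sup] <- pmax(rd$alt[low_sup],
                            floor(rd$alt[low_sup] / vaf[low_sup]))
  rd$vaf <- rd$alt / rd$depth
  # guard the 5% boundary after integer rounding
  fix <- !low_vaf & rd$vaf < 0.05
  rd$alt[fix] <- as.integer(ceiling(0.05 * rd$depth[fix]))
  fix2 <- low_vaf & rd$alt / rd$depth >= 0.05
  rd$alt[fix2] <- pmax(1L, as.integer(floor(0.049 * rd$depth[fix2])))
  v$alt_reads <- rd$alt
  v$depth <- rd$depth
  v$vaf <- rd$alt / rd$depth
  v$category <- category
  v
}

# planting tables: gene, lesion shape and the priority the grading rules
# assign by construction (validated direct target + known effect -> very
# high; pathway-level evidence -> high)
SNV_PLANT_TABLE <- data.frame(
  gene = c("ALK", "PIK3CA", "ATRX", "TP53", "BRAF", "MTOR"),
  consequence = c("missense", "missense", "frameshift", "stopgain",
                  "missense", "missense"),
  effect = c("GOF", "GOF", "LOF", "LOF", "GOF", "GOF"),
  expected_priority = c("VERY_HIGH", "VERY_HIGH", "HIGH", "HIGH",
                        "VERY_HIGH", "VERY_HIGH"),
  stringsAsFactors = FALSE)

CNV_PLANT_TABLE <- data.frame(
  gene = c("MYCN", "MDM2", "CDKN2A", "ATRX"),
  kind = c("amplification", "amplification", "deletion", "deletion"),
  expected_priority = c("VERY_HIGH", "VERY_HIGH", "VERY_HIGH", "HIGH"),
  stringsAsFactors = FALSE)

OUTLIER_PLANT_GENES <- c("CDK6", "CCND1", "TOP2A", "HIF1A", "MDM2", "PSMC2")

planted_snvs <- function(patient_idx, n, pos) {
  if (n == 0) return(NULL)
  rows <- ((patient_idx - 1) * n + seq_len(n) - 1) %% nrow(SNV_PLANT_TABLE) + 1
  tab <- SNV_PLANT_TABLE[rows, ]
  vaf <- runif(n, 0.15, 0.5)
  rd <- reads_for_vaf(vaf, sample(200:400, n, replace = TRUE))
  alleles <- random_alleles(n)
  data.frame(chrom = pos$chrom, pos = pos$pos, ref = alleles$ref,
             alt = alleles$alt, consequence = tab$consequence,
             gene = tab$gene, caller_pass = TRUE, in_segdup = FALSE,
             on_target = TRUE, popmax_af = NA_real_, in_cosmic = TRUE,
             cadd_phred = runif(n, 25, 40),
             cancervar_score = runif(n, 0.85, 0.99),
             clinvar_class = "Pathogenic", intervar_class = "Pathogenic",
             hotspot = tab$effect == "GOF" & tab$consequence == "missense",
             alt_reads = rd$alt, depth = rd$depth, vaf = rd$vaf,
             category = "planted", expected_priority = tab$expected_priority,
             effect = tab$effect, stringsAsFactors = FALSE)
}

hypermutator_extras <- function(n, pos) {
  vaf <- rtruncbeta(n, 2, 5, 0.08)
  rd <- reads_for_vaf(vaf, sample(150:400, n, replace = TRUE))
  alleles <- random_alleles(n)
  data.frame(chrom = pos$chrom, pos = pos$pos, ref = alleles$ref,
             alt = alleles$alt, consequence = "missense",
             gene = sprintf("BG%03d", sample.int(400, n, replace = TRUE)),
             caller_pass = TRUE, in_segdup = FALSE, on_target = TRUE,
             popmax_af = NA_real_, in_cosmic = FALSE,
             cadd_phred = runif(n, 0, 20), cancervar_score = runif(n, 0, 0.5),
             clinvar_class = NA_character_, intervar_class = NA_character_,
             hotspot = FALSE, alt_reads = rd$alt, depth = rd$depth,
             vaf = rd$vaf, category = "hypermutator_extra",
             stringsAsFactors = FALSE)
}

# one drift transition: Bernoulli retention + multiplicative VAF scaling
# with Gaussian jitter, clipped into (0, 1]; read support re-simulated
drift_stage <- function(variants, loss_rate, vaf_factor, jitter_sd) {
  retained <- runif(nrow(variants)) >= loss_rate
  out <- variants[retained, , drop = FALSE]
  vaf <- clip01(out$vaf * vaf_factor + rnorm(nrow(out), 0, jitter_sd))
  vaf <- pmax(vaf, 0.01)
  rd <- reads_for_vaf(vaf, sample(150:400, nrow(out), replace = TRUE))
  out$alt_reads <- rd$alt
  out$depth <- rd$depth
  out$vaf <- rd$vaf
  list(variants = out, retained = retained)
}

#' Simulate a matched tumor / xenograft / 3D cohort
#'
#' Generates, per patient: a PZ tumor variant table (background calls with
#' per-rule exemplars plus planted actionable SNVs and hypermutator
#' extras), CNV segments (background plus planted actionable ones), a
#' germline table with occasional predisposition-gene carriers, MSI scores,
#' and drifted P1/P2/P2_3D variant tables (Bernoulli variant loss, VAF
#' inflation in the xenograft and deflation in 3D culture, plus newly
#' gained passage variants); a gene-by-sample expression count matrix with
#' planted over-expression outliers; target and segmental-duplication BEDs;
#' the built-in knowledge base; and a truth ledger (`$truth`) recording
#' every planted lesion with its expected priority, every drift event and
#' every planted outlier.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_cohort` list: `config`, `knowledge_base`, `samples`,
#'   `variants`, `cnvs`, `germline`, `msi`, `expression`, `targets`,
#'   `segdups`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stop_config("config must be created with simulation_config()")
  set.seed(config$seed)
  kb <- default_knowledge_base()
  geom <- synthetic_regions()
  n_extra_hyper <- as.integer(ceiling(5 * config$exome_length_bp / 1e6)) + 60L

  patients <- sprintf("Pz%02d", seq_len(config$n_patients))
  samples <- do.call(rbind, lapply(patients, function(p)
    data.frame(sample_id = paste(p, STAGES, sep = "_"), patient_id = p,
               stage = STAGES, stringsAsFactors = FALSE)))

  all_variants <- list()
  all_cnvs <- list()
  lesions <- list()
  drift_log <- list()
  germline <- list()
  carriers <- list()
  hyper_flags <- runif(config$n_patients) < config$hypermutator_flag_probability

  for (i in seq_along(patients)) {
    p <- patients[i]
    pz_id <- paste(p, "PZ", sep = "_")

    bg <- r_background_variants(config$n_background_variants_per_tumor,
                                config, geom$pools)
    bg$expected_priority <- NA_character_
    bg$effect <- NA_character_

    n_plant <- config$planted_actionable_snvs_per_tumor
    n_hyper <- if (hyper_flags[i]) n_extra_hyper else 0L
    planted_pos <- sample_pool_positions(geom$pools$planted, n_plant + n_hyper)
    pl <- planted_snvs(i, n_plant, planted_pos[seq_len(n_plant), , drop = FALSE])
    hx <- NULL
    if (n_hyper > 0) {
      hx <- hypermutator_extras(n_hyper,
                                planted_pos[n_plant + seq_len(n_hyper), , drop = FALSE])
      hx$expected_priority <- NA_character_
      hx$effect <- NA_character_
    }
    pz <- rbind(bg, if (!is.null(pl)) pl, if (!is.null(hx)) hx)
    pz$sample_id <- pz_id
    pz$patient_id <- p

    if (!is.null(pl))
      lesions[[length(lesions) + 1L]] <- data.frame(
        kind = "SNV_INDEL", gene = pl$gene, patient_id = p, sample_id = pz_id,
        expected_priority = pl$expected_priority, chrom = pl$chrom,
        pos = pl$pos, ref = pl$ref, alt = pl$alt, copy_number = NA_real_,
        stringsAsFactors = FALSE)
    if (hyper_flags[i])
      lesions[[length(lesions) + 1L]] <- data.frame(
        kind = "HYPERMUTATION", gene = NA_character_, patient_id = p,
        sample_id = pz_id, expected_priority = "VERY_HIGH",
        chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
        alt = NA_character_, copy_number = NA_real_, stringsAsFactors = FALSE)

    # ---- CNV segments ----------------------------------------------------
    cnv_rows <- list(
      data.frame(chrom = "chr10", start = 1e6L, end = 2e6L, copy_number = 3,
                 genes = "BG101,BG102", acmg_class = NA_character_,
                 igv_flag = "passed", stringsAsFactors = FALSE),
      data.frame(chrom = "chr10", start = 3e6L, end = 4e6L, copy_number = 9,
                 genes = "KRAS", acmg_class = NA_character_,
                 igv_flag = "passed", stringsAsFactors = FALSE),
      data.frame(chrom = "chr10", start = 5e6L, end = 6e6L, copy_number = 0,
                 genes = "RB1", acmg_class = "benign",
                 igv_flag = "passed", stringsAsFactors = FALSE),
      data.frame(chrom = "chr10", start = 7e6L, end = 8e6L, copy_number = 1,
                 genes = "PTEN", acmg_class = NA_character_,
                 igv_flag = "passed", stringsAsFactors = FALSE))
    planted_cnv <- NULL
    if (runif(1) < config$planted_cnv_probability) {
      row <- (i - 1) %% nrow(CNV_PLANT_TABLE) + 1
      tab <- CNV_PLANT_TABLE[row, ]
      cn <- if (tab$kind == "amplification") sample(12:60, 1) else 0
      planted_cnv <- data.frame(chrom = "chr11", start = 1e6L + i * 1e4L,
                                end = 15e5L + i * 1e4L, copy_number = cn,
                                genes = tab$gene, acmg_class = "pathogenic",
                                igv_flag = "passed", stringsAsFactors = FALSE)
      lesions[[length(lesions) + 1L]] <- data.frame(
        kind = "CNV", gene = tab$gene, patient_id = p, sample_id = pz_id,
        expected_priority = tab$expected_priority, chrom = NA_character_,
        pos = NA_integer_, ref = NA_character_, alt = NA_character_,
        copy_number = cn, stringsAsFactors = FALSE)
    }
    pz_cnv <- do.call(rbind, c(cnv_rows, list(planted_cnv)))
    pz_cnv$sample_id <- pz_id
    pz_cnv$patient_id <- p

    # ---- germline table --------------------------------------------------
    gl <- r_background_variants(20L, config, geom$pools)
    gl$sample_id <- paste(p, "germline", sep = "_")
    gl$patient_id <- p
    gl$expected_priority <- NA_character_
    gl$effect <- NA_character_
    is_carrier <- runif(1) < config$germline_carrier_probability
    if (is_carrier) {
      carrier_gene <- c("MITF", "TSHR")[(i %% 2) + 1]
      pos <- sample_pool_positions(geom$pools$planted, 1)
      al <- random_alleles(1)
      gv <- gl[1, ]
      gv$chrom <- pos$chrom; gv$pos <- pos$pos
      gv$ref <- al$ref; gv$alt <- al$alt
      gv$gene <- carrier_gene
      gv$consequence <- "missense"
      gv$caller_pass <- TRUE; gv$in_segdup <- FALSE; gv$on_target <- TRUE
      gv$popmax_af <- 0.0005
      gv$clinvar_class <- "Pathogenic"; gv$intervar_class <- "Pathogenic"
      rd <- reads_for_vaf(0.5, 300L)
      gv$alt_reads <- rd$alt; gv$depth <- rd$depth; gv$vaf <- rd$vaf
      gv$category <- "germline_carrier"
      gl <- rbind(gl, gv)
      carriers[[length(carriers) + 1L]] <-
        data.frame(patient_id = p, gene = carrier_gene, stringsAsFactors = FALSE)
    }
    germline[[i]] <- gl

    # ---- drift across generations ---------------------------------------
    n_gain <- as.integer(round(config$pdx_gain_rate * nrow(pz)))
    gain_pos <- if (n_gain > 0)
      sample_pool_positions(geom$pools$gain, 2L * n_gain) else NULL
    make_gains <- function(which_half, stage_id) {
      if (n_gain == 0) return(NULL)
      idx <- (which_half - 1L) * n_gain + seq_len(n_gain)
      g <- r_background_variants(n_gain, config, geom$pools)
      g$chrom <- gain_pos$chrom[idx]
      g$pos <- gain_pos$pos[idx]
      g$category <- "pdx_gain"
      g$expected_priority <- NA_character_
      g$effect <- NA_character_
      g$sample_id <- stage_id
      g$patient_id <- p
      g
    }

    p1_id <- paste(p, "P1", sep = "_")
    d1 <- drift_stage(pz, config$p1_variant_loss_rate,
                      config$vaf_inflation_p1, config$vaf_jitter_sd)
    p1 <- d1$variants
    p1$sample_id <- p1_id
    drift_log[[length(drift_log) + 1L]] <- data.frame(
      patient_id = p, key = variant_key(pz), stage = "P1",
      retained = d1$retained,
      vaf = replace(rep(NA_real_, nrow(pz)), d1$retained, p1$vaf),
      stringsAsFactors = FALSE)
    p1 <- rbind(p1, make_gains(1L, p1_id))

    p2_id <- paste(p, "P2", sep = "_")
    d2 <- drift_stage(p1, config$p2_additional_loss_rate,
                      config$vaf_inflation_p2, config$vaf_jitter_sd)
    p2 <- d2$variants
    p2$sample_id <- p2_id
    drift_log[[length(drift_log) + 1L]] <- data.frame(
      patient_id = p, key = variant_key(p1), stage = "P2",
      retained = d2$retained,
      vaf = replace(rep(NA_real_, nrow(p1)), d2$retained, p2$vaf),
      stringsAsFactors = FALSE)
    p2 <- rbind(p2, make_gains(2L, p2_id))

    p3d_id <- paste(p, "P2_3D", sep = "_")
    d3 <- drift_stage(p2, config$p3d_additional_loss_rate,
                      config$vaf_deflation_3d, config$vaf_jitter_sd)
    p3d <- d3$variants
    p3d$sample_id <- p3d_id
    drift_log[[length(drift_log) + 1L]] <- data.frame(
      patient_id = p, key = variant_key(p2), stage = "P2_3D",
      retained = d3$retained,
      vaf = replace(rep(NA_real_, nrow(p2)), d3$retained, p3d$vaf),
      stringsAsFactors = FALSE)

    all_variants[[i]] <- rbind(pz, p1, p2, p3d)

    # CNVs conserved across generations; amplifications tend to gain copies
    stage_cnv <- lapply(c("P1", "P2", "P2_3D"), function(st) {
      x <- pz_cnv
      x$sample_id <- paste(p, st, sep = "_")
      amp <- x$copy_number >= 10
      x$copy_number[amp] <- x$copy_number[amp] + sample(0:4, sum(amp), TRUE)
      x
    })
    all_cnvs[[i]] <- rbind(pz_cnv, do.call(rbind, stage_cnv))
  }

  variants <- do.call(rbind, all_variants)
  rownames(variants) <- NULL
  cnvs <- do.call(rbind, all_cnvs)
  rownames(cnvs) <- NULL

  msi <- data.frame(sample_id = samples$sample_id,
                    msi_score = runif(nrow(samples), 0, 6),
                    stringsAsFactors = FALSE)

  expr <- simulate_expression(config, samples)

  # planted outliers on knowledge-base genes in the originating tumor are
  # actionable lesions in their own right (validated direct targets)
  pz_ids <- samples$sample_id[samples$stage == "PZ"]
  ol <- expr$planted[expr$planted$sample_id %in% pz_ids &
                       expr$planted$gene %in% kb$genes$symbol, , drop = FALSE]
  if (nrow(ol) > 0)
    lesions[[length(lesions) + 1L]] <- data.frame(
      kind = "OVEREXPRESSION", gene = ol$gene, patient_id = ol$patient_id,
      sample_id = ol$sample_id, expected_priority = "VERY_HIGH",
      chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
      alt = NA_character_, copy_number = NA_real_, stringsAsFactors = FALSE)

  truth <- list(
    lesions = if (length(lesions) > 0) do.call(rbind, lesions) else
      data.frame(kind = character(0), gene = character(0),
                 patient_id = character(0), sample_id = character(0),
                 expected_priority = character(0), stringsAsFactors = FALSE),
    drift = do.call(rbind, drift_log),
    outliers = expr$planted,
    hypermutators = patients[hyper_flags],
    germline_carriers = if (length(carriers) > 0) do.call(rbind, carriers) else
      data.frame(patient_id = character(0), gene = character(0),
                 stringsAsFactors = FALSE))

  structure(list(config = config, knowledge_base = kb, samples = samples,
                 variants = variants, cnvs = cnvs,
                 germline = do.call(rbind, germline), msi = msi,
                 expression = expr$counts, targets = geom$targets,
                 segdups = geom$segdups, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_patients, "patients,",
      nrow(x$samples), "samples,", nrow(x$variants), "variant calls\n")
  cat("  planted lesions:", nrow(x$truth$lesions),
      "| planted outliers:", nrow(x$truth$outliers), "\n")
  invisible(x)
}

#' Simulate a gene-by-sample expression count matrix
#'
#' Counts are Poisson draws around lognormal gene baselines with a shared
#' per-patient (lineage) effect, so samples of one lineage correlate more
#' strongly with each other than with other lineages. A pool of
#' high-baseline genes (the knowledge base's over-expression targets plus
#' synthetic fillers) hosts the planted outliers: their counts are scaled
#' by `outlier_fold_change` in exactly the designated samples. With fold
#' change 1 nothing is planted and the ledger is empty.
#'
#' @param config a [simulation_config()].
#' @param samples sample table with `sample_id` and `patient_id` columns.
#' @param planted explicit data.frame of (gene, sample_id) assignments, or
#'   NULL to plant `planted_outlier_genes_per_sample` pool genes per
#'   patient across all samples of that patient's lineage.
#' @param seed optional seed; leave NULL when calling inside
#'   [simulate_cohort()] (which seeds the stream once).
#' @return list with `counts` (integer matrix), `planted` (the ledger:
#'   gene, sample_id, patient_id) and `pool_genes`.
#' @export
simulate_expression <- function(config, samples, planted = NULL, seed = NULL) {
  if (config$n_genes_expression < 50)
    stop_config("field 'n_genes_expression' must be >= 50")
  if (!is.null(seed)) set.seed(seed)
  n_pool <- 40L
  pool_genes <- c(OUTLIER_PLANT_GENES,
                  sprintf("HX%02d", seq_len(n_pool - length(OUTLIER_PLANT_GENES))))
  other_kb <- setdiff(default_knowledge_base()$genes$symbol, pool_genes)
  n_bg <- max(0L, config$n_genes_expression - n_pool - length(other_kb))
  genes <- c(pool_genes, other_kb, sprintf("EXPR%04d", seq_len(n_bg)))

  # pool genes sit ~1.5 log2 units above the background mean so that a
  # planted fold change of 8+ clears the z >= 3 call with a wide margin
  # while unplanted pool genes stay well below it
  base <- c(rnorm(n_pool, 5.05, 0.15), rnorm(length(other_kb), 4, 0.5),
            rnorm(n_bg, 4, 0.7))
  names(base) <- genes

  patients <- unique(samples$patient_id)
  lineage_eff <- matrix(rnorm(length(genes) * length(patients), 0, 0.2),
                        nrow = length(genes),
                        dimnames = list(genes, patients))
  noise <- matrix(rnorm(length(genes) * nrow(samples), 0, 0.15),
                  nrow = length(genes),
                  dimnames = list(genes, samples$sample_id))
  lambda <- exp(base + lineage_eff[, samples$patient_id] + noise)
  counts <- matrix(rpois(length(lambda), lambda), nrow = length(genes),
                   dimnames = list(genes, samples$sample_id))

  if (is.null(planted)) {
    planted <- if (config$outlier_fold_change > 1 &&
                   config$planted_outlier_genes_per_sample > 0) {
      do.call(rbind, lapply(seq_along(patients), function(i) {
        k <- config$planted_outlier_genes_per_sample
        g <- pool_genes[(((i - 1) * k + seq_len(k)) - 1) %% n_pool + 1]
        sids <- samples$sample_id[samples$patient_id == patients[i]]
        expand.grid(gene = g, sample_id = sids, stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(gene = character(0), sample_id = character(0),
                 stringsAsFactors = FALSE)
    }
  }
  if (nrow(planted) > 0 && config$outlier_fold_change > 1) {
    idx <- cbind(match(planted$gene, genes),
                 match(planted$sample_id, samples$sample_id))
    counts[idx] <- as.integer(round(counts[idx] * config$outlier_fold_change))
  }
  planted$patient_id <- samples$patient_id[match(planted$sample_id,
                                                 samples$sample_id)]
  list(counts = counts, planted = planted, pool_genes = pool_genes)
}
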