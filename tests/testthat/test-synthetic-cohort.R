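test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(p1_variant_loss_rate = 1.2),
               "p1_variant_loss_rate")
  expect_error(simulation_config(planted_cnv_probability = -0.1),
               "planted_cnv_probability")
  expect_error(simulation_config(vaf_inflation_p1 = 0), "vaf_inflation_p1")
  expect_error(simulation_config(n_genes_expression = 10),
               "n_genes_expression")
  expect_error(simulation_config(n_patients = 0), "n_patients")
})

test_that("one seed gives identical cohorts across invocations", {
  a <- simulate_cohort(tiny_simulation_config(seed = 11))
  b <- simulate_cohort(tiny_simulation_config(seed = 11))
  expect_identical(a$variants, b$variants)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(tiny_simulation_config(seed = 12))
  expect_false(identical(a$variants, c$variants))
})

test_that("zero loss keeps every originating-tumor variant at P1", {
  co <- simulate_cohort(tiny_simulation_config(seed = 2,
                                               p1_variant_loss_rate = 0))
  expect_true(all(co$truth$drift$retained[co$truth$drift$stage == "P1"]))
  for (p in unique(co$samples$patient_id)) {
    pz <- co$variants[co$variants$sample_id == paste0(p, "_PZ"), ]
    p1 <- co$variants[co$variants$sample_id == paste0(p, "_P1"), ]
    expect_equal(conserved_fraction(pz, p1)$fraction, 1)
  }
})

test_that("the mean conserved fraction recovers the generating loss rate", {
  fr <- vapply(1:20, function(seed) {
    co <- simulate_cohort(simulation_config(
      seed = seed, n_patients = 1, n_background_variants_per_tumor = 500,
      p1_variant_loss_rate = 0.2, planted_actionable_snvs_per_tumor = 0,
      hypermutator_flag_probability = 0, pdx_gain_rate = 0))
    pz <- co$variants[co$variants$sample_id == "Pz01_PZ", ]
    p1 <- co$variants[co$variants$sample_id == "Pz01_P1", ]
    conserved_fraction(pz, p1)$fraction
  }, numeric(1))
  se <- sqrt(0.2 * 0.8 / 500) / sqrt(20)
  expect_lt(abs(mean(fr) - 0.8), 3 * se)
})

test_that("the truth ledger lists each planted lesion once and they survive the filters they target", {
  co <- simulate_cohort(simulation_config(seed = 7, planted_cnv_probability = 1))
  lesions <- co$truth$lesions
  expect_equal(anyDuplicated(lesions[, c("kind", "gene", "sample_id")]), 0)
  snv <- lesions[lesions$kind == "SNV_INDEL", ]
  pz <- co$variants[co$variants$sample_id %in% snv$sample_id, ]
  kept <- filter_somatic(pz)$kept
  prio <- prioritize_pathogenic(kept)
  expect_true(all(paste(snv$chrom, snv$pos, snv$ref, snv$alt) %in%
                    paste(prio$chrom, prio$pos, prio$ref, prio$alt)))
  cnv <- lesions[lesions$kind == "CNV", ]
  sel <- select_actionable_cnvs(
    co$cnvs[co$cnvs$sample_id %in% cnv$sample_id, ], co$knowledge_base)
  expect_true(all(paste(cnv$gene, cnv$sample_id) %in%
                    paste(sel$gene, sel$sample_id)))
})

test_that("VAF medians drift upward at P1 whenever inflation exceeds one", {
  for (seed in 4:6) {
    co <- simulate_cohort(tiny_simulation_config(seed = seed,
                                                 vaf_inflation_p1 = 1.3))
    pz <- co$variants$vaf[grepl("_PZ$", co$variants$sample_id)]
    p1 <- co$variants$vaf[grepl("_P1$", co$variants$sample_id)]
    expect_gte(median(p1), median(pz))
  }
})

test_that("3D models lose VAF relative to their P2 xenografts", {
  co <- simulate_cohort(tiny_simulation_config(seed = 9))
  p2 <- co$variants$vaf[grepl("_P2$", co$variants$sample_id)]
  p3d <- co$variants$vaf[grepl("_P2_3D$", co$variants$sample_id)]
  expect_lt(median(p3d), median(p2))
})

test_that("expression planting honours the fold-change switch and the ledger", {
  cfg1 <- tiny_simulation_config(seed = 3, outlier_fold_change = 1)
  co1 <- simulate_cohort(cfg1)
  expect_equal(nrow(co1$truth$outliers), 0)

  cfg2 <- tiny_simulation_config(seed = 3, outlier_fold_change = 16)
  co2 <- simulate_cohort(cfg2)
  expect_gt(nrow(co2$truth$outliers), 0)
  # the planted cells really are scaled relative to the unplanted run
  idx <- cbind(match(co2$truth$outliers$gene, rownames(co2$expression)),
               match(co2$truth$outliers$sample_id, colnames(co2$expression)))
  expect_true(all(co2$expression[idx] >= 4 * co1$expression[idx]))
})

test_that("within-lineage expression correlation exceeds between-lineage correlation", {
  within <- c(); between <- c()
  for (seed in 1:10) {
    co <- simulate_cohort(tiny_simulation_config(seed = seed))
    cors <- cor(log2(co$expression + 1), method = "spearman")
    pat <- co$samples$patient_id[match(colnames(cors), co$samples$sample_id)]
    same <- outer(pat, pat, "==") & upper.tri(cors)
    within <- c(within, cors[same])
    between <- c(between, cors[!same & upper.tri(cors)])
  }
  expect_gt(mean(within), mean(between))
})

test_that("hypermutator tumors cross the TMB threshold and others do not", {
  co <- simulate_cohort(simulation_config(seed = 13, n_patients = 6,
                                          hypermutator_flag_probability = 0.5))
  expect_gt(length(co$truth$hypermutators), 0)
  for (p in unique(co$samples$patient_id)) {
    kept <- filter_somatic(
      co$variants[co$variants$sample_id == paste0(p, "_PZ"), ])$kept
    r <- compute_tmb(kept, co$config$exome_length_bp)
    expect_equal(r$actionable, p %in% co$truth$hypermutators)
  }
})
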