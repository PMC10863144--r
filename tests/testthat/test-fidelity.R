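lineage_variants <- function(sample_id, pos, vaf, chrom = "chr1") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = "A",
             alt = "T", vaf = vaf, stringsAsFactors = FALSE)
}

test_that("VAF matrix is the zero-filled union of per-sample calls", {
  v <- rbind(lineage_variants("A", 100L, 0.4), lineage_variants("B", 200L, 0.5))
  m <- build_vaf_matrix(v)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["A", "chr1:100:A:T"], 0.4)
  expect_equal(m["A", "chr1:200:A:T"], 0)
  expect_equal(m["B", "chr1:200:A:T"], 0.5)
  # identical call sets give identical rows
  v2 <- rbind(lineage_variants("A", c(1L, 2L), c(0.1, 0.2)),
              lineage_variants("B", c(1L, 2L), c(0.1, 0.2)))
  m2 <- build_vaf_matrix(v2)
  expect_equal(unname(m2["A", ]), unname(m2["B", ]))
  # missing-aware mode encodes absence as NA
  expect_true(is.na(build_vaf_matrix(v, absent = "na")["A", "chr1:200:A:T"]))
  dup <- rbind(lineage_variants("A", 5L, 0.3), lineage_variants("A", 5L, 0.4))
  expect_error(build_vaf_matrix(dup), "duplicate")
  # random batch: entries match per-sample lookups
  set.seed(12)
  r <- data.frame(sample_id = sample(c("s1", "s2", "s3"), 60, TRUE),
                  chrom = "chr2", pos = sample.int(1e5, 60), ref = "G",
                  alt = "C", vaf = runif(60), stringsAsFactors = FALSE)
  r <- r[!duplicated(r[, c("sample_id", "pos")]), ]
  mr <- build_vaf_matrix(r)
  for (i in sample(nrow(r), 10))
    expect_equal(mr[r$sample_id[i], variant_key(r[i, ])], r$vaf[i])
})

test_that("duplicated samples correlate perfectly, merge first, and coincide in PCA", {
  set.seed(13)
  base <- runif(30, 0.05, 0.6)
  m <- rbind(A = base, B = base, C = runif(30, 0.05, 0.6),
             D = runif(30, 0.05, 0.6))
  suite <- similarity_suite(m)
  expect_equal(suite$correlation["A", "B"], 1)
  expect_equal(unname(suite$correlation[cbind(rownames(m), rownames(m))]),
               rep(1, 4))
  expect_equal(suite$correlation, t(suite$correlation))
  expect_setequal(rownames(m)[suite$hclust$merge[1, ] * -1], c("A", "B"))
  expect_equal(unname(suite$pca$scores["A", ]), unname(suite$pca$scores["B", ]))
  expect_lte(sum(suite$pca$explained_variance), 1 + 1e-9)
  expect_error(similarity_suite(matrix(1, 3, 5)), "degenerate")
})

test_that("Ward merge heights match the Lance-Williams recurrence on a 3-sample toy", {
  m <- rbind(a = c(0, 1), b = c(3, 0), c = c(10, 4))
  suite <- similarity_suite(m)
  d_ab <- sqrt(10); d_ac <- sqrt(109); d_bc <- sqrt(65)
  h1 <- d_ab
  # ward.D2 Lance-Williams update for cluster {a,b} vs c
  h2 <- sqrt((2 * d_ac^2 + 2 * d_bc^2 - d_ab^2) / 3)
  expect_equal(unname(suite$hclust$height), c(h1, h2), tolerance = 1e-12)
})

test_that("two simulated lineages separate perfectly at the 2-cluster cut", {
  for (seed in 1:10) {
    set.seed(seed)
    pos1 <- 1:40 * 10L
    pos2 <- 1:40 * 10L + 100000L
    base1 <- runif(40, 0.1, 0.6)
    base2 <- runif(40, 0.1, 0.6)
    v <- do.call(rbind, c(
      lapply(1:5, function(i) lineage_variants(paste0("L1_", i), pos1,
                                               pmax(0.01, base1 + rnorm(40, 0, 0.02)))),
      lapply(1:5, function(i) lineage_variants(paste0("L2_", i), pos2,
                                               pmax(0.01, base2 + rnorm(40, 0, 0.02))))))
    suite <- similarity_suite(build_vaf_matrix(v))
    cut <- cutree(suite$hclust, k = 2)
    truth <- rep(1:2, each = 5)
    agree <- max(mean(cut == truth), mean(cut == 3 - truth))
    expect_equal(agree, 1)
  }
})

test_that("conserved fraction is shared-over-origin with the documented edge cases", {
  expect_equal(conserved_fraction(c("a", "b", "c"), c("a", "b", "c"))$fraction, 1)
  expect_equal(conserved_fraction(c("a", "b", "c"), c("a", "b", "d"))$fraction, 2 / 3)
  expect_equal(conserved_fraction(c("a", "b"), character(0))$fraction, 0)
  expect_true(is.na(conserved_fraction(character(0), c("a"))$fraction))
})

test_that("simulated loss rate is recovered by the conserved fraction", {
  set.seed(21)
  fr <- replicate(20, {
    origin <- paste0("v", 1:500)
    target <- origin[runif(500) >= 0.2]
    conserved_fraction(origin, target)$fraction
  })
  se <- sqrt(0.2 * 0.8 / 500) # binomial SE of one replicate
  expect_lt(abs(mean(fr) - 0.8), 3 * se / sqrt(20))
})

test_that("Mann-Whitney shift test matches enumeration and wilcox.test", {
  same <- vaf_shift_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$p_value, 1)
  sep <- vaf_shift_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(sep$u, 0)
  expect_equal(sep$p_value, 2 / choose(6, 3))   # 2 of the 20 assignments are as extreme
  # untied small samples agree with wilcox.test's exact two-sided p
  set.seed(31)
  for (i in 1:10) {
    a <- round(runif(6), 3); b <- round(runif(7), 3)
    if (anyDuplicated(c(a, b))) next
    got <- vaf_shift_test(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large samples take the tie-corrected normal approximation
  big <- vaf_shift_test(runif(50), runif(60))
  expect_match(big$method, "normal")
  expect_error(vaf_shift_test(numeric(0), 1), "non-empty")
})

test_that("VAF inflation at P1 is detected by the shift test", {
  detected <- 0
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed, n_patients = 2,
                             n_background_variants_per_tumor = 250,
                             vaf_inflation_p1 = 1.3)
    co <- simulate_cohort(cfg)
    pz_ids <- co$samples$sample_id[co$samples$stage == "PZ"]
    p1_ids <- co$samples$sample_id[co$samples$stage == "P1"]
    a <- co$variants$vaf[co$variants$sample_id %in% pz_ids]
    b <- co$variants$vaf[co$variants$sample_id %in% p1_ids]
    t <- vaf_shift_test(a, b)
    if (t$median_b > t$median_a && t$p_value < 0.01) detected <- detected + 1
  }
  expect_gte(detected, 9)
})

test_that("actionable events are tracked across stages with missingness preserved", {
  samples <- data.frame(sample_id = c("P_PZ", "P_P1", "P_P2"),
                        patient_id = "P", stage = c("PZ", "P1", "P2"),
                        stringsAsFactors = FALSE)
  variants <- rbind(lineage_variants("P_PZ", 100L, 0.2),
                    lineage_variants("P_P2", 100L, 0.5))
  events <- data.frame(patient_id = "P", sample_id = "P_PZ",
                       event_class = "SNV_INDEL", gene = "ALK",
                       chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                       priority = "VERY_HIGH", stringsAsFactors = FALSE)
  tr <- track_actionable(events, samples, variants)
  expect_equal(tr$value[tr$stage == "PZ"], 0.2)
  expect_true(is.na(tr$value[tr$stage == "P1"]))   # absent, not zero
  expect_equal(tr$value[tr$stage == "P2"], 0.5)
  # CNV trajectories report copy number by stage
  cnvs <- data.frame(sample_id = c("P_PZ", "P_P1"), chrom = "chr2",
                     start = 1L, end = 10L, copy_number = c(12, 14),
                     genes = "MYCN", stringsAsFactors = FALSE)
  cev <- data.frame(patient_id = "P", sample_id = "P_PZ",
                    event_class = "CNV", gene = "MYCN", chrom = NA, pos = NA,
                    ref = NA, alt = NA, priority = "VERY_HIGH",
                    stringsAsFactors = FALSE)
  trc <- track_actionable(cev, samples, variants, cnvs = cnvs)
  expect_equal(trc$value[trc$stage %in% c("PZ", "P1")], c(12, 14))
  expect_true(is.na(trc$value[trc$stage == "P2"]))
})

test_that("drift without loss and with inflation never decreases tracked VAFs", {
  cfg <- tiny_simulation_config(seed = 5, p1_variant_loss_rate = 0,
                                vaf_jitter_sd = 0, vaf_inflation_p1 = 1.2)
  co <- simulate_cohort(cfg)
  d <- co$truth$drift
  p1 <- d[d$stage == "P1", ]
  expect_true(all(p1$retained))
  pz_ids <- co$samples$sample_id[co$samples$stage == "PZ"]
  pz <- co$variants[co$variants$sample_id %in% pz_ids, ]
  vaf_pz <- pz$vaf[match(p1$key, variant_key(pz))]
  # read-depth re-rounding moves VAFs by less than 1/150
  expect_true(all(p1$vaf >= pmin(1, vaf_pz * 1.2) - 1 / 150))
})
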