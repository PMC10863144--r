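test_that("somatic cascade removes each rule's exemplar and keeps full passes", {
  planned <- rbind(
    make_variants(10, pos = 1:10 * 10L),                          # full pass
    make_variants(pos = 1001L, caller_pass = FALSE),
    make_variants(pos = 1002L, in_segdup = TRUE),
    make_variants(pos = 1003L, popmax_af = 0.02),
    make_variants(pos = 1004L, on_target = FALSE),
    make_variants(pos = 1005L, consequence = "synonymous"),
    make_variants(pos = 1006L, alt_reads = 7L, vaf = 0.20))
  res <- filter_somatic(planned)
  expect_equal(res$audit$kept_count, 10)
  expect_equal(unname(res$audit$removed_by_rule[c(
    "caller_fail", "segdup", "common_polymorphism", "off_target",
    "synonymous", "low_read_support")]), rep(1L, 6))
  expect_equal(unname(res$audit$removed_by_rule[["low_vaf"]]), 0L)
})

test_that("somatic thresholds behave as documented at their boundaries", {
  # strictly-greater MAF removal: 2% removed, exactly 1% kept
  expect_equal(nrow(filter_somatic(make_variants(popmax_af = 0.02))$kept), 0)
  expect_equal(nrow(filter_somatic(make_variants(popmax_af = 0.01))$kept), 1)
  # read support and VAF are independent inclusive minima
  expect_equal(nrow(filter_somatic(make_variants(alt_reads = 7L, vaf = 0.2))$kept), 0)
  expect_equal(nrow(filter_somatic(make_variants(alt_reads = 8L, vaf = 0.08,
                                                 depth = 100L))$kept), 1)
  low <- make_variants(alt_reads = 4L, depth = 100L, vaf = 0.04)
  expect_equal(nrow(filter_somatic(low)$kept), 0)
})

test_that("somatic filtering matches a brute-force per-record oracle", {
  for (seed in 1:3) {
    v <- random_variant_batch(400, seed)
    res <- filter_somatic(v)
    expect_equal(variant_key(res$kept),
                 variant_key(v[somatic_oracle_keep(v), ]))
    expect_equal(res$audit$kept_count + sum(res$audit$removed_by_rule),
                 res$audit$input_count)
  }
})

test_that("kept set is rule-order independent and filtering is idempotent", {
  v <- random_variant_batch(300, 7)
  res <- filter_somatic(v)
  # intersection of single-rule kept sets
  rules <- list(
    function(r) r$caller_pass, function(r) !r$in_segdup,
    function(r) is.na(r$popmax_af) | r$popmax_af <= 0.01,
    function(r) r$on_target, function(r) r$consequence != "synonymous",
    function(r) r$alt_reads >= 8, function(r) r$vaf >= 0.05)
  single_rule_keep <- Reduce(`&`, lapply(rules, function(f) f(v)))
  expect_equal(variant_key(res$kept), variant_key(v[single_rule_keep, ]))
  again <- filter_somatic(res$kept)
  expect_equal(again$audit$kept_count, nrow(res$kept))
  expect_true(all(again$audit$removed_by_rule == 0))
})

test_that("missing mandatory fields are rejected by name", {
  v <- make_variants()
  v$vaf <- NULL
  expect_error(filter_somatic(v), "vaf")
  bad <- make_variants(vaf = 1.5)
  expect_error(filter_somatic(bad), "VAF")
})

test_that("pathogenicity prioritization is strict in both scores", {
  expect_equal(nrow(prioritize_pathogenic(
    make_variants(cadd_phred = 21, cancervar_score = NA))), 1)
  expect_equal(nrow(prioritize_pathogenic(
    make_variants(cadd_phred = 20, cancervar_score = 0.80))), 0)
  expect_equal(nrow(prioritize_pathogenic(
    make_variants(cadd_phred = NA_real_, cancervar_score = 0.81))), 1)
  expect_equal(nrow(prioritize_pathogenic(
    make_variants(cadd_phred = NA_real_, cancervar_score = NA_real_))), 0)

  v <- random_variant_batch(1000, 11)
  got <- prioritize_pathogenic(v)
  oracle <- vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    (!is.na(r$cadd_phred) && r$cadd_phred > 20) ||
      (!is.na(r$cancervar_score) && r$cancervar_score > 0.80)
  }, logical(1))
  expect_equal(variant_key(got), variant_key(v[oracle, ]))
})

test_that("tumor-only rule removes frequent non-COSMIC variants only", {
  base <- function(popmax, cosmic) make_variants(popmax_af = popmax,
                                                 in_cosmic = cosmic)
  expect_equal(nrow(filter_tumor_only(base(0.01, TRUE))$kept), 1)   # rescued
  expect_equal(nrow(filter_tumor_only(base(0.01, FALSE))$kept), 0)
  expect_equal(nrow(filter_tumor_only(base(0.0005, FALSE))$kept), 1)
  # strict mode: each condition removes independently
  expect_equal(nrow(filter_tumor_only(base(0.01, TRUE),
                                      cosmic_rescue = FALSE)$kept), 0)
  expect_equal(nrow(filter_tumor_only(base(0.0005, TRUE),
                                      cosmic_rescue = FALSE)$kept), 1)
  # the shared somatic rules still apply first
  common <- make_variants(popmax_af = 0.05, in_cosmic = TRUE)
  res <- filter_tumor_only(common)
  expect_equal(unname(res$audit$removed_by_rule[["common_polymorphism"]]), 1L)
})

test_that("germline filtration keeps pathogenic predisposition-gene calls", {
  genes <- c("MITF", "TSHR", "TP53")
  carrier <- make_variants(gene = "MITF", clinvar_class = "Pathogenic")
  expect_equal(nrow(filter_germline(carrier, genes)$kept), 1)
  conflicting <- make_variants(gene = "MITF", clinvar_class = "Conflicting",
                               intervar_class = "Pathogenic")
  expect_equal(nrow(filter_germline(conflicting, genes)$kept), 0)
  off_list <- make_variants(gene = "GENE1", clinvar_class = "Pathogenic")
  expect_equal(nrow(filter_germline(off_list, genes)$kept), 0)
  intervar_only <- make_variants(gene = "TSHR",
                                 clinvar_class = NA_character_,
                                 intervar_class = "Likely_pathogenic")
  expect_equal(nrow(filter_germline(intervar_only, genes)$kept), 1)
  expect_error(filter_germline(carrier, character(0)), "non-empty")
})
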