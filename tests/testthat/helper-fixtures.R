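# Fixture builders shared across the test files. Everything is generated
# in code; no data files.

make_variants <- function(n = 1, chrom = "chr1", pos = seq_len(n) * 100L,
                          ref = "A", alt = "T", caller_pass = TRUE,
                          consequence = "missense", gene = "GENE1",
                          popmax_af = NA_real_, cadd_phred = 30,
                          cancervar_score = NA_real_,
                          clinvar_class = NA_character_,
                          intervar_class = NA_character_,
                          in_cosmic = FALSE, alt_reads = 20L, depth = 100L,
                          vaf = 0.2, in_segdup = FALSE, on_target = TRUE,
                          hotspot = FALSE, sample_id = "S1") {
  if (n == 0) return(make_variants(1)[0, , drop = FALSE])
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             caller_pass = caller_pass, consequence = consequence,
             gene = gene, popmax_af = popmax_af, cadd_phred = cadd_phred,
             cancervar_score = cancervar_score,
             clinvar_class = clinvar_class, intervar_class = intervar_class,
             in_cosmic = in_cosmic, alt_reads = alt_reads, depth = depth,
             vaf = vaf, in_segdup = in_segdup, on_target = on_target,
             hotspot = hotspot, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

# random annotated batch exercising every filtration rule
random_variant_batch <- function(n, seed) {
  set.seed(seed)
  v <- make_variants(n)
  v$pos <- sample.int(1e6, n)
  v$caller_pass <- runif(n) < 0.9
  v$in_segdup <- runif(n) < 0.1
  v$on_target <- runif(n) < 0.9
  v$consequence <- sample(c("missense", "synonymous", "stopgain",
                            "frameshift", "splice"), n, replace = TRUE)
  v$popmax_af <- ifelse(runif(n) < 0.4, NA_real_, runif(n, 0, 0.05))
  v$in_cosmic <- runif(n) < 0.3
  v$cadd_phred <- ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 40))
  v$cancervar_score <- ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 1))
  v$clinvar_class <- sample(c("Pathogenic", "Likely_pathogenic", "Benign",
                              "VUS", "Conflicting", NA), n, replace = TRUE)
  v$intervar_class <- sample(c("Pathogenic", "VUS", NA), n, replace = TRUE)
  v$depth <- sample(20:300, n, replace = TRUE)
  v$alt_reads <- pmin(v$depth, sample(1:60, n, replace = TRUE))
  v$vaf <- v$alt_reads / v$depth
  v$gene <- sample(c("ALK", "TP53", "MITF", "GENE1", "GENE2"), n, TRUE)
  v
}

# independent per-record re-implementation of the somatic predicate
somatic_oracle_keep <- function(v, maf = 0.01, min_alt = 8, min_vaf = 0.05) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    keep[i] <- isTRUE(r$caller_pass) && !isTRUE(r$in_segdup) &&
      (is.na(r$popmax_af) || r$popmax_af <= maf) && isTRUE(r$on_target) &&
      r$consequence != "synonymous" && r$alt_reads >= min_alt &&
      r$vaf >= min_vaf
  }
  keep
}

tiny_simulation_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_patients = 2,
                    n_background_variants_per_tumor = 60,
                    n_genes_expression = 120, ...)
}
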