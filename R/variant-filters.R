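# Small-variant filtration cascades: somatic, tumor-only, germline.
#
# Each cascade is an ordered list of removal rules. Rule order affects only
# the audit trail (a removed variant is attributed to the first failing
# rule); the kept set is the intersection of the single-rule kept sets.

CONSEQUENCES <- c("missense", "synonymous", "stopgain", "frameshift",
                  "inframe_indel", "splice", "other_exonic", "non_exonic")
CLINVAR_CLASSES <- c("Pathogenic", "Likely_pathogenic", "Benign",
                     "Likely_benign", "VUS", "Conflicting")

MANDATORY_VARIANT_FIELDS <- c("chrom", "pos", "ref", "alt", "vaf")

validate_variants <- function(variants) {
  missing <- setdiff(MANDATORY_VARIANT_FIELDS, names(variants))
  if (length(missing) > 0)
    stop_input("variant table is missing mandatory field(s): ",
               paste(missing, collapse = ", "))
  bad <- which(is.na(variants$vaf) | variants$vaf < 0 | variants$vaf > 1)
  if (length(bad) > 0)
    stop_input("VAF missing or outside [0,1] for record(s): ",
               paste(head(bad, 5), collapse = ", "))
  if (!is.null(variants$alt_reads) && !is.null(variants$depth)) {
    bad <- which(!is.na(variants$alt_reads) & !is.na(variants$depth) &
                   variants$alt_reads > variants$depth)
    if (length(bad) > 0)
      stop_input("alt_reads exceeds depth for record(s): ",
                 paste(head(bad, 5), collapse = ", "))
  }
  invisible(variants)
}

# Apply an ordered cascade of removal rules. `rules` is a named list of
# functions mapping the variant data.frame to a logical "remove" vector.
apply_cascade <- function(variants, rules) {
  n <- nrow(variants)
  removed_by <- rep(NA_character_, n)
  for (rule in names(rules)) {
    fails <- rules[[rule]](variants)
    fails[is.na(fails)] <- FALSE
    removed_by[is.na(removed_by) & fails] <- rule
  }
  audit <- structure(
    list(input_count = n,
         kept_count = sum(is.na(removed_by)),
         removed_by_rule = vapply(names(rules), function(r)
           sum(removed_by == r, na.rm = TRUE), integer(1))),
    class = "filter_audit")
  list(kept = variants[is.na(removed_by), , drop = FALSE], audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filtration audit:", x$input_count, "in,", x$kept_count, "kept\n")
  rem <- x$removed_by_rule[x$removed_by_rule > 0]
  for (r in names(rem)) cat("  removed by ", r, ": ", rem[[r]], "\n", sep = "")
  invisible(x)
}

somatic_rules <- function(maf_cutoff, min_alt_reads, min_vaf) {
  list(
    caller_fail = function(v) !v$caller_pass,
    segdup = function(v) v$in_segdup,
    common_polymorphism = function(v) !is.na(v$popmax_af) & v$popmax_af > maf_cutoff,
    off_target = function(v) !v$on_target,
    synonymous = function(v) v$consequence == "synonymous",
    low_read_support = function(v) v$alt_reads < min_alt_reads,
    low_vaf = function(v) v$vaf < min_vaf
  )
}

#' Somatic small-variant filtration
#'
#' Removes, in order: calls failing the upstream caller's quality filter,
#' calls in segmental-duplication regions, common polymorphisms (population
#' maximum allele frequency strictly above `maf_cutoff`; absent frequency
#' passes, i.e. never-observed means rare), off-target calls, synonymous
#' SNVs, calls supported by fewer than `min_alt_reads` alternate reads, and
#' calls with VAF below `min_vaf`. The read-support and VAF thresholds are
#' two independent requirements: failing either one removes the call.
#'
#' @param variants data.frame of annotated variant calls; mandatory columns
#'   `chrom`, `pos`, `ref`, `alt`, `vaf`, plus the annotation columns the
#'   rules read (`caller_pass`, `in_segdup`, `popmax_af`, `on_target`,
#'   `consequence`, `alt_reads`). Region flags can be derived from BEDs
#'   with [annotate_regions()] (pass `targets` / `segdups`).
#' @param maf_cutoff population-frequency cutoff; strictly greater is
#'   removed (exactly at the cutoff is kept). Default 0.01.
#' @param min_alt_reads minimum alternate-read support (inclusive). Default 8.
#' @param min_vaf minimum variant allele frequency (inclusive). Default 0.05.
#' @param targets,segdups optional BED data.frames used to derive missing
#'   `on_target` / `in_segdup` columns.
#' @return list with `kept` (the surviving rows) and `audit`
#'   (a `filter_audit`: input count, kept count, removals attributed to the
#'   first failing rule; counts always reconcile).
#' @export
filter_somatic <- function(variants, maf_cutoff = 0.01, min_alt_reads = 8,
                           min_vaf = 0.05, targets = NULL, segdups = NULL) {
  validate_variants(variants)
  variants <- annotate_regions(variants, targets, segdups)
  apply_cascade(variants, somatic_rules(maf_cutoff, min_alt_reads, min_vaf))
}

#' Pathogenicity prioritization of filtered somatic variants
#'
#' A variant is retained when its CADD phred score is strictly greater than
#' `cadd_cutoff` or its CancerVar score is strictly greater than
#' `cancervar_cutoff`. A score that is absent fails its clause (so a variant
#' with both scores missing is dropped).
#'
#' @param variants output of [filter_somatic()]`$kept` (or any variant
#'   data.frame with `cadd_phred` / `cancervar_score` columns).
#' @param cadd_cutoff,cancervar_cutoff strict lower bounds (defaults 20 and
#'   0.80).
#' @return the retained subset.
#' @export
prioritize_pathogenic <- function(variants, cadd_cutoff = 20,
                                  cancervar_cutoff = 0.80) {
  keep <- (!is.na(variants$cadd_phred) & variants$cadd_phred > cadd_cutoff) |
    (!is.na(variants$cancervar_score) & variants$cancervar_score > cancervar_cutoff)
  variants[keep, , drop = FALSE]
}

#' Tumor-only filtration (no matched normal)
#'
#' Applies the full somatic cascade of [filter_somatic()], then the
#' tumor-only rarity rule: a variant is removed when its population maximum
#' allele frequency exceeds `popmax_cutoff` *and* it is not in COSMIC
#' (COSMIC membership rescues a moderately frequent variant). Set
#' `cosmic_rescue = FALSE` for the strict reading in which the two
#' conditions remove independently (frequency above the cutoff removes
#' regardless of COSMIC, and absence from COSMIC removes regardless of
#' frequency).
#'
#' @inheritParams filter_somatic
#' @param popmax_cutoff tumor-only rarity cutoff (default 0.001).
#' @param cosmic_rescue logical; see Description.
#' @return list with `kept` and `audit` as in [filter_somatic()]; the extra
#'   rule is audited as `popmax_cosmic`.
#' @export
filter_tumor_only <- function(variants, popmax_cutoff = 0.001,
                              cosmic_rescue = TRUE,
                              maf_cutoff = 0.01, min_alt_reads = 8,
                              min_vaf = 0.05, targets = NULL, segdups = NULL) {
  validate_variants(variants)
  variants <- annotate_regions(variants, targets, segdups)
  rules <- somatic_rules(maf_cutoff, min_alt_reads, min_vaf)
  rules$popmax_cosmic <- if (cosmic_rescue) {
    function(v) !is.na(v$popmax_af) & v$popmax_af > popmax_cutoff & !v$in_cosmic
  } else {
    function(v) (!is.na(v$popmax_af) & v$popmax_af > popmax_cutoff) | !v$in_cosmic
  }
  apply_cascade(variants, rules)
}

#' Germline variant filtration
#'
#' After the shared pre-filters (caller pass, segmental duplications,
#' common-polymorphism cutoff, on-target), germline variants are restricted
#' to a list of cancer-predisposition genes and to calls annotated
#' Pathogenic or Likely_pathogenic in ClinVar or InterVar; calls annotated
#' with conflicting interpretations in ClinVar are excluded even when
#' InterVar calls them pathogenic.
#'
#' @inheritParams filter_somatic
#' @param predisposition_genes non-empty character vector of gene symbols.
#' @return list with `kept` and `audit`.
#' @export
filter_germline <- function(variants, predisposition_genes,
                            maf_cutoff = 0.01, targets = NULL, segdups = NULL) {
  if (length(predisposition_genes) == 0)
    stop_config("predisposition gene list must be non-empty")
  validate_variants(variants)
  variants <- annotate_regions(variants, targets, segdups)
  plp <- c("Pathogenic", "Likely_pathogenic")
  rules <- list(
    caller_fail = function(v) !v$caller_pass,
    segdup = function(v) v$in_segdup,
    common_polymorphism = function(v) !is.na(v$popmax_af) & v$popmax_af > maf_cutoff,
    off_target = function(v) !v$on_target,
    not_predisposition_gene = function(v) !(v$gene %in% predisposition_genes),
    conflicting_clinvar = function(v) v$clinvar_class %in% "Conflicting",
    not_pathogenic = function(v) !(v$clinvar_class %in% plp | v$intervar_class %in% plp)
  )
  apply_cascade(variants, rules)
}
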