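# End-to-end orchestration: filtration -> CNV selection -> burden ->
# expression outliers -> actionability -> xenograft fidelity, with every
# threshold collected in one validated configuration object.

#' Pipeline configuration
#'
#' All thresholds of the analysis stages with their defaults: population
#' allele-frequency cutoff 0.01, minimum alternate reads 8, minimum VAF
#' 0.05, CADD 20, CancerVar 0.80, amplification cutoff 10, TMB cutoff 5
#' mutations/Mb (VAF gate 0.05), MSI cutoff 10, Z-score cutoff 3, low-count
#' threshold 20 reads, tumor-only popmax cutoff 0.001, and the panel /
#' exome target lengths (3,040,053 / 38,289,292 bp).
#'
#' @param maf_cutoff,min_alt_reads,min_vaf somatic filtration thresholds.
#' @param cadd_cutoff,cancervar_cutoff pathogenicity prioritization cutoffs.
#' @param popmax_cutoff_tumor_only,cosmic_rescue tumor-only rule settings.
#' @param amp_cutoff CNV amplification threshold.
#' @param tmb_cutoff,tmb_min_vaf,tmb_comparison TMB actionability settings.
#' @param msi_cutoff MSI-high threshold.
#' @param z_cutoff,min_reads,pseudocount,orientation expression settings.
#' @param panel_length_bp,exome_length_bp TMB target lengths.
#' @param seed seed used by any stochastic step.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_cutoff = 0.01, min_alt_reads = 8,
                            min_vaf = 0.05, cadd_cutoff = 20,
                            cancervar_cutoff = 0.80,
                            popmax_cutoff_tumor_only = 0.001,
                            cosmic_rescue = TRUE, amp_cutoff = 10,
                            tmb_cutoff = 5, tmb_min_vaf = 0.05,
                            tmb_comparison = ">=", msi_cutoff = 10,
                            z_cutoff = 3, min_reads = 20, pseudocount = 1,
                            orientation = "per_sample",
                            panel_length_bp = 3040053L,
                            exome_length_bp = 38289292L, seed = 1L) {
  config <- list(maf_cutoff = maf_cutoff, min_alt_reads = min_alt_reads,
                 min_vaf = min_vaf, cadd_cutoff = cadd_cutoff,
                 cancervar_cutoff = cancervar_cutoff,
                 popmax_cutoff_tumor_only = popmax_cutoff_tumor_only,
                 cosmic_rescue = cosmic_rescue, amp_cutoff = amp_cutoff,
                 tmb_cutoff = tmb_cutoff, tmb_min_vaf = tmb_min_vaf,
                 tmb_comparison = tmb_comparison, msi_cutoff = msi_cutoff,
                 z_cutoff = z_cutoff, min_reads = min_reads,
                 pseudocount = pseudocount, orientation = orientation,
                 panel_length_bp = as.integer(panel_length_bp),
                 exome_length_bp = as.integer(exome_length_bp),
                 seed = as.integer(seed))
  for (f in c("maf_cutoff", "min_vaf", "popmax_cutoff_tumor_only"))
    if (config[[f]] < 0 || config[[f]] > 1)
      stop_config("field '", f, "' must be in [0, 1]")
  for (f in c("min_alt_reads", "cadd_cutoff", "cancervar_cutoff",
              "amp_cutoff", "tmb_cutoff", "msi_cutoff", "z_cutoff",
              "min_reads", "panel_length_bp", "exome_length_bp"))
    if (!is.numeric(config[[f]]) || config[[f]] < 0)
      stop_config("field '", f, "' must be non-negative")
  if (!config$tmb_comparison %in% c(">=", ">"))
    stop_config("field 'tmb_comparison' must be '>=' or '>'")
  if (!config$orientation %in% c("per_sample", "per_gene"))
    stop_config("field 'orientation' must be 'per_sample' or 'per_gene'")
  structure(config, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected; serialize -> parse -> serialize
#' is idempotent.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0)
    stop_config("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

rare_missense_keys <- function(variants, maf_cutoff = 0.01) {
  keep <- variants$consequence == "missense" &
    (is.na(variants$popmax_af) | variants$popmax_af <= maf_cutoff)
  unique(variant_key(variants[keep, , drop = FALSE]))
}

#' Run the full downstream analysis on a cohort
#'
#' Fixed stage order: somatic filtration and pathogenicity prioritization
#' per originating tumor; actionable-CNV selection; TMB (exome length) and
#' hypermutation flags; MSI-high calls; expression low-count filtering,
#' CPM/log2 normalization and over-expression outlier detection; germline
#' predisposition screening; actionability grading and cohort summary; and
#' the xenograft-fidelity suite (VAF-matrix correlation / Ward clustering /
#' PCA over all stages, conserved rare+missense fractions for PZ->P1,
#' PZ->P2, P1->P2_3D and P2->P2_3D, pooled Mann-Whitney VAF-shift tests,
#' and per-event trajectories of the originating tumor's actionable
#' lesions).
#'
#' @param cohort a `synthetic_cohort` (or an equivalently shaped list read
#'   from disk).
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `somatic` (kept + audits per sample),
#'   `prioritized`, `cnv_selected`, `tmb`, `msi`, `expression`
#'   (normalized layers + calls), `germline`, `events`, `summary`,
#'   `fidelity`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  kb <- cohort$knowledge_base
  samples <- cohort$samples
  pz <- samples[samples$stage == "PZ", , drop = FALSE]
  patient_of <- function(sid) samples$patient_id[match(sid, samples$sample_id)]

  # --- somatic filtration + prioritization (originating tumors) ----------
  audits <- list()
  kept <- list()
  for (sid in pz$sample_id) {
    v <- cohort$variants[cohort$variants$sample_id == sid, , drop = FALSE]
    res <- filter_somatic(v, config$maf_cutoff, config$min_alt_reads,
                          config$min_vaf)
    audits[[sid]] <- res$audit
    kept[[sid]] <- res$kept
  }
  somatic_kept <- do.call(rbind, kept)
  rownames(somatic_kept) <- NULL
  prioritized <- prioritize_pathogenic(somatic_kept, config$cadd_cutoff,
                                       config$cancervar_cutoff)
  prioritized <- infer_effect(prioritized)

  # --- CNVs ---------------------------------------------------------------
  pz_cnvs <- cohort$cnvs[cohort$cnvs$sample_id %in% pz$sample_id, , drop = FALSE]
  cnv_selected <- select_actionable_cnvs(pz_cnvs, kb, config$amp_cutoff)
  if (nrow(cnv_selected) > 0)
    cnv_selected$patient_id <- patient_of(cnv_selected$sample_id)

  # --- burden metrics -----------------------------------------------------
  tmb <- do.call(rbind, lapply(pz$sample_id, function(sid) {
    r <- compute_tmb(kept[[sid]], config$exome_length_bp, config$tmb_min_vaf,
                     config$tmb_cutoff, config$tmb_comparison, sample_id = sid)
    data.frame(sample_id = sid, patient_id = patient_of(sid),
               missense_count = r$missense_count, tmb = r$tmb,
               actionable = r$actionable, stringsAsFactors = FALSE)
  }))
  hypermutated <- tmb[tmb$actionable, , drop = FALSE]

  msi <- cohort$msi[cohort$msi$sample_id %in% pz$sample_id, , drop = FALSE]
  msi$msi_high <- call_msi_high(msi$msi_score, config$msi_cutoff)
  msi$patient_id <- patient_of(msi$sample_id)
  msi_high <- msi[msi$msi_high, , drop = FALSE]

  # --- expression ---------------------------------------------------------
  counts <- filter_low_counts(cohort$expression, config$min_reads)
  layers <- cpm_log2(counts, config$pseudocount)
  calls <- detect_outliers(layers$log2_cpm, config$z_cutoff,
                           config$orientation)
  pz_calls <- calls[calls$sample %in% pz$sample_id, , drop = FALSE]
  pz_calls$patient_id <- patient_of(pz_calls$sample)
  actionable_calls <- pz_calls[pz_calls$gene %in% kb$genes$symbol, ,
                               drop = FALSE]

  # --- germline -----------------------------------------------------------
  predisposition <- kb$genes$symbol[kb$genes$predisposition]
  germ <- filter_germline(cohort$germline, predisposition, config$maf_cutoff)
  carriers <- unique(germ$kept$patient_id)
  germline <- list(kept = germ$kept, audit = germ$audit,
                   carriers = carriers,
                   n_patients = length(unique(samples$patient_id)),
                   carrier_rate_pct = percent_truncate1(
                     length(carriers), length(unique(samples$patient_id))))

  # --- actionability ------------------------------------------------------
  candidates <- assemble_candidates(snvs = prioritized, cnvs = cnv_selected,
                                    outliers = actionable_calls,
                                    hypermutated = hypermutated,
                                    msi_high = msi_high)
  events <- classify_events(candidates, kb)
  summary <- summarize_cohort(events, pz$sample_id)

  # --- fidelity -----------------------------------------------------------
  vaf_matrix <- build_vaf_matrix(cohort$variants)
  similarity <- similarity_suite(vaf_matrix, "pearson")

  stage_keys <- function(pid, stage) {
    sid <- samples$sample_id[samples$patient_id == pid & samples$stage == stage]
    rare_missense_keys(
      cohort$variants[cohort$variants$sample_id == sid, , drop = FALSE],
      config$maf_cutoff)
  }
  pairs <- rbind(c("PZ", "P1"), c("PZ", "P2"), c("P1", "P2_3D"),
                 c("P2", "P2_3D"))
  conserved <- do.call(rbind, lapply(unique(samples$patient_id), function(pid) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      cf <- conserved_fraction(stage_keys(pid, pairs[k, 1]),
                               stage_keys(pid, pairs[k, 2]))
      data.frame(patient_id = pid, origin_stage = pairs[k, 1],
                 target_stage = pairs[k, 2], shared = cf$shared,
                 n_origin = cf$n_origin, fraction = cf$fraction,
                 stringsAsFactors = FALSE)
    }))
  }))

  stage_vafs <- function(stage) {
    sids <- samples$sample_id[samples$stage == stage]
    cohort$variants$vaf[cohort$variants$sample_id %in% sids]
  }
  shift_pairs <- rbind(c("PZ", "P1"), c("P1", "P2"), c("P2", "P2_3D"))
  vaf_shifts <- lapply(seq_len(nrow(shift_pairs)), function(k)
    vaf_shift_test(stage_vafs(shift_pairs[k, 1]),
                   stage_vafs(shift_pairs[k, 2])))
  names(vaf_shifts) <- apply(shift_pairs, 1, paste, collapse = "_vs_")

  all_calls <- calls
  all_calls$patient_id <- patient_of(all_calls$sample)
  tracking <- track_actionable(events, samples, cohort$variants,
                               cohort$cnvs, all_calls)

  structure(list(
    somatic = list(kept = somatic_kept, audits = audits),
    prioritized = prioritized,
    cnv_selected = cnv_selected,
    tmb = tmb, msi = msi,
    expression = list(counts = counts, cpm = layers$cpm,
                      log2_cpm = layers$log2_cpm, calls = calls,
                      pz_actionable_calls = actionable_calls),
    germline = germline,
    events = events,
    summary = summary,
    fidelity = list(vaf_matrix = vaf_matrix, similarity = similarity,
                    conserved = conserved, vaf_shifts = vaf_shifts,
                    tracking = tracking),
    config = config), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Precision-medicine pipeline result\n")
  print(x$summary)
  cat(sprintf("  germline carriers: %d/%d patients (%.1f%%)\n",
              length(x$germline$carriers), x$germline$n_patients,
              x$germline$carrier_rate_pct))
  cons <- x$fidelity$conserved
  p1 <- cons$fraction[cons$origin_stage == "PZ" & cons$target_stage == "P1"]
  cat(sprintf("  mean conserved fraction PZ->P1: %.3f\n",
              mean(p1, na.rm = TRUE)))
  invisible(x)
}
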