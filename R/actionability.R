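# Two-tier actionability grading with drug-mechanism concordance.
#
# Candidates from every detection channel (pathogenic SNV/INDELs, selected
# CNVs, expression outliers, hypermutation, MSI-high) are matched to
# knowledge-base drug records; records whose mechanism cannot act on the
# lesion (an inhibitor aimed at a lost tumor-suppressor function) are
# pruned, and the surviving evidence sets the grade:
# VERY_HIGH = validated direct target, HIGH = pathway-level prediction.

EVENT_CLASSES <- c("SNV_INDEL", "CNV", "OVEREXPRESSION", "HYPERMUTATION",
                   "MSI_HIGH")

#' Infer functional effect of small variants
#'
#' Frameshift and stopgain default to loss of function; missense flagged as
#' a hotspot defaults to gain of function; anything else is `unknown`. An
#' existing non-missing `effect` column is respected.
#'
#' @param variants variant data.frame; optional logical `hotspot` column.
#' @return the data.frame with an `effect` column (LOF / GOF / unknown).
#' @export
infer_effect <- function(variants) {
  eff <- variants$effect %||% rep(NA_character_, nrow(variants))
  hotspot <- variants$hotspot %||% rep(FALSE, nrow(variants))
  fill <- ifelse(variants$consequence %in% c("frameshift", "stopgain"), "LOF",
                 ifelse(variants$consequence == "missense" & hotspot,
                        "GOF", "unknown"))
  variants$effect <- ifelse(is.na(eff), fill, eff)
  variants
}

#' Assemble actionability candidates from the detection channels
#'
#' @param snvs prioritized pathogenic somatic variants (with `sample_id`,
#'   `patient_id`, `gene`, `effect` -- see [infer_effect()] -- and
#'   coordinates), or NULL.
#' @param cnvs output of [select_actionable_cnvs()] with `patient_id`, or
#'   NULL. Deletions act as LOF lesions, amplifications as GOF.
#' @param outliers over-expression calls (`gene`, `sample` columns as from
#'   [detect_outliers()]) with `patient_id`, or NULL; treated as GOF.
#' @param hypermutated,msi_high data.frames with `sample_id`, `patient_id`
#'   for samples flagged by the burden metrics, or NULL.
#' @return candidate data.frame ready for [classify_events()].
#' @export
assemble_candidates <- function(snvs = NULL, cnvs = NULL, outliers = NULL,
                                hypermutated = NULL, msi_high = NULL) {
  cand <- function(patient_id, sample_id, event_class, gene, effect,
                   chrom = NA_character_, pos = NA_integer_,
                   ref = NA_character_, alt = NA_character_,
                   detail = NA_real_) {
    data.frame(patient_id = patient_id, sample_id = sample_id,
               event_class = event_class, gene = gene, effect = effect,
               chrom = chrom, pos = pos, ref = ref, alt = alt,
               detail = detail, stringsAsFactors = FALSE)
  }
  out <- list()
  if (!is.null(snvs) && nrow(snvs) > 0)
    out$snv <- cand(snvs$patient_id, snvs$sample_id, "SNV_INDEL", snvs$gene,
                    snvs$effect, snvs$chrom, snvs$pos, snvs$ref, snvs$alt,
                    snvs$vaf)
  if (!is.null(cnvs) && nrow(cnvs) > 0)
    out$cnv <- cand(cnvs$patient_id, cnvs$sample_id, "CNV", cnvs$gene,
                    ifelse(cnvs$kind == "deletion", "LOF", "GOF"),
                    detail = cnvs$copy_number)
  if (!is.null(outliers) && nrow(outliers) > 0)
    out$expr <- cand(outliers$patient_id, outliers$sample, "OVEREXPRESSION",
                     outliers$gene, "GOF", detail = outliers$zscore)
  if (!is.null(hypermutated) && nrow(hypermutated) > 0)
    out$tmb <- cand(hypermutated$patient_id, hypermutated$sample_id,
                    "HYPERMUTATION", NA_character_, "unknown",
                    detail = hypermutated$tmb %||% NA_real_)
  if (!is.null(msi_high) && nrow(msi_high) > 0)
    out$msi <- cand(msi_high$patient_id, msi_high$sample_id, "MSI_HIGH",
                    NA_character_, "unknown",
                    detail = msi_high$msi_score %||% NA_real_)
  if (length(out) == 0)
    return(empty_events()[, c("patient_id", "sample_id", "event_class",
                              "gene", "effect", "chrom", "pos", "ref",
                              "alt", "detail"), drop = FALSE])
  do.call(rbind, unname(out))
}

# Mechanism concordance: an inhibitor or antagonist cannot target a lost
# function, so such records are dropped for LOF lesions in pure tumor
# suppressors. Everything else is mechanism-compatible.
mechanism_concordant <- function(mechanism, effect, role) {
  !(mechanism %in% c("inhibitor", "antagonist") &
      effect == "LOF" & role == "tumor_suppressor")
}

#' Grade actionability candidates into events
#'
#' For each candidate the knowledge-base drug records of its gene are
#' pruned by mechanism concordance (see Details); a candidate with no
#' surviving record is dropped, as is a candidate whose gene is absent from
#' the knowledge base (with a notice). Grade is `VERY_HIGH` when at least
#' one surviving record is a validated direct target and the lesion's
#' functional effect is known (a mechanism-unknown lesion is never graded
#' VERY_HIGH); otherwise `HIGH`. Hypermutation and MSI-high events carry
#' the knowledge base's immune-checkpoint records and grade VERY_HIGH.
#'
#' @param candidates data.frame from [assemble_candidates()].
#' @param kb a [knowledge_base()].
#' @param checkpoint_genes knowledge-base genes whose drug records back
#'   hypermutation / MSI-high events (default PD-1 / PD-L1).
#' @return data.frame of events: candidate columns plus `pathway`,
#'   `priority` (VERY_HIGH / HIGH), `n_drugs`, `drugs` (collapsed label).
#' @export
classify_events <- function(candidates, kb,
                            checkpoint_genes = c("PDCD1", "CD274")) {
  if (nrow(candidates) == 0) return(empty_events())
  if (!all(candidates$event_class %in% EVENT_CLASSES))
    stop_input("unknown event class(es)")
  rows <- vector("list", nrow(candidates))
  n_unresolved <- 0L
  for (i in seq_len(nrow(candidates))) {
    cl <- candidates$event_class[i]
    burden_class <- cl %in% c("HYPERMUTATION", "MSI_HIGH")
    gene <- candidates$gene[i]
    effect <- candidates$effect[i]
    if (burden_class) {
      recs <- kb$drugs[kb$drugs$gene %in% checkpoint_genes, , drop = FALSE]
      pathway <- "immune checkpoint"
      priority <- "VERY_HIGH"
    } else {
      role <- kb_role(kb, gene)
      if (is.na(role)) {
        n_unresolved <- n_unresolved + 1L
        next
      }
      recs <- kb$drugs[kb$drugs$gene == gene, , drop = FALSE]
      recs <- recs[mechanism_concordant(recs$mechanism, effect, role), ,
                   drop = FALSE]
      if (nrow(recs) == 0) next
      pathway <- kb_pathway(kb, gene)
      validated <- any(recs$evidence == "validated_direct")
      priority <- if (validated && effect != "unknown") "VERY_HIGH" else "HIGH"
    }
    rows[[i]] <- cbind(candidates[i, , drop = FALSE],
                       data.frame(pathway = pathway, priority = priority,
                                  n_drugs = nrow(recs),
                                  drugs = paste(recs$drug, collapse = "; "),
                                  stringsAsFactors = FALSE))
  }
  if (n_unresolved > 0)
    message(n_unresolved, " candidate(s) with gene absent from knowledge base; dropped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_events())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

empty_events <- function() {
  data.frame(patient_id = character(0), sample_id = character(0),
             event_class = character(0), gene = character(0),
             effect = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), detail = numeric(0),
             pathway = character(0), priority = character(0),
             n_drugs = integer(0), drugs = character(0),
             stringsAsFactors = FALSE)
}

#' Cohort-level actionability summary
#'
#' Builds the gene-by-sample event matrix (cells encode
#' "event class/priority") and the cohort tallies: per-class event counts
#' with integer percentages apportioned by largest remainder so they sum to
#' 100, per-priority counts, and the fractions of samples carrying at least
#' one event (overall and very-high-priority), rounded half-up to integer
#' percent.
#'
#' @param events data.frame from [classify_events()].
#' @param samples character vector of all sample ids in the cohort
#'   (including samples without events), or a data.frame with a
#'   `sample_id` column.
#' @return a `cohort_summary`: list with `matrix`, `class_tally`,
#'   `priority_tally`, `n_samples`, `n_events`,
#'   `pct_samples_actionable`, `pct_samples_very_high`.
#' @export
summarize_cohort <- function(events, samples) {
  if (is.data.frame(samples)) samples <- samples$sample_id
  samples <- unique(samples)
  n_samples <- length(samples)

  feature <- ifelse(is.na(events$gene), events$event_class, events$gene)
  feats <- unique(feature)
  mat <- matrix("", nrow = length(feats), ncol = n_samples,
                dimnames = list(feats, samples))
  for (i in seq_len(nrow(events))) {
    code <- paste0(events$event_class[i], "/", events$priority[i])
    cur <- mat[feature[i], events$sample_id[i]]
    mat[feature[i], events$sample_id[i]] <-
      if (nzchar(cur)) paste(cur, code, sep = "; ") else code
  }

  class_counts <- vapply(EVENT_CLASSES, function(cl)
    sum(events$event_class == cl), integer(1))
  class_counts <- class_counts[class_counts > 0]
  class_tally <- data.frame(event_class = names(class_counts),
                            n = as.integer(class_counts),
                            pct = percent_largest_remainder(class_counts),
                            row.names = NULL, stringsAsFactors = FALSE)

  prio_counts <- c(VERY_HIGH = sum(events$priority == "VERY_HIGH"),
                   HIGH = sum(events$priority == "HIGH"))
  priority_tally <- data.frame(priority = names(prio_counts),
                               n = as.integer(prio_counts),
                               row.names = NULL, stringsAsFactors = FALSE)

  with_event <- samples %in% events$sample_id
  with_vh <- samples %in% events$sample_id[events$priority == "VERY_HIGH"]
  structure(list(
    matrix = mat,
    class_tally = class_tally,
    priority_tally = priority_tally,
    n_samples = n_samples,
    n_events = nrow(events),
    n_samples_actionable = sum(with_event),
    n_samples_very_high = sum(with_vh),
    pct_samples_actionable = percent_half_up(sum(with_event), n_samples),
    pct_samples_very_high = percent_half_up(sum(with_vh), n_samples)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort actionability summary\n")
  cat(sprintf("  %d events in %d/%d samples (%d%% actionable, %d%% with very-high-priority events)\n",
              x$n_events, x$n_samples_actionable, x$n_samples,
              x$pct_samples_actionable, x$pct_samples_very_high))
  if (nrow(x$class_tally) > 0) {
    for (i in seq_len(nrow(x$class_tally)))
      cat(sprintf("  %-15s n = %2d (%d%%)\n", x$class_tally$event_class[i],
                  x$class_tally$n[i], x$class_tally$pct[i]))
  }
  invisible(x)
}
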