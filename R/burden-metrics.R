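# Tumor mutational burden and microsatellite-instability threshold calls.

#' Tumor mutational burden
#'
#' TMB is the count of missense variants at or above a VAF gate, divided by
#' the targeted (non-overlapping) region length in megabases. The default
#' target lengths used in this package are 3,040,053 bp for the cancer gene
#' panel and 38,289,292 bp for the whole exome; a burden of at least
#' `actionable_cutoff` mutations/Mb is flagged actionable
#' (immune-checkpoint trial eligibility).
#'
#' @param variants variant data.frame with `consequence` and `vaf` columns
#'   (normally an already-filtered somatic set).
#' @param target_length_bp length of the targeted regions in base pairs
#'   (> 0). See [pipeline_config()] for the packaged panel/exome defaults.
#' @param min_vaf VAF gate, inclusive (default 0.05).
#' @param actionable_cutoff burden threshold in mutations/Mb (default 5).
#' @param comparison `">="` (default) flags burden at or above the cutoff;
#'   `">"` requires strictly more than the cutoff (the two readings differ
#'   only exactly at the cutoff).
#' @param sample_id optional label carried into the result.
#' @return a `tmb_result`: list with `sample_id`, `missense_count`,
#'   `target_length_bp`, `tmb` (mutations/Mb) and `actionable`.
#' @export
compute_tmb <- function(variants, target_length_bp, min_vaf = 0.05,
                        actionable_cutoff = 5, comparison = c(">=", ">"),
                        sample_id = NA_character_) {
  comparison <- match.arg(comparison)
  if (!is.numeric(target_length_bp) || length(target_length_bp) != 1 ||
      is.na(target_length_bp) || target_length_bp <= 0)
    stop_config("target_length_bp must be a single positive number")
  qualifying <- variants$consequence == "missense" & variants$vaf >= min_vaf
  n <- sum(qualifying, na.rm = TRUE)
  tmb <- n / (target_length_bp / 1e6)
  actionable <- if (comparison == ">=") tmb >= actionable_cutoff else tmb > actionable_cutoff
  structure(list(sample_id = sample_id, missense_count = n,
                 target_length_bp = target_length_bp, tmb = tmb,
                 actionable = actionable),
            class = "tmb_result")
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB: %.3f mutations/Mb (%d missense / %.3f Mb)%s\n",
              x$tmb, x$missense_count, x$target_length_bp / 1e6,
              if (x$actionable) " [actionable]" else ""))
  invisible(x)
}

#' MSI-high call from a precomputed instability score
#'
#' The microsatellite-instability score itself is an upstream input; this
#' is the threshold call only: a score of `cutoff` or higher is MSI-high
#' (potentially targetable with immune checkpoint inhibitors).
#'
#' @param msi_score numeric vector of non-negative, finite scores.
#' @param cutoff inclusive threshold (default 10).
#' @return logical vector.
#' @export
call_msi_high <- function(msi_score, cutoff = 10) {
  if (any(!is.finite(msi_score)) || any(msi_score < 0))
    stop_input("MSI scores must be finite and non-negative")
  msi_score >= cutoff
}
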