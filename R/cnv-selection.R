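# Actionable copy-number selection: biallelic deletions of tumor
# suppressors and focal amplifications of oncogenes, minus ACMG-benign
# calls and calls that failed manual IGV review.

#' Select actionable copy-number variants
#'
#' A (segment, gene) pair is selected when the segment has copy number 0 and
#' the gene's role includes tumor suppressor (biallelic deletion), or copy
#' number at least `amp_cutoff` and the gene's role includes oncogene
#' (focal amplification). Genes with role `both` qualify under either
#' branch and are flagged in the output. Segments classified benign or
#' likely benign under ACMG, or that failed IGV review, are excluded.
#' Segments overlapping no gene annotated in the knowledge base are skipped
#' with a notice (not an error); duplicate gene listings on a segment are
#' deduplicated.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `copy_number`, `genes` (comma-separated overlapped
#'   symbols), `acmg_class` (benign / likely_benign / VUS /
#'   likely_pathogenic / pathogenic / NA) and optionally `igv_flag`
#'   (passed / failed / not_reviewed) and `sample_id`.
#' @param kb a [knowledge_base()] resolving gene roles; genes with unknown
#'   role are never selected.
#' @param amp_cutoff amplification threshold, inclusive (default 10).
#' @param not_reviewed_passes treat `igv_flag = "not_reviewed"` as passed
#'   (default TRUE): manual review cannot be automated, so its absence is
#'   not held against a call unless requested.
#' @param max_amp_length optional guard: amplified segments longer than this
#'   many bases are not considered focal (default `NULL`, off).
#' @return data.frame with one row per selected (segment, gene) pair:
#'   segment coordinates, `sample_id` (if given), `gene`, `role`,
#'   `copy_number`, `kind` (deletion / amplification).
#' @export
select_actionable_cnvs <- function(segments, kb, amp_cutoff = 10,
                                   not_reviewed_passes = TRUE,
                                   max_amp_length = NULL) {
  if (nrow(segments) == 0) return(empty_cnv_selection())
  if (any(segments$start >= segments$end))
    stop_input("CNV segments must have start < end")
  if (any(segments$copy_number < 0))
    stop_input("copy numbers must be non-negative")

  igv <- segments$igv_flag %||% rep("not_reviewed", nrow(segments))
  igv_ok <- igv == "passed" | (not_reviewed_passes & igv == "not_reviewed")
  acmg_ok <- !(segments$acmg_class %in% c("benign", "likely_benign"))

  out <- vector("list", nrow(segments))
  n_unannotated <- 0L
  for (i in seq_len(nrow(segments))) {
    genes <- unique(strsplit(segments$genes[i] %||% "", ",")[[1]])
    genes <- trimws(genes[nzchar(genes)])
    roles <- kb_role(kb, genes)
    known <- !is.na(roles)
    if (!any(known)) {
      n_unannotated <- n_unannotated + 1L
      next
    }
    genes <- genes[known]; roles <- roles[known]
    cn <- segments$copy_number[i]
    is_del <- cn == 0 & roles %in% c("tumor_suppressor", "both")
    seg_len <- segments$end[i] - segments$start[i]
    focal <- is.null(max_amp_length) || seg_len <= max_amp_length
    is_amp <- cn >= amp_cutoff & focal & roles %in% c("oncogene", "both")
    hit <- (is_del | is_amp) & acmg_ok[i] & igv_ok[i]
    if (!any(hit)) next
    out[[i]] <- data.frame(
      sample_id = (segments$sample_id %||% rep(NA_character_, nrow(segments)))[i],
      chrom = segments$chrom[i], start = segments$start[i],
      end = segments$end[i], gene = genes[hit], role = roles[hit],
      copy_number = cn,
      kind = ifelse(is_del[hit], "deletion", "amplification"),
      stringsAsFactors = FALSE)
  }
  if (n_unannotated > 0)
    message(n_unannotated, " segment(s) overlapped no knowledge-base gene; skipped")
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_cnv_selection())
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("sample_id", "chrom", "start", "end", "gene")]), ,
      drop = FALSE]
}

empty_cnv_selection <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), gene = character(0),
             role = character(0), copy_number = numeric(0),
             kind = character(0), stringsAsFactors = FALSE)
}
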