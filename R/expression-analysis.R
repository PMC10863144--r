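# Expression normalization and over-expression outlier detection:
# low-count filter -> CPM -> log2 -> Z-score calls, plus a hypergeometric
# test for outlier-set preservation across tumor generations.

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0 || ncol(counts) == 0)
    stop_input("count matrix must be a non-empty matrix (genes x samples)")
  if (any(counts < 0)) stop_input("counts must be non-negative")
  invisible(counts)
}

#' Filter low-count genes
#'
#' The default rule (`"all_below"`) removes a gene only when its count
#' fails to reach `min_reads` in every sample, i.e. the gene's maximum
#' across samples is below the threshold; a single sample at or above the
#' threshold retains the gene. The alternative `"any_below"` removes a gene
#' as soon as any sample falls below the threshold (a far more aggressive
#' reading, kept for sensitivity analyses).
#'
#' @param counts integer matrix, genes as rows, samples as columns.
#' @param min_reads threshold (default 20).
#' @param rule `"all_below"` (default) or `"any_below"`; see Description.
#' @return the retained sub-matrix.
#' @export
filter_low_counts <- function(counts, min_reads = 20,
                              rule = c("all_below", "any_below")) {
  check_count_matrix(counts)
  rule <- match.arg(rule)
  keep <- if (rule == "all_below") {
    apply(counts, 1, max) >= min_reads
  } else {
    apply(counts, 1, min) >= min_reads
  }
  counts[keep, , drop = FALSE]
}

#' Counts-per-million normalization with log2 layer
#'
#' CPM is computed against per-sample library sizes summed over the genes
#' present in the input (i.e. after any low-count filtering, matching the
#' pipeline order); the log2 layer is `log2(cpm + pseudocount)`.
#'
#' @param counts count matrix, genes as rows.
#' @param pseudocount added before the log (default 1).
#' @return list with `cpm`, `log2_cpm` and `library_sizes`. Each CPM column
#'   sums to 1e6.
#' @export
cpm_log2 <- function(counts, pseudocount = 1) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_input("zero library size for sample(s): ",
               paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  list(cpm = cpm, log2_cpm = log2(cpm + pseudocount), library_sizes = lib)
}

#' Over-expression outlier calls by Z-score of log2 CPM
#'
#' In the default `per_sample` orientation the Z-score of gene g in sample
#' s standardizes the sample's own log2-CPM distribution across genes; a
#' call is made when z is at or above `z_cutoff`. The `per_gene`
#' orientation standardizes each gene across samples instead
#' (cohort-relative over-expression). A zero standard deviation along the
#' standardization axis yields no calls there.
#'
#' @param log2_cpm matrix from [cpm_log2()], genes as rows.
#' @param z_cutoff inclusive threshold (default 3).
#' @param orientation `"per_sample"` (default) or `"per_gene"`.
#' @return data.frame with columns `gene`, `sample`, `zscore`.
#' @export
detect_outliers <- function(log2_cpm, z_cutoff = 3,
                            orientation = c("per_sample", "per_gene")) {
  orientation <- match.arg(orientation)
  if (orientation == "per_sample" && nrow(log2_cpm) < 2)
    stop_input("per-sample Z-scores need at least 2 genes")
  if (orientation == "per_gene" && ncol(log2_cpm) < 2)
    stop_input("per-gene Z-scores need at least 2 samples")
  z <- if (orientation == "per_sample") {
    scale(log2_cpm)                      # column-wise: within each sample
  } else {
    t(scale(t(log2_cpm)))                # row-wise: within each gene
  }
  z[!is.finite(z)] <- -Inf               # sd = 0 -> no calls
  hit <- which(z >= z_cutoff, arr.ind = TRUE)
  data.frame(gene = rownames(log2_cpm)[hit[, 1]],
             sample = colnames(log2_cpm)[hit[, 2]],
             zscore = z[hit], stringsAsFactors = FALSE)
}

#' Hypergeometric overlap test for two gene sets
#'
#' Tests whether two gene sets (e.g. over-expression outliers of a tumor
#' and of its xenograft generation) share more members than expected by
#' chance: the upper-tail probability of observing at least the seen
#' overlap when `|set_b|` genes are drawn without replacement from a
#' universe of `universe_size` genes of which `|set_a|` are marked.
#'
#' @param set_a,set_b character vectors (deduplicated internally).
#' @param universe_size total number of genes considered; must be at least
#'   `|set_a U set_b|`.
#' @return list with `overlap`, `n_a`, `n_b`, `universe_size`, `p_value`.
#' @export
outlier_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(union(set_a, set_b)) > universe_size)
    stop_input("sets exceed the stated universe size")
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1, length(set_a), universe_size - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(overlap = ov, n_a = length(set_a), n_b = length(set_b),
       universe_size = universe_size, p_value = p)
}
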