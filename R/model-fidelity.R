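# Genomic fidelity of xenograft generations and 3D tumor-spheres:
# sample-by-variant VAF matrices, correlation / Ward clustering / PCA,
# conserved-variant fractions and Mann-Whitney VAF-shift tests.

#' Sample-by-variant VAF matrix
#'
#' Rows are samples, columns the union of variant keys
#' (chrom:pos:ref:alt) across samples; an entry is the VAF where the
#' variant was called. By default absence is encoded as 0 (the joint "all
#' mutations detected" view that keeps correlation and PCA well defined);
#' `absent = "na"` gives the missing-aware variant for sensitivity checks.
#'
#' @param variants data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `vaf`; at least 2 distinct samples.
#' @param absent `"zero"` (default) or `"na"`.
#' @return numeric matrix, samples x variant keys.
#' @export
build_vaf_matrix <- function(variants, absent = c("zero", "na")) {
  absent <- match.arg(absent)
  samples <- unique(variants$sample_id)
  key <- variant_key(variants)
  dup <- duplicated(paste(variants$sample_id, key))
  if (any(dup))
    stop_input("duplicate variant key within a sample: ",
               paste(head(key[dup], 3), collapse = ", "))
  if (length(samples) < 2) stop_input("need at least 2 samples")
  keys <- sort(unique(key))
  fill <- if (absent == "zero") 0 else NA_real_
  mat <- matrix(fill, nrow = length(samples), ncol = length(keys),
                dimnames = list(samples, keys))
  mat[cbind(match(variants$sample_id, samples), match(key, keys))] <- variants$vaf
  mat
}

#' Correlation, Ward clustering and PCA of a VAF (or expression) matrix
#'
#' The similarity toolkit applied jointly to genomic (Pearson on VAFs) and
#' transcriptomic (Spearman on log2 CPM) profiles: pairwise sample
#' correlations, agglomerative clustering with Ward's criterion on
#' Euclidean distances, and PCA on mean-centered, unscaled features with
#' explained-variance fractions. Zero-variance features are dropped with a
#' notice before correlation/PCA.
#'
#' @param mat numeric matrix, samples as rows, features as columns.
#' @param corr_method `"pearson"` or `"spearman"`.
#' @return a `similarity_suite`: list with `correlation` (samples x
#'   samples), `hclust` (Ward tree on Euclidean distances), `pca`
#'   (`scores`, `explained_variance`), `n_dropped_features`,
#'   `corr_method`.
#' @export
similarity_suite <- function(mat, corr_method = c("pearson", "spearman")) {
  corr_method <- match.arg(corr_method)
  if (nrow(mat) < 2) stop_input("need at least 2 samples")
  vars <- apply(mat, 2, function(x) stats::var(x))
  informative <- which(vars > 0)
  n_dropped <- ncol(mat) - length(informative)
  if (length(informative) < 2)
    stop_input("degenerate input: fewer than 2 features with nonzero variance")
  if (n_dropped > 0)
    message(n_dropped, " constant feature(s) dropped")
  m <- mat[, informative, drop = FALSE]
  cors <- cor(t(m), method = corr_method)
  tree <- hclust(dist(m), method = "ward.D2")
  pca <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(correlation = cors, hclust = tree,
                 pca = list(scores = pca$x, explained_variance = ev),
                 n_dropped_features = n_dropped, corr_method = corr_method),
            class = "similarity_suite")
}

#' @export
print.similarity_suite <- function(x, ...) {
  cat("Similarity suite (", x$corr_method, " correlation, Ward/Euclidean clustering, PCA)\n",
      sep = "")
  cat("  samples:", nrow(x$correlation), "\n")
  cat("  PC1/PC2 explained variance:",
      paste(sprintf("%.1f%%", 100 * head(x$pca$explained_variance, 2)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.similarity_suite <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x$correlation, main = "Correlation", axes = FALSE)
  plot(x$hclust, main = "Ward clustering", xlab = "", sub = "")
  plot(x$pca$scores[, 1], x$pca$scores[, 2], pch = 19,
       xlab = "PC1", ylab = "PC2", main = "PCA")
  graphics::text(x$pca$scores[, 1], x$pca$scores[, 2],
                 rownames(x$pca$scores), pos = 3, cex = 0.7)
  graphics::barplot(100 * x$pca$explained_variance, ylab = "% variance",
                    main = "Scree")
  invisible(x)
}

#' Conserved-variant fraction between two sample stages
#'
#' The fraction of the origin sample's (filtered, rare + missense) variant
#' set found again in the target sample, matched by the
#' chrom:pos:ref:alt key.
#'
#' @param origin,target character vectors of variant keys, or variant
#'   data.frames (keys derived with [variant_key()]).
#' @return list with `shared`, `n_origin`, `fraction` (NA when the origin
#'   set is empty).
#' @export
conserved_fraction <- function(origin, target) {
  if (is.data.frame(origin)) origin <- variant_key(origin)
  if (is.data.frame(target)) target <- variant_key(target)
  origin <- unique(origin); target <- unique(target)
  if (length(origin) == 0)
    return(list(shared = 0L, n_origin = 0L, fraction = NA_real_))
  shared <- length(intersect(origin, target))
  list(shared = shared, n_origin = length(origin),
       fraction = shared / length(origin))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments,
# tie-aware (U counts ties as 1/2). Used for small samples.
mw_exact_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  centre <- na * length(b) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p <- mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
  list(u = u_obs, p = p)
}

#' Mann-Whitney VAF-shift test between two stages
#'
#' Two-sided Mann-Whitney U test comparing pooled variant-level VAFs of two
#' stages (e.g. the original tumors against their first xenograft
#' generation). For small samples (both groups <= `exact_max`) the p-value
#' is computed by exact enumeration over all group assignments, which
#' handles ties; larger samples use the tie-corrected normal
#' approximation.
#'
#' @param group_a,group_b non-empty numeric vectors of VAFs.
#' @param exact_max largest per-group size for the exact path (default 10).
#' @return a `vaf_shift_test`: list with `u` (U statistic of `group_a`),
#'   `p_value`, `median_a`, `median_b`, `n_a`, `n_b`, `method`.
#' @export
vaf_shift_test <- function(group_a, group_b, exact_max = 10) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop_input("both groups must be non-empty")
  if (length(group_a) <= exact_max && length(group_b) <= exact_max) {
    res <- mw_exact_enumeration(group_a, group_b)
    u <- res$u; p <- res$p; method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE,
                                       correct = TRUE))
    u <- unname(wt$statistic)
    p <- wt$p.value
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(u = u, p_value = p,
                 median_a = median(group_a), median_b = median(group_b),
                 n_a = length(group_a), n_b = length(group_b),
                 method = method),
            class = "vaf_shift_test")
}

#' @export
print.vaf_shift_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney VAF shift: medians %.3f vs %.3f, U = %.1f, p = %.3g (%s)\n",
              x$median_a, x$median_b, x$u, x$p_value, x$method))
  invisible(x)
}

#' Track actionable events across xenograft stages
#'
#' For each actionable event detected in the originating tumor, looks up
#' its footprint at every stage of the patient's lineage: VAF by stage for
#' SNV/INDELs (matched by variant key; missing where the variant was not
#' called, which is distinct from VAF 0), copy number by stage for CNVs
#' (matched by gene), and an outlier presence flag by stage for
#' over-expression events.
#'
#' @param events data.frame from [classify_events()] for the originating
#'   tumor samples.
#' @param samples sample table with `sample_id`, `patient_id`, `stage`.
#' @param variants all-stage variant calls (with `sample_id`).
#' @param cnvs all-stage CNV segments (with `sample_id`, `genes`,
#'   `copy_number`), or NULL.
#' @param outlier_calls all-stage over-expression calls (`gene`, `sample`),
#'   or NULL.
#' @return long data.frame: one row per (event, stage) with `value` (VAF or
#'   copy number; NA where absent) and `present`.
#' @export
track_actionable <- function(events, samples, variants, cnvs = NULL,
                             outlier_calls = NULL) {
  if (nrow(events) == 0)
    return(data.frame(event_id = integer(0), patient_id = character(0),
                      event_class = character(0), gene = character(0),
                      stage = character(0), value = numeric(0),
                      present = logical(0), stringsAsFactors = FALSE))
  vkey <- variant_key(variants)
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    lineage <- samples[samples$patient_id == ev$patient_id, , drop = FALSE]
    for (j in seq_len(nrow(lineage))) {
      sid <- lineage$sample_id[j]
      value <- NA_real_; present <- FALSE
      if (ev$event_class == "SNV_INDEL") {
        k <- paste(ev$chrom, ev$pos, ev$ref, ev$alt, sep = ":")
        hit <- which(variants$sample_id == sid & vkey == k)
        if (length(hit) > 0) { value <- variants$vaf[hit[1]]; present <- TRUE }
      } else if (ev$event_class == "CNV" && !is.null(cnvs)) {
        rows <- cnvs[cnvs$sample_id == sid, , drop = FALSE]
        hit <- which(vapply(strsplit(rows$genes, ","), function(g)
          ev$gene %in% trimws(g), logical(1)))
        if (length(hit) > 0) { value <- rows$copy_number[hit[1]]; present <- TRUE }
      } else if (ev$event_class == "OVEREXPRESSION" && !is.null(outlier_calls)) {
        present <- any(outlier_calls$gene == ev$gene &
                         outlier_calls$sample == sid)
        value <- as.numeric(present)
      } else {
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        event_id = i, patient_id = ev$patient_id,
        event_class = ev$event_class, gene = ev$gene,
        stage = lineage$stage[j], value = value, present = present,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(track_actionable(events[0, ], samples, variants))
  do.call(rbind, out)
}
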