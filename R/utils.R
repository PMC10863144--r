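#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist hclust median na.omit prcomp pbeta qbeta
#'   phyper rbeta rbinom rlnorm rnorm rpois runif setNames wilcox.test
#' @importFrom utils read.delim write.table head
NULL

stop_config <- function(...) {
  stop(structure(class = c("configuration_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_input <- function(...) {
  stop(structure(class = c("input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variant identity key
#'
#' Variants are matched across samples and xenograft generations by the
#' tuple (chromosome, 1-based position, reference allele, alternate allele),
#' the VCF convention for variant identity.
#'
#' @param x data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Integer percentages
#'
#' `percent_half_up()` rounds a single rate to an integer percentage with
#' ties going up (84.2 -> 84, 52.5 -> 53). `percent_truncate1()` truncates
#' to one decimal (11.76 -> 11.7), the convention used for germline carrier
#' rates. `percent_largest_remainder()` converts a vector of counts to
#' integer percentages that sum exactly to 100 by Hamilton (largest
#' remainder) apportionment, the rule used for event-class breakdowns.
#'
#' @param n,total numerator and denominator counts.
#' @param counts non-negative counts to apportion.
#' @return numeric percentage(s).
#' @export
percent_half_up <- function(n, total) {
  if (total <= 0) return(0)
  floor(100 * n / total + 0.5)
}

#' @rdname percent_half_up
#' @export
percent_truncate1 <- function(n, total) {
  if (total <= 0) return(0)
  trunc(1000 * n / total) / 10
}

#' @rdname percent_half_up
#' @export
percent_largest_remainder <- function(counts) {
  if (length(counts) == 0) return(numeric(0))
  total <- sum(counts)
  if (total == 0) return(rep(0, length(counts)))
  exact <- 100 * counts / total
  base <- floor(exact)
  short <- 100 - sum(base)
  if (short > 0) {
    # break remainder ties in favour of the larger count
    ord <- order(exact - base, counts, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  base
}

clip01 <- function(x) pmin(1, pmax(0, x))
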