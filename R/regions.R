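# Genomic region handling. BED intervals are 0-based half-open; variant
# positions are 1-based. The conversion lives here and nowhere else.

#' Read and write BED3 region files
#'
#' Regions are 0-based half-open intervals, as in the BED standard. Target
#' and segmental-duplication regions used by the filtration cascades are
#' exchanged in this format.
#'
#' @param path file path.
#' @param regions data.frame with columns `chrom`, `start`, `end`.
#' @return `read_bed()` returns a data.frame with columns
#'   `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_input("BED file not found: ", path)
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop_input("BED file needs >= 3 columns: ", path)
  bed <- bed[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  if (any(bed$start >= bed$end)) stop_input("BED intervals must have start < end")
  bed
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

bed_to_granges <- function(bed) {
  GenomicRanges::GRanges(bed$chrom,
                         IRanges::IRanges(start = bed$start + 1L, end = bed$end))
}

# 1-based footprint of a variant: an INDEL overlaps a region if any affected
# reference base does.
variants_to_granges <- function(variants) {
  width <- pmax(1L, nchar(variants$ref))
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(start = variants$pos,
                                          end = variants$pos + width - 1L))
}

#' Annotate variants with region membership
#'
#' Fills the `on_target` and `in_segdup` logical columns from BED interval
#' overlap when they are not already present. Overlap is computed on the
#' variant's reference footprint (an INDEL overlaps if any affected base
#' does).
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param targets,segdups region data.frames as returned by [read_bed()],
#'   or `NULL` to leave the corresponding column untouched.
#' @param overwrite recompute membership even when the column exists.
#' @return the variant data.frame with `on_target` / `in_segdup` filled.
#' @export
annotate_regions <- function(variants, targets = NULL, segdups = NULL,
                             overwrite = FALSE) {
  gr <- NULL
  if (!is.null(targets) && (overwrite || is.null(variants$on_target))) {
    gr <- variants_to_granges(variants)
    hits <- GenomicRanges::countOverlaps(gr, bed_to_granges(targets))
    variants$on_target <- hits > 0
  }
  if (!is.null(segdups) && (overwrite || is.null(variants$in_segdup))) {
    if (is.null(gr)) gr <- variants_to_granges(variants)
    hits <- GenomicRanges::countOverlaps(gr, bed_to_granges(segdups))
    variants$in_segdup <- hits > 0
  }
  variants
}
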