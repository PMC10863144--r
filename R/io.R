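# Readers and writers for the tabular exchange formats: annotated variant
# TSV (the documented fixed header) and VCF 4.2 with annotation INFO keys.
# Variant positions are 1-based in both formats.

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "sample_id", "patient_id",
                     "caller_pass", "consequence", "gene", "popmax_af",
                     "cadd_phred", "cancervar_score", "clinvar_class",
                     "intervar_class", "in_cosmic", "alt_reads", "depth",
                     "vaf", "in_segdup", "on_target", "hotspot", "effect")
VARIANT_NUMERIC <- c("pos", "popmax_af", "cadd_phred", "cancervar_score",
                     "alt_reads", "depth", "vaf")
VARIANT_LOGICAL <- c("caller_pass", "in_cosmic", "in_segdup", "on_target",
                     "hotspot")

#' Read and write annotated variant tables
#'
#' The TSV layout has one row per call and the documented column header
#' (chrom, pos, ref, alt, then the annotation columns; absent annotations
#' are empty/NA). The VCF 4.2 layout stores annotations as INFO keys
#' (POPMAX_AF, CADD, CANCERVAR, CLNSIG, INTERVAR, COSMIC, CSQ, GENE, VAF,
#' ALT_READS, DP, HOTSPOT, EFFECT) with the caller's quality filter in the
#' FILTER column.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @param variants variant data.frame.
#' @return `read_variants()` returns a variant data.frame with 1-based
#'   positions and typed columns; records with an unparseable VAF or
#'   position are rejected with their line numbers.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(read_variants_vcf(path))
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  missing <- setdiff(MANDATORY_VARIANT_FIELDS, names(raw))
  if (length(missing) > 0)
    stop_input("missing mandatory column(s): ", paste(missing, collapse = ", "))
  out <- raw
  for (col in intersect(VARIANT_NUMERIC, names(out))) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & is.na(val))
    if (length(bad) > 0)
      stop_input("malformed value in column '", col, "' at line(s): ",
                 paste(bad + 1L, collapse = ", "))  # +1 for the header
    out[[col]] <- val
  }
  for (col in intersect(VARIANT_LOGICAL, names(out)))
    out[[col]] <- as.logical(out[[col]])
  out$pos <- as.integer(out$pos)
  if (!is.null(out$alt_reads)) out$alt_reads <- as.integer(out$alt_reads)
  if (!is.null(out$depth)) out$depth <- as.integer(out$depth)
  validate_variants(out)
  out
}

#' @rdname read_variants
#' @export
write_variants <- function(variants, path) {
  cols <- intersect(VARIANT_COLUMNS, names(variants))
  write.table(variants[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_variants
#' @export
write_variants_vcf <- function(variants, path) {
  info_field <- function(key, value, fmt = "%s") {
    ifelse(is.na(value), NA_character_, sprintf(paste0(key, "=", fmt), value))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=POPMAX_AF,Number=1,Type=Float,Description=\"Population maximum allele frequency\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
    "##INFO=<ID=CANCERVAR,Number=1,Type=Float,Description=\"CancerVar score\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"ClinVar class\">",
    "##INFO=<ID=INTERVAR,Number=1,Type=String,Description=\"InterVar class\">",
    "##INFO=<ID=COSMIC,Number=0,Type=Flag,Description=\"In COSMIC\">",
    "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"Hotspot missense\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=ALT_READS,Number=1,Type=Integer,Description=\"Alternate-supporting reads\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Functional effect (LOF/GOF/unknown)\">",
    "##FILTER=<ID=caller_fail,Description=\"Failed upstream caller quality filter\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  n <- nrow(variants)
  get <- function(col, default) variants[[col]] %||% rep(default, n)
  info <- cbind(info_field("GENE", get("gene", NA_character_)),
                info_field("CSQ", get("consequence", NA_character_)),
                info_field("POPMAX_AF", get("popmax_af", NA_real_), "%g"),
                info_field("CADD", get("cadd_phred", NA_real_), "%g"),
                info_field("CANCERVAR", get("cancervar_score", NA_real_), "%g"),
                info_field("CLNSIG", get("clinvar_class", NA_character_)),
                info_field("INTERVAR", get("intervar_class", NA_character_)),
                ifelse(get("in_cosmic", FALSE) %in% TRUE, "COSMIC", NA),
                ifelse(get("hotspot", FALSE) %in% TRUE, "HOTSPOT", NA),
                info_field("VAF", variants$vaf, "%g"),
                info_field("ALT_READS", get("alt_reads", NA_integer_), "%d"),
                info_field("DP", get("depth", NA_integer_), "%d"),
                info_field("EFFECT", get("effect", NA_character_)))
  info_str <- apply(info, 1, function(x) paste(na.omit(x), collapse = ";"))
  filter <- ifelse(get("caller_pass", TRUE) %in% TRUE, "PASS", "caller_fail")
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", filter, info_str, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

read_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  get_num <- function(key) {
    if (key %in% names(info)) as.numeric(info[[key]]) else
      rep(NA_real_, length(vcf))
  }
  get_chr <- function(key) {
    if (key %in% names(info)) as.character(info[[key]]) else
      rep(NA_character_, length(vcf))
  }
  filt <- as.character(rr$FILTER)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    caller_pass = filt %in% c("PASS", "."),
    consequence = get_chr("CSQ"),
    gene = get_chr("GENE"),
    popmax_af = get_num("POPMAX_AF"),
    cadd_phred = get_num("CADD"),
    cancervar_score = get_num("CANCERVAR"),
    clinvar_class = get_chr("CLNSIG"),
    intervar_class = get_chr("INTERVAR"),
    in_cosmic = if ("COSMIC" %in% names(info)) as.logical(info$COSMIC) else
      rep(FALSE, length(vcf)),
    hotspot = if ("HOTSPOT" %in% names(info)) as.logical(info$HOTSPOT) else
      rep(FALSE, length(vcf)),
    alt_reads = as.integer(get_num("ALT_READS")),
    depth = as.integer(get_num("DP")),
    vaf = get_num("VAF"),
    effect = get_chr("EFFECT"),
    stringsAsFactors = FALSE)
  validate_variants(out)
  out
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Serializes every component of a [simulate_cohort()] bundle: variant,
#' CNV, germline, MSI and sample TSVs, the expression count matrix (genes
#' as rows), target and segdup BEDs, the knowledge-base tables, the truth
#' ledger and the configuration as YAML. Two runs with the same
#' configuration produce byte-identical directories.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) write.table(x, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE,
                                       na = "NA")
  tsv(cohort$samples, "samples.tsv")
  write_variants(cohort$variants, file.path(dir, "variants.tsv"))
  tsv(cohort$cnvs, "cnvs.tsv")
  write_variants(cohort$germline, file.path(dir, "germline.tsv"))
  tsv(cohort$msi, "msi.tsv")
  expr <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
  tsv(expr, "expression_counts.tsv")
  write_bed(cohort$targets, file.path(dir, "targets.bed"))
  write_bed(cohort$segdups, file.path(dir, "segdups.bed"))
  write_knowledge_base(cohort$knowledge_base,
                       file.path(dir, "kb_genes.tsv"),
                       file.path(dir, "kb_drugs.tsv"))
  tsv(cohort$truth$lesions, "truth_lesions.tsv")
  tsv(cohort$truth$drift, "truth_drift.tsv")
  tsv(cohort$truth$outliers, "truth_outliers.tsv")
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
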