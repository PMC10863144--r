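# Gene/drug knowledge base: the curated table that stands behind
# actionability grading. Roles and mechanisms come from closed
# vocabularies so grading is deterministic and testable.

GENE_ROLES <- c("oncogene", "tumor_suppressor", "both", "unknown")
DRUG_MECHANISMS <- c("inhibitor", "antagonist", "agonist", "other")
DRUG_EVIDENCE <- c("validated_direct", "pathway_predicted")
DRUG_STAGES <- c("approved", "investigational")

#' Assemble and validate a knowledge base
#'
#' @param genes data.frame with columns `symbol`, `role` (one of
#'   oncogene / tumor_suppressor / both / unknown), `predisposition`
#'   (logical: cancer-predisposition gene) and `pathway` (free label used to
#'   group the cohort summary rows).
#' @param drugs data.frame with columns `gene`, `drug`, `mechanism`
#'   (inhibitor / antagonist / agonist / other), `evidence`
#'   (validated_direct / pathway_predicted) and `stage`
#'   (approved / investigational). Every `gene` must exist in `genes`.
#' @return a `knowledge_base` object (list of the two validated tables).
#' @export
knowledge_base <- function(genes, drugs) {
  need_g <- c("symbol", "role", "predisposition", "pathway")
  need_d <- c("gene", "drug", "mechanism", "evidence", "stage")
  if (!all(need_g %in% names(genes)))
    stop_input("gene table needs columns: ", paste(need_g, collapse = ", "))
  if (!all(need_d %in% names(drugs)))
    stop_input("drug table needs columns: ", paste(need_d, collapse = ", "))
  if (anyDuplicated(genes$symbol))
    stop_input("duplicate gene symbols in knowledge base")
  if (!all(genes$role %in% GENE_ROLES))
    stop_input("unknown gene role(s): ",
               paste(setdiff(genes$role, GENE_ROLES), collapse = ", "))
  if (!all(drugs$mechanism %in% DRUG_MECHANISMS))
    stop_input("unknown drug mechanism(s)")
  if (!all(drugs$evidence %in% DRUG_EVIDENCE))
    stop_input("unknown drug evidence tag(s)")
  if (!all(drugs$stage %in% DRUG_STAGES))
    stop_input("unknown drug stage tag(s)")
  orphan <- setdiff(drugs$gene, genes$symbol)
  if (length(orphan) > 0)
    stop_input("drug record(s) for gene(s) absent from gene table: ",
               paste(orphan, collapse = ", "))
  structure(list(genes = genes, drugs = drugs), class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base:", nrow(x$genes), "genes,", nrow(x$drugs),
      "drug records\n")
  invisible(x)
}

kb_role <- function(kb, gene) {
  i <- match(gene, kb$genes$symbol)
  ifelse(is.na(i), NA_character_, kb$genes$role[i])
}

kb_pathway <- function(kb, gene) {
  i <- match(gene, kb$genes$symbol)
  ifelse(is.na(i), NA_character_, kb$genes$pathway[i])
}

#' Built-in neuroblastoma-oriented knowledge base
#'
#' A compact synthetic curation (~40 genes) of the genes recurrently
#' actionable in relapsed neuroblastoma -- ALK, MYCN, ATRX, MDM2, CDK6,
#' CCND1, PIK3CA, HIF1A, TOP2A, CDKN2A/B, TP53 and companions -- each with
#' at least one drug record tagged with mechanism, evidence level
#' (validated direct target vs pathway-level prediction) and development
#' stage. The contents are synthetic stand-ins for live oncology knowledge
#' bases; they carry the structure grading needs, not clinical truth.
#'
#' @return a `knowledge_base` object.
#' @export
default_knowledge_base <- function() {
  g <- function(symbol, role, predisposition, pathway)
    data.frame(symbol = symbol, role = role, predisposition = predisposition,
               pathway = pathway, stringsAsFactors = FALSE)
  genes <- rbind(
    g("ALK", "oncogene", TRUE, "RTK/growth factor signaling"),
    g("MYCN", "oncogene", FALSE, "transcription/MYC"),
    g("MDM2", "oncogene", FALSE, "cell cycle control"),
    g("CDK6", "oncogene", FALSE, "cell cycle control"),
    g("CDK4", "oncogene", FALSE, "cell cycle control"),
    g("CCND1", "oncogene", FALSE, "cell cycle control"),
    g("PIK3CA", "oncogene", FALSE, "PI3K/AKT/mTOR"),
    g("AKT1", "oncogene", FALSE, "PI3K/AKT/mTOR"),
    g("MTOR", "oncogene", FALSE, "PI3K/AKT/mTOR"),
    g("HIF1A", "oncogene", FALSE, "hypoxia response"),
    g("TOP2A", "oncogene", FALSE, "DNA damage/repair"),
    g("AURKA", "oncogene", FALSE, "cell cycle control"),
    g("BRAF", "oncogene", FALSE, "MAPK signaling"),
    g("KRAS", "oncogene", FALSE, "MAPK signaling"),
    g("NRAS", "oncogene", FALSE, "MAPK signaling"),
    g("RET", "oncogene", TRUE, "RTK/growth factor signaling"),
    g("KIT", "oncogene", FALSE, "RTK/growth factor signaling"),
    g("FGFR1", "oncogene", FALSE, "RTK/growth factor signaling"),
    g("EGFR", "oncogene", FALSE, "RTK/growth factor signaling"),
    g("ERBB2", "oncogene", FALSE, "RTK/growth factor signaling"),
    g("MET", "oncogene", FALSE, "RTK/growth factor signaling"),
    g("MITF", "both", TRUE, "transcription/differentiation"),
    g("TSHR", "oncogene", TRUE, "GPCR signaling"),
    g("ATRX", "tumor_suppressor", FALSE, "DNA damage/repair"),
    g("TP53", "tumor_suppressor", TRUE, "DNA damage/repair"),
    g("CDKN2A", "tumor_suppressor", FALSE, "cell cycle control"),
    g("CDKN2B", "tumor_suppressor", FALSE, "cell cycle control"),
    g("CUL4A", "both", FALSE, "protein homeostasis"),
    g("PSMC2", "oncogene", FALSE, "protein homeostasis"),
    g("TNKS", "oncogene", FALSE, "WNT signaling"),
    g("BRCA1", "tumor_suppressor", TRUE, "DNA damage/repair"),
    g("BRCA2", "tumor_suppressor", TRUE, "DNA damage/repair"),
    g("PALB2", "tumor_suppressor", TRUE, "DNA damage/repair"),
    g("CHEK2", "tumor_suppressor", TRUE, "DNA damage/repair"),
    g("PTEN", "tumor_suppressor", TRUE, "PI3K/AKT/mTOR"),
    g("RB1", "tumor_suppressor", TRUE, "cell cycle control"),
    g("NF1", "tumor_suppressor", TRUE, "MAPK signaling"),
    g("SMARCA4", "tumor_suppressor", TRUE, "chromatin remodeling"),
    g("PHOX2B", "both", TRUE, "transcription/differentiation"),
    g("PDCD1", "unknown", FALSE, "immune checkpoint"),
    g("CD274", "unknown", FALSE, "immune checkpoint")
  )
  d <- function(gene, drug, mechanism, evidence, stage)
    data.frame(gene = gene, drug = drug, mechanism = mechanism,
               evidence = evidence, stage = stage, stringsAsFactors = FALSE)
  drugs <- rbind(
    d("ALK", "lorlatinib", "inhibitor", "validated_direct", "investigational"),
    d("ALK", "crizotinib", "inhibitor", "validated_direct", "approved"),
    d("MYCN", "BET-bromodomain inhibitor", "other", "pathway_predicted", "investigational"),
    d("MYCN", "aurora-A destabilizer", "other", "validated_direct", "investigational"),
    d("MDM2", "idasanutlin", "inhibitor", "validated_direct", "investigational"),
    d("CDK6", "ribociclib", "inhibitor", "validated_direct", "investigational"),
    d("CDK4", "palbociclib", "inhibitor", "validated_direct", "approved"),
    d("CCND1", "CDK4/6 blockade (palbociclib)", "inhibitor", "validated_direct", "approved"),
    d("PIK3CA", "alpelisib", "inhibitor", "validated_direct", "approved"),
    d("AKT1", "capivasertib", "inhibitor", "validated_direct", "investigational"),
    d("MTOR", "temsirolimus", "inhibitor", "validated_direct", "approved"),
    d("HIF1A", "belzutifan (HIF pathway)", "inhibitor", "validated_direct", "investigational"),
    d("TOP2A", "etoposide", "inhibitor", "validated_direct", "approved"),
    d("AURKA", "alisertib", "inhibitor", "validated_direct", "investigational"),
    d("BRAF", "dabrafenib", "inhibitor", "validated_direct", "approved"),
    d("KRAS", "MEK blockade (trametinib)", "other", "pathway_predicted", "approved"),
    d("NRAS", "MEK blockade (trametinib)", "other", "pathway_predicted", "approved"),
    d("RET", "selpercatinib", "inhibitor", "validated_direct", "approved"),
    d("KIT", "imatinib", "inhibitor", "validated_direct", "approved"),
    d("FGFR1", "erdafitinib", "inhibitor", "validated_direct", "investigational"),
    d("EGFR", "erlotinib", "inhibitor", "validated_direct", "approved"),
    d("ERBB2", "trastuzumab", "antagonist", "validated_direct", "approved"),
    d("MET", "crizotinib", "inhibitor", "validated_direct", "approved"),
    d("MITF", "surveillance/HDAC pathway", "other", "pathway_predicted", "investigational"),
    d("TSHR", "pathway surveillance", "other", "pathway_predicted", "investigational"),
    d("ATRX", "olaparib + irinotecan", "other", "pathway_predicted", "investigational"),
    d("TP53", "eprenetapopt (p53 reactivator)", "other", "pathway_predicted", "investigational"),
    d("CDKN2A", "CDK4/6 blockade (palbociclib)", "other", "validated_direct", "investigational"),
    d("CDKN2B", "CDK4/6 blockade (palbociclib)", "other", "validated_direct", "investigational"),
    d("CUL4A", "proteasome pathway", "other", "pathway_predicted", "investigational"),
    d("PSMC2", "carfilzomib", "inhibitor", "validated_direct", "investigational"),
    d("TNKS", "tankyrase inhibitor", "inhibitor", "validated_direct", "investigational"),
    d("BRCA1", "olaparib", "other", "validated_direct", "approved"),
    d("BRCA2", "olaparib", "other", "validated_direct", "approved"),
    d("PALB2", "olaparib", "other", "pathway_predicted", "investigational"),
    d("CHEK2", "PARP pathway", "other", "pathway_predicted", "investigational"),
    d("PTEN", "AKT pathway blockade", "other", "pathway_predicted", "investigational"),
    d("RB1", "aurora pathway", "other", "pathway_predicted", "investigational"),
    d("NF1", "MEK blockade (selumetinib)", "other", "validated_direct", "approved"),
    d("SMARCA4", "EZH2 pathway", "other", "pathway_predicted", "investigational"),
    d("PHOX2B", "surveillance", "other", "pathway_predicted", "investigational"),
    d("PDCD1", "pembrolizumab", "antagonist", "validated_direct", "approved"),
    d("CD274", "atezolizumab", "antagonist", "validated_direct", "approved")
  )
  knowledge_base(genes, drugs)
}

#' Read / write a knowledge base as two TSV files
#'
#' @param kb a `knowledge_base`.
#' @param genes_path,drugs_path file paths for the two tables.
#' @return `read_knowledge_base()` returns a validated `knowledge_base`.
#' @export
write_knowledge_base <- function(kb, genes_path, drugs_path) {
  write.table(kb$genes, genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(kb$drugs, drugs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_knowledge_base
#' @export
read_knowledge_base <- function(genes_path, drugs_path) {
  knowledge_base(read.delim(genes_path, stringsAsFactors = FALSE),
                 read.delim(drugs_path, stringsAsFactors = FALSE))
}
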