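---
title: "Variant prioritization, actionability tiering and xenograft fidelity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant prioritization, actionability tiering and xenograft fidelity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticaction)
```

# Scope

`somaticaction` implements the downstream, decision-making half of a
pediatric precision-oncology workflow, with relapsed neuroblastoma as the
motivating setting. Upstream engines (aligners, somatic and germline
callers, CNV callers, annotators, RNA quantifiers) are consumed as inputs;
the package owns everything from annotated calls to clinical shortlists:

1. small-variant filtration (somatic, germline, tumor-only cascades),
2. pathogenicity prioritization (CADD / CancerVar),
3. actionable copy-number selection,
4. tumor mutational burden (TMB) and MSI-high threshold calls,
5. expression-outlier detection from raw counts,
6. two-tier actionability grading against a gene/drug knowledge base,
7. genomic-fidelity quantification of patient-derived xenograft (PDX)
   generations and 3D tumor-sphere models.

Because patient sequencing data of this kind cannot be redistributed, the
package ships a synthetic-cohort generator whose outputs carry the
statistical structure the analysis assumes, together with a truth ledger
of every planted lesion. All tests, including the cohort-level acceptance
suite, run against these synthetic cohorts.

# Filtration cascades

A somatic call survives `filter_somatic()` iff it passes *all* of:
caller quality filter; not in a segmental-duplication region; population
maximum allele frequency (popmax) absent or `<= 0.01`; on target; not
synonymous; `alt_reads >= 8`; `VAF >= 0.05`. Two readings deserve note:

* **Read support and VAF are independent requirements.** The source rule
  ("fewer than 8 reads and VAF below 5%") could be parsed so that only
  calls failing *both* thresholds are removed; that reading would keep a
  7-read, 60%-VAF artifact, defeating the rule's purpose. We require both
  thresholds (failing either removes), and both are configurable.
* **Absent popmax passes.** A variant never observed in population panels
  is rare by construction; only an observed frequency strictly above the
  cutoff removes. The cutoff itself is strict: exactly 1% is kept.

The audit trail attributes each removal to the *first* failing rule in the
order above. This affects bookkeeping only: the kept set equals the
intersection of single-rule kept sets, which the test suite asserts as an
order-independence property, along with idempotence and the
`kept + removed = input` conservation law.

`prioritize_pathogenic()` retains a filtered call iff CADD phred `> 20`
*or* CancerVar `> 0.80`, both strict, with an absent score failing its
clause.

**Tumor-only mode** (no matched normal) appends one more rule: remove when
popmax `> 0.001` *and* the variant is not in COSMIC, i.e. COSMIC
membership rescues moderately frequent variants. The sentence defining the
rule admits a harsher reading in which each condition removes
independently; we implement the rescue reading as the default and expose
`cosmic_rescue = FALSE` for the strict one.

**Germline** screening applies the shared prefilters (caller pass,
segdup, popmax, on-target), then restricts to a supplied
cancer-predisposition gene list, requires Pathogenic/Likely_pathogenic in
ClinVar *or* InterVar, and excludes ClinVar conflicting interpretations
even when InterVar is pathogenic.

# Copy-number selection

`select_actionable_cnvs()` keeps `(segment, gene)` pairs with CN = 0 on a
tumor-suppressor (biallelic deletion) or CN >= 10 on an oncogene (focal
amplification), minus ACMG benign/likely-benign calls and segments that
failed manual IGV review. Choices made where the rule is silent:

* Focality is not re-derived from segment length; CN >= 10 is the
  operative criterion. An optional `max_amp_length` guard exists, off by
  default.
* Genes annotated `both` (context-dependent role) qualify under either
  branch and are flagged via the `role` column.
* `igv_flag = "not_reviewed"` counts as passed by default: manual review
  cannot be automated, and withholding unreviewed calls is a cohort-level
  policy decision (`not_reviewed_passes = FALSE`).

# Burden metrics

TMB = (missense calls with VAF >= 0.05) / (target length in Mb). The
packaged target lengths are 3,040,053 bp for the cancer-gene-panel assay
and 38,289,292 bp for the whole exome. A burden of >= 5 mutations/Mb is
flagged actionable. The boundary is deliberately configurable
(`comparison = ">="` or `">"`): the two conventions circulate side by
side in clinical practice and differ only exactly at the cutoff; the
inclusive form is the default. The MSI score itself is an upstream input;
the package makes the threshold call only (score >= 10 is MSI-high).

# Expression outliers

The order is fixed and asserted by tests: low-count filter, then CPM on
library sizes computed over the *retained* genes, then `log2(cpm + 1)`,
then Z-scores.

* The low-count rule removes a gene only when it fails to reach 20 reads
  in **every** sample (`max < 20`). The alternative reading -- drop a gene
  as soon as any sample is below 20 -- would discard most of the
  transcriptome and is available as `rule = "any_below"` for sensitivity
  analyses only.
* The pseudocount is 1 (configurable); CPM columns sum to 1e6 exactly.
* Z-scores standardize each **sample's** log2-CPM distribution across
  genes (`per_sample`, the default): an outlier is a gene extreme within
  its own transcriptome snapshot. The cohort-relative alternative
  (`per_gene`, standardizing each gene across samples) answers a subtly
  different question -- "is this gene unusually high in this sample
  compared to the rest of the cohort?" -- and is tested equally. Calls use
  an inclusive z >= 3; a zero standard deviation yields no calls rather
  than infinities.

Preservation of outlier sets across tumor generations is tested with the
upper-tail hypergeometric probability of the observed overlap
(`outlier_overlap_test()`), computed with `phyper`; an exhaustive
enumeration oracle backs it in the tests.

# Actionability grading

Candidates from all channels (pathogenic SNV/INDELs, selected CNVs,
over-expression outliers, hypermutation, MSI-high) are matched to a
knowledge base of gene roles and drug records. Each drug record carries a
mechanism (inhibitor / antagonist / agonist / other), an evidence tag
(`validated_direct` vs `pathway_predicted`) and a development stage. This
encoding replaces live queries to oncology databases: the curation that
would normally happen at a molecular tumor board is frozen into a table,
making the grading deterministic and testable.

The mechanism-concordance rule prunes records whose action cannot touch
the lesion: an inhibitor or antagonist is dropped for loss-of-function
alterations in tumor suppressors (one cannot inhibit a lost function).
Lesion effects come from the `effect` field; when absent, frameshift and
stopgain default to LOF, hotspot-flagged missense to GOF, everything else
to unknown. Copy-number deletions act as LOF, amplifications and
over-expression as GOF.

Grades: `VERY_HIGH` when at least one surviving record is a validated
direct target *and* the lesion's effect is known; otherwise `HIGH` when
any record survives; candidates with no surviving record, or whose gene
the knowledge base does not know, are dropped (with a notice).
A lesion of unknown functional effect is never graded `VERY_HIGH`, even
on validated evidence -- the conservative choice where the grading
convention is unstated. Hypermutation and MSI-high events attach the
immune-checkpoint records (PD-1/PD-L1 blockade) and grade `VERY_HIGH`.

Cohort summaries report per-class percentages by largest-remainder
(Hamilton) apportionment so that integer percentages sum to exactly 100
-- the rule that reproduces published breakdowns such as
21/8/10/1 events -> 53/20/25/2% where plain half-up rounding would give
103 in total. Single rates (e.g. the fraction of tumors with any event)
round half-up; the germline carrier rate alone is reported truncated to
one decimal, following the convention of clinical cohort reports.

# Xenograft and 3D-model fidelity

Variants are identified by the `(chrom, pos, ref, alt)` tuple throughout.
`build_vaf_matrix()` assembles samples x variant-keys with VAF entries;
absence is encoded as 0 by default -- the joint "all detected mutations"
view that keeps correlation and PCA well defined -- with an `absent = "na"`
mode for sensitivity checks (whether published analyses of this type use
zero-fill or pairwise-complete entries is generally unstated).

`similarity_suite()` computes pairwise correlations (Pearson for VAF
profiles, Spearman for expression), agglomerative clustering with Ward's
criterion on Euclidean distances (`hclust(method = "ward.D2")`, the form
consistent with unsquared distances), and PCA on mean-centered, unscaled
features -- VAFs share a scale, so feature scaling would only inflate
noise. Constant features are dropped with a notice.

Conservation between stages is the fraction of the origin sample's rare
(popmax <= 1%) missense set found again in the target, and is undefined
(NA) for an empty origin. VAF shifts between stages are tested with a
two-sided Mann-Whitney U on variant-level VAFs pooled across patients per
stage. For small groups (both n <= 10) the p-value comes from exact
enumeration over all group assignments, which handles ties through
midrank U counting; larger groups use the tie-corrected normal
approximation. The enumeration threshold is a numerical choice: at
n = 10 + 10 the enumeration is 184,756 assignments and still instant,
beyond that the approximation is accurate.

`track_actionable()` follows each originating-tumor event across the
lineage: VAF by stage for SNVs (absent is recorded as missing, *not* 0 --
a variant not called is different from a variant at frequency zero), copy
number by stage for CNVs, presence flags for outliers.

# The synthetic cohort: what it emulates, and what it does not

Defaults were fixed once, as the study conditions of the package:

| knob | default | rationale |
|---|---|---|
| patients | 5 | lineage count typical of PDX programs reaching P2 |
| background calls/tumor | 200 | enough exemplars per filtration rule |
| P1 loss rate | 0.20 | origin-variant conservation ~ 0.8 at first passage |
| P2 additional loss | 0.05 | second-passage drift smaller than first |
| 3D additional loss | 0.30 | culture bottleneck larger than passage drift |
| VAF inflation P1 / P2 | 1.3 / 1.05 | tumor-cell enrichment in xenografts raises VAFs, strongly at P1, marginally at P2 |
| VAF deflation 3D | 0.7 | frequency drop in sphere culture |
| VAF jitter sd | 0.02 | resequencing noise |
| passage gain rate | 0.02 | new variants per passage; small, as lineage drift is loss-dominated |
| background VAFs | Beta(2, 5) truncated at 0.05 | right-skewed clonal spectrum; no published distribution to copy |
| sub-threshold VAF fraction | 0.15 | exercises the 5% gate |
| hypermutator probability | 1/19 | one hypermutated tumor per ~19-sample cohort |
| germline carrier probability | 2/17 | two carriers per ~17 germlines |
| expression genes / fold change | 500 / 16x | compact but filterable transcriptome; planted outliers separable at z >= 3 |

Drift is multiplicative with Gaussian jitter and clipping into (0, 1];
loss is Bernoulli per variant per transition. Background calls are
assigned one violated rule each (or none), so the audit of a synthetic
tumor is predictable from the generating probabilities. Planted
actionable lesions rotate deterministically through knowledge-base genes
whose grading outcome is forced by construction; the truth ledger records
each with its expected priority, and the acceptance suite requires the
pipeline to recover all of them with no spurious very-high calls.

Expression counts are Poisson around lognormal gene baselines with a
shared per-lineage effect (sd 0.2 on the log scale) and per-sample noise
(sd 0.15), so lineage members correlate more with each other than across
lineages. Planted outlier genes are drawn from a high-baseline pool
(~1.5 log2 units above the background mean): a 16x fold change then sits
~4 z-units above its own sample's distribution while unplanted pool genes
stay ~1.5 sd below the calling threshold, which is what makes exact
planted-set recovery a fair requirement rather than a coin flip.

Limitations a user should keep in mind before generalizing from green
tests to real data:

* The generator produces *annotations*, not reads: caller errors,
  mapping artifacts, contamination by host (mouse) reads and
  batch effects are out of scope.
* Lineage drift is a single chain PZ -> P1 -> P2 -> 3D with
  loss-dominated dynamics. Real xenograft programs implant sibling
  fragments, so a second-generation tumor can conserve *more* of the
  origin's variants than a first-generation one -- per-sample conservation
  minima of ~77% at P1 and ~84% at P2 have been reported side by side. A
  pure-loss chain cannot reproduce that inversion; ours gives
  P2-vs-origin conservation of about (1 - 0.20)(1 - 0.05) = 0.76.
* No mutational signatures, no subclonal structure beyond VAF scaling,
  no copy-number segmentation noise, and expression has no
  composition effects that would require TMM-style normalization.

# Reproducibility and problem sizes

Every stochastic step flows from a single integer seed
(`simulation_config(seed = )`); one seed gives byte-identical serialized
cohorts across processes, which the tests assert by comparing written
files. The test suite uses 5-patient default cohorts for end-to-end
checks, 1-patient/500-variant cohorts with 20 replicates for loss-rate
recovery, 2-patient cohorts over 10 seeds for the shift and clustering
checks, and random batches of up to 1,000 records for the brute-force
oracle comparisons. `scripts/acceptance.R` re-runs the same computations
from the installed package and writes the headline numbers as JSON.
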