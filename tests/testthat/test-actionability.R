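kb <- default_knowledge_base()

cand <- function(event_class = "SNV_INDEL", gene = "ALK", effect = "GOF",
                 patient_id = "P1", sample_id = "P1_PZ") {
  data.frame(patient_id = patient_id, sample_id = sample_id,
             event_class = event_class, gene = gene, effect = effect,
             chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
             alt = NA_character_, detail = NA_real_, stringsAsFactors = FALSE)
}

test_that("effect inference follows consequence and hotspot status", {
  v <- make_variants(4)
  v$consequence <- c("frameshift", "stopgain", "missense", "missense")
  v$hotspot <- c(FALSE, FALSE, TRUE, FALSE)
  expect_equal(infer_effect(v)$effect, c("LOF", "LOF", "GOF", "unknown"))
  v$effect <- c("GOF", NA, NA, NA)   # explicit annotation wins
  expect_equal(infer_effect(v)$effect[1], "GOF")
})

test_that("validated direct targets grade very high; pathway evidence grades high", {
  ev <- classify_events(cand("SNV_INDEL", "ALK", "GOF"), kb)
  expect_equal(ev$priority, "VERY_HIGH")
  expect_match(ev$drugs, "lorlatinib")
  ev2 <- classify_events(cand("SNV_INDEL", "ATRX", "LOF"), kb)
  expect_equal(ev2$priority, "HIGH")
  expect_match(ev2$drugs, "olaparib")
})

test_that("mechanism concordance drops inhibitors aimed at lost tumor-suppressor function", {
  # PSMC2-style case: gene whose only record is an inhibitor
  toy <- knowledge_base(
    data.frame(symbol = "TSX", role = "tumor_suppressor",
               predisposition = FALSE, pathway = "p", stringsAsFactors = FALSE),
    data.frame(gene = "TSX", drug = "tsx-inhibitor", mechanism = "inhibitor",
               evidence = "validated_direct", stage = "approved",
               stringsAsFactors = FALSE))
  expect_equal(nrow(classify_events(cand(gene = "TSX", effect = "LOF"), toy)), 0)
  # the same record is concordant with a GOF lesion
  expect_equal(classify_events(cand(gene = "TSX", effect = "GOF"), toy)$priority,
               "VERY_HIGH")
  # no event ever carries a discordant record
  set.seed(19)
  batch <- do.call(rbind, lapply(1:100, function(i)
    cand(gene = sample(kb$genes$symbol, 1),
         effect = sample(c("LOF", "GOF", "unknown"), 1))))
  evs <- classify_events(batch, kb)
  for (i in seq_len(nrow(evs))) {
    recs <- kb$drugs[kb$drugs$gene == evs$gene[i], ]
    role <- kb$genes$role[kb$genes$symbol == evs$gene[i]]
    surviving <- strsplit(evs$drugs[i], "; ")[[1]]
    discordant <- recs$drug[recs$mechanism %in% c("inhibitor", "antagonist") &
                              evs$effect[i] == "LOF" &
                              role == "tumor_suppressor"]
    expect_length(intersect(surviving, discordant), 0)
  }
})

test_that("unknown effect is never graded very high; unknown genes are dropped with notice", {
  ev <- classify_events(cand("SNV_INDEL", "ALK", "unknown"), kb)
  expect_equal(ev$priority, "HIGH")
  expect_message(out <- classify_events(cand(gene = "NOT_A_GENE"), kb),
                 "dropped")
  expect_equal(nrow(out), 0)
})

test_that("hypermutation and MSI-high events carry immune-checkpoint drugs at very high priority", {
  for (cl in c("HYPERMUTATION", "MSI_HIGH")) {
    ev <- classify_events(cand(cl, NA_character_, "unknown"), kb)
    expect_equal(ev$priority, "VERY_HIGH")
    expect_equal(ev$pathway, "immune checkpoint")
    expect_match(ev$drugs, "pembrolizumab|atezolizumab")
  }
})

test_that("cohort summary reproduces printed-count arithmetic", {
  # class counts 21/8/10/1 over 19 samples, 16 with >= 1 event, 13 with a
  # very-high event
  classes <- rep(c("SNV_INDEL", "CNV", "OVEREXPRESSION", "HYPERMUTATION"),
                 c(21, 8, 10, 1))
  sample_of_event <- c(rep(sprintf("S%02d", 1:16), length.out = 40))
  prio <- rep("HIGH", 40)
  prio[sample_of_event %in% sprintf("S%02d", 1:13)][1:19] <- "VERY_HIGH"
  ev <- data.frame(patient_id = sample_of_event, sample_id = sample_of_event,
                   event_class = classes, gene = "ALK", priority = prio,
                   stringsAsFactors = FALSE)
  s <- summarize_cohort(ev, sprintf("S%02d", 1:19))
  expect_equal(s$class_tally$pct[match(
    c("SNV_INDEL", "CNV", "OVEREXPRESSION", "HYPERMUTATION"),
    s$class_tally$event_class)], c(53, 20, 25, 2))
  expect_equal(sum(s$class_tally$pct), 100)
  expect_equal(s$pct_samples_actionable, 84)   # 16/19
  expect_equal(s$n_events, 40)
})

test_that("empty event sets give an empty matrix and zero tallies", {
  s <- summarize_cohort(empty <- classify_events(cand()[0, ], kb), c("S1", "S2"))
  expect_equal(nrow(s$class_tally), 0)
  expect_equal(s$n_events, 0)
  expect_equal(s$pct_samples_actionable, 0)
  expect_equal(dim(s$matrix), c(0, 2))
})

test_that("largest-remainder percentages sum to 100 and match known breakdowns", {
  expect_equal(percent_largest_remainder(c(21, 8, 10, 1)), c(53, 20, 25, 2))
  expect_equal(percent_largest_remainder(c(8, 6, 4, 1)), c(42, 32, 21, 5))
  set.seed(23)
  for (i in 1:20) {
    counts <- sample(0:30, sample(2:6, 1), replace = TRUE)
    if (sum(counts) == 0) next
    expect_equal(sum(percent_largest_remainder(counts)), 100)
  }
  expect_equal(percent_half_up(16, 19), 84)
  expect_equal(percent_half_up(13, 19), 68)
  expect_equal(percent_half_up(3, 19), 16)
  expect_equal(percent_truncate1(2, 17), 11.7)
})
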