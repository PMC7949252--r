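# Pathway completeness arithmetic, presence rules (80% / key-reaction
# 2/3 / vague 1/3), and the batch driver on the planted organisms.

test_that("reaction status classification follows spontaneity and evidence", {
  ev <- rec_complete$evidence
  spont <- list(reaction_id = "CAH", spontaneous = TRUE, has_seq = TRUE)
  expect_equal(classify_reaction_status(spont, NULL), "spontaneous")
  vague <- list(reaction_id = "RXN-UNKNOWN1", spontaneous = FALSE,
                has_seq = FALSE)
  expect_equal(classify_reaction_status(vague, ev), "vague")
  found <- list(reaction_id = "HEX1", spontaneous = FALSE, has_seq = TRUE)
  expect_equal(classify_reaction_status(found, ev), "found")
  missing <- list(reaction_id = "SBDH", spontaneous = FALSE, has_seq = TRUE)
  expect_equal(classify_reaction_status(missing, ev), "missing")
})

test_that("completeness excludes vague entries only below the vague cutoff", {
  p <- pathway_params()
  expect_equal(pathway_completeness(c(rep("found", 8), rep("missing", 2)), p),
               0.8)
  # 10 entries, 5 found, 3 vague: 3/10 < 1/3 so denominator drops to 7
  st <- c(rep("found", 5), rep("vague", 3), rep("missing", 2))
  expect_equal(pathway_completeness(st, p), 5 / 7)
  # 6 entries, 2 found, 3 vague: 3/6 >= 1/3 so vague count as missing
  st <- c(rep("found", 2), rep("vague", 3), "missing")
  expect_equal(pathway_completeness(st, p), 2 / 6)
  expect_error(pathway_completeness(character(0), p), "empty")
  # with vague_cutoff = 0 the exclusion branch can never fire
  p0 <- pathway_params(vague_cutoff = 0)
  st <- c(rep("found", 5), rep("vague", 3), rep("missing", 2))
  expect_equal(pathway_completeness(st, p0), 0.5)
})

test_that("presence combines the plain cutoff with the key-reaction rule", {
  p <- pathway_params()
  mk <- function(n, keys) {
    list(id = "P", entries = data.frame(
      reaction_id = paste0("r", seq_len(n)), ec = "",
      key = seq_len(n) %in% keys, spontaneous = FALSE, has_seq = TRUE))
  }
  # 10 reactions, 8 found, no keys: 0.8 -> present
  pw <- mk(10, integer())
  st <- c(rep("found", 8), rep("missing", 2))
  expect_true(call_pathway_presence(pw, st, p)$present)
  # 9 reactions incl. 2 keys, both found, 6 found total: 2/3 -> present
  pw <- mk(9, c(1, 2))
  st <- c(rep("found", 6), rep("missing", 3))
  expect_true(call_pathway_presence(pw, st, p)$present)
  # same but only one key found: not present
  st2 <- c("found", "missing", rep("found", 5), rep("missing", 2))
  expect_false(call_pathway_presence(pw, st2, p)$present)
  # a vague key does not satisfy the key rule
  st3 <- c("found", "vague", rep("found", 5), rep("missing", 2))
  expect_false(call_pathway_presence(pw, st3, p)$keys_all_found)
})

test_that("the planted organism resolves all six pathways as designed", {
  calls <- rec_complete$pathway_calls
  present <- names(calls)[vapply(calls, `[[`, TRUE, "present")]
  expect_setequal(present, org_complete$truth$present_pathways)
  absent <- setdiff(names(calls), present)
  expect_setequal(absent, org_complete$truth$absent_pathways)
})

test_that("without evidence only all-spontaneous pathways can be present", {
  empty_ev <- build_evidence_table(org_complete$hits[0, ])
  calls <- predict_pathways(tw$pathway_db, empty_ev)
  for (cl in calls) {
    if (cl$present) {
      expect_true(all(cl$statuses == "spontaneous"))
    }
  }
  # raising the bitscore cutoff to infinity reproduces the empty result
  thr <- match_thresholds(min_bitscore = Inf)
  ev_inf <- build_evidence_table(org_complete$hits, thr)
  calls_inf <- predict_pathways(tw$pathway_db, ev_inf)
  expect_equal(vapply(calls_inf, `[[`, TRUE, "present"),
               vapply(calls, `[[`, TRUE, "present"))
})

test_that("presence is monotone under added passing evidence", {
  set.seed(99)
  base_hits <- org_complete$hits
  all_rxns <- unique(unlist(lapply(tw$pathway_db, function(p)
    p$entries$reaction_id)))
  for (i in 1:200) {
    drop <- runif(nrow(base_hits)) < 0.5
    hits1 <- base_hits[!drop, , drop = FALSE]
    ev1 <- build_evidence_table(hits1)
    calls1 <- predict_pathways(tw$pathway_db, ev1)
    extra <- data.frame(ref_seq_id = "gX",
                        reaction_ids = sample(all_rxns, 1),
                        bitscore = 300, coverage_pct = 90,
                        identity_pct = 90, subunit_label = "")
    ev2 <- build_evidence_table(rbind(hits1, extra))
    calls2 <- predict_pathways(tw$pathway_db, ev2)
    p1 <- vapply(calls1, `[[`, TRUE, "present")
    p2 <- vapply(calls2, `[[`, TRUE, "present")
    expect_true(all(p2 >= p1))
  }
})
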