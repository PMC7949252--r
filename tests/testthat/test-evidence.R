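# Hit-table parsing, binary match calls, and per-reaction evidence
# reduction (best bitscore b_i, matched flag).

test_that("hit tables round-trip and malformed rows abort with row numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(org_complete$hits, path)
  hits <- parse_hit_table(path)
  expect_equal(nrow(hits), nrow(org_complete$hits))
  expect_equal(hits$bitscore, org_complete$hits$bitscore)

  bad <- org_complete$hits
  bad$bitscore[3] <- -5
  write_hit_table(bad, path)
  expect_error(parse_hit_table(path), "row")

  empty <- org_complete$hits[0, ]
  write_hit_table(empty, path)
  expect_equal(nrow(parse_hit_table(path)), 0)
})

test_that("the 12-column alignment dialect is accepted with a sidecar map", {
  dir <- withr::local_tempdir()
  aln <- data.frame(q = c("s1", "s2"), s = "genome", pid = c(80, 60),
                    len = c(90, 40), mm = 0, go = 0, qs = 1, qe = 90,
                    ss = 1, se = 90, ev = 1e-50, bits = c(250, 120))
  utils::write.table(aln, file.path(dir, "aln.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  map <- data.frame(seq_id = c("s1", "s2"), reaction_ids = c("HEX1", "PGI"),
                    ref_length = c(100, 100))
  utils::write.table(map, file.path(dir, "map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hits <- parse_blast_table(file.path(dir, "aln.tsv"),
                            file.path(dir, "map.tsv"))
  expect_equal(hits$coverage_pct, c(90, 40))
  expect_equal(hits$bitscore, c(250, 120))
})

test_that("match calls apply bitscore, coverage, and per-reaction exceptions", {
  thr <- match_thresholds()
  expect_true(call_match(list(bitscore = 250, coverage_pct = 80,
                              identity_pct = 90), thr))
  expect_false(call_match(list(bitscore = 199, coverage_pct = 99,
                               identity_pct = 90), thr))
  expect_false(call_match(list(bitscore = 300, coverage_pct = 60,
                               identity_pct = 90), thr))
  thr_exc <- match_thresholds(exceptions = list(
    RXA = list(min_identity_pct = 75)))
  hit <- list(bitscore = 300, coverage_pct = 80, identity_pct = 60,
              reaction_id = "RXA")
  expect_false(call_match(hit, thr_exc))
  hit$identity_pct <- 80
  expect_true(call_match(hit, thr_exc))
})

test_that("evidence table takes the maximum bitscore regardless of coverage", {
  hits <- rbind(
    data.frame(ref_seq_id = "s1", reaction_ids = "r1", bitscore = 150,
               coverage_pct = 10, identity_pct = 50, subunit_label = ""),
    data.frame(ref_seq_id = "s2", reaction_ids = "r1", bitscore = 90,
               coverage_pct = 95, identity_pct = 50, subunit_label = ""),
    data.frame(ref_seq_id = "s3", reaction_ids = "r3", bitscore = 240,
               coverage_pct = 80, identity_pct = 50, subunit_label = ""))
  ev <- build_evidence_table(hits)
  expect_equal(ev$table$best_bitscore[ev$table$reaction_id == "r1"], 150)
  expect_false(ev$table$matched[ev$table$reaction_id == "r1"])
  expect_true(ev$table$matched[ev$table$reaction_id == "r3"])
  expect_false("r2" %in% ev$table$reaction_id)
})

test_that("multi-reaction reference sequences feed every mapped reaction", {
  hits <- data.frame(ref_seq_id = "s1", reaction_ids = "r1;r2",
                     bitscore = 260, coverage_pct = 90,
                     identity_pct = 80, subunit_label = "")
  ev <- build_evidence_table(hits)
  expect_setequal(ev$table$reaction_id, c("r1", "r2"))
  expect_true(all(ev$table$best_bitscore == 260))
})

test_that("b_i is permutation-invariant and monotone under added hits", {
  set.seed(42)
  base <- org_complete$hits
  for (i in 1:10) {
    perm <- base[sample(nrow(base)), ]
    ev1 <- build_evidence_table(base)
    ev2 <- build_evidence_table(perm)
    expect_identical(ev1$table, ev2$table)
    extra <- base[sample(nrow(base), 1), ]
    extra$bitscore <- extra$bitscore + runif(1, 0, 200)
    ev3 <- build_evidence_table(rbind(base, extra))
    common <- ev1$table$reaction_id
    expect_true(all(
      ev3$table$best_bitscore[match(common, ev3$table$reaction_id)] >=
        ev1$table$best_bitscore))
  }
  # matched implies the bitscore threshold was reached
  ev <- build_evidence_table(base)
  expect_true(all(ev$table$best_bitscore[ev$table$matched] >= 200))
})
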