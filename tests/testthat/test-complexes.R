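# Subunit label homogenisation, catalog extraction filters, and the
# majority rule for complex presence.

test_that("roman, greek, arabic, and letter numbering homogenise together", {
  expect_equal(homogenise_subunit_label("II"), "subunit 2")
  expect_equal(homogenise_subunit_label("beta"), "subunit 2")
  expect_equal(homogenise_subunit_label("2"), "subunit 2")
  expect_equal(homogenise_subunit_label("B"), "subunit 2")
  expect_equal(homogenise_subunit_label("alpha"), "subunit 1")
  expect_equal(homogenise_subunit_label("IV"), "subunit 4")
  expect_equal(homogenise_subunit_label("γ"), "subunit 3")
  expect_true(is.na(homogenise_subunit_label("hypothetical protein")))
})

test_that("labels below the frequency floor are demoted to undefined", {
  headers <- c(rep("x subunit 1", 10), rep("x subunit 2", 7),
               rep("x subunit 3", 3))
  cat1 <- parse_subunits(headers, "R")
  expect_setequal(names(cat1$counts), c("subunit 1", "subunit 2"))
  expect_equal(cat1$undefined_count, 3)
})

test_that("a dominant label (>= 66%) suppresses the minority labels", {
  headers <- c(rep("x subunit 1", 20), rep("x subunit 2", 6))
  cat1 <- parse_subunits(headers, "R")
  expect_equal(names(cat1$counts), "subunit 1")
  expect_equal(cat1$undefined_count, 6)
})

test_that("fully unlabelled header sets yield zero recognised subunits", {
  cat1 <- parse_subunits(rep("hypothetical protein", 4), "R")
  expect_equal(length(cat1$counts), 0)
  expect_equal(cat1$undefined_count, 4)
})

test_that("catalog extraction is invariant to header order", {
  headers <- c(rep("a subunit 1", 6), rep("b subunit 2", 5),
               rep("junk", 3))
  set.seed(7)
  for (i in 1:5) {
    c1 <- parse_subunits(headers, "R")
    c2 <- parse_subunits(sample(headers), "R")
    expect_identical(c1$counts, c2$counts)
    expect_identical(c1$undefined_count, c2$undefined_count)
  }
})

make_catalog4 <- function() {
  parse_subunits(c(rep("x subunit 1", 5), rep("x subunit 2", 5),
                   rep("x subunit 3", 5), rep("x subunit 4", 5)), "R")
}
pass_hit <- list(bitscore = 300, coverage_pct = 90, identity_pct = 80)
fail_hit <- list(bitscore = 100, coverage_pct = 90, identity_pct = 80)

test_that("majority of subunits found implies presence", {
  cat4 <- make_catalog4()
  hits <- list("subunit 1" = pass_hit, "subunit 2" = pass_hit,
               "subunit 3" = pass_hit)
  cc <- call_complex_presence(cat4, hits)
  expect_true(cc$present)
  expect_equal(cc$n_subunits_found, 3)
})

test_that("an exact tie is broken by a passing undefined-pool hit only", {
  cat4 <- make_catalog4()
  two <- list("subunit 1" = pass_hit, "subunit 2" = pass_hit)
  expect_false(call_complex_presence(cat4, two)$present)
  with_undef <- c(two, list(undefined = pass_hit))
  expect_true(call_complex_presence(cat4, with_undef)$present)
  with_bad_undef <- c(two, list(undefined = fail_hit))
  expect_false(call_complex_presence(cat4, with_bad_undef)$present)
})

test_that("zero recognised subunits falls back to plain matching", {
  cat0 <- parse_subunits(rep("hypothetical", 3), "R")
  expect_true(call_complex_presence(cat0, list(undefined = pass_hit))$present)
  expect_false(call_complex_presence(cat0, list(undefined = fail_hit))$present)
})

test_that("presence is monotone in added passing subunit hits", {
  cat4 <- make_catalog4()
  labs <- names(cat4$counts)
  set.seed(3)
  for (i in 1:20) {
    found <- labs[runif(4) < 0.5]
    if (length(found) == 4) next
    hits <- stats::setNames(rep(list(pass_hit), length(found)), found)
    before <- call_complex_presence(cat4, hits)$present
    extra_lab <- sample(setdiff(labs, found), 1)
    hits_after <- c(hits, stats::setNames(list(pass_hit), extra_lab))
    after <- call_complex_presence(cat4, hits_after)$present
    expect_true(!before || after)
  }
})

test_that("the toy ATP synthase complex is called from the hit table", {
  cc <- rec_complete$complex_calls[["ATPS"]]
  expect_equal(cc$n_subunits_recognized, 3)   # alpha, beta, gamma refs
  expect_equal(cc$n_subunits_found, 2)        # atpA, atpB hits
  expect_true(cc$present)                     # 2/3 > 50%
})
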