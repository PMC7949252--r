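# Carbon-source tests, fermentation profiles, and gene essentiality on
# the planted organisms.

test_that("carbon sources resolve per the planted truth on the draft", {
  d <- rec_complete$draft
  for (s in org_complete$truth$carbon_sources_positive) {
    expect_true(test_carbon_source(d, tw_mineral, s,
                                   tw$substance_map)$utilisable,
                label = s)
  }
  for (s in org_complete$truth$carbon_sources_negative) {
    expect_false(test_carbon_source(d, tw_mineral, s,
                                    tw$substance_map)$utilisable,
                 label = s)
  }
  # the input model object is untouched by the test
  n_before <- nrow(d$rxns)
  invisible(test_carbon_source(d, tw_mineral, "glucose", tw$substance_map))
  expect_equal(nrow(d$rxns), n_before)
  expect_error(test_carbon_source(d, tw_mineral, "unobtainium",
                                  tw$substance_map), "unknown substance")
})

test_that("an absent compound can never be an energy source", {
  d <- rec_complete$draft
  # ethanol cannot be oxidised by this organism (no alcohol dehydrogenase
  # running in the oxidative direction)
  r <- test_carbon_source(d, tw_mineral, "ethanol", tw$substance_map)
  expect_false(r$utilisable)
})

test_that("anaerobic growth secretes the lactate branch, aerobic does not", {
  d <- rec_complete$draft
  fp <- predict_fermentation_products(d, tw$media$m9_glc_anaerobic)
  expect_true(org_complete$truth$anaerobic_product %in% fp$exchange)
  expect_true(all(fp$mtf_release_mmol_per_gDW >= 0))
  expect_true(all(fp$fva_max_mmol_per_gDW >=
                    fp$mtf_release_mmol_per_gDW - 1e-6))
  expect_gt(attr(fp, "growth"), 0.1)
  fpa <- predict_fermentation_products(d, tw$media$m9_glc)
  expect_false(org_complete$truth$aerobic_nonproduct %in% fpa$exchange)
})

test_that("no growth means the normalisation is refused", {
  expect_error(
    predict_fermentation_products(rec_complete$draft,
                                  stats::setNames(numeric(0), character(0))),
    "no feasible growth|no growth")
})

test_that("essentiality matches the planted truth table", {
  d <- rec_complete$draft
  ess <- single_gene_deletions(d, tw$media$m9_glc)
  essential <- sort(ess$gene[ess$essential])
  expect_setequal(essential, org_complete$truth$essential_genes)
  expect_true(all(org_complete$truth$nonessential_genes %in%
                    ess$gene[!ess$essential]))
  # deleting nothing reproduces wild-type growth
  wt <- attr(ess, "wild_type_growth")
  expect_equal(wt, fba(d, medium = tw$media$m9_glc)$objective,
               tolerance = 1e-9)
  # the toy truth is binary: thresholds 0.001 and 0.05 agree
  e1 <- single_gene_deletions(d, tw$media$m9_glc, growth_threshold = 0.001)
  e2 <- single_gene_deletions(d, tw$media$m9_glc, growth_threshold = 0.05)
  expect_identical(e1$essential, e2$essential)
})

test_that("essentiality is monotone under medium enrichment", {
  d <- rec_complete$draft
  rich <- single_gene_deletions(d, tw$media$complete)
  minimal <- single_gene_deletions(d, tw$media$m9_glc)
  rich_ess <- rich$gene[rich$essential]
  expect_true(all(minimal$essential[match(rich_ess, minimal$gene)]))
})

test_that("confusion metrics add up", {
  cm <- phenotype_confusion(c(TRUE, TRUE, FALSE, FALSE),
                            c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(cm$accuracy, 0.5)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 0.5)
})
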