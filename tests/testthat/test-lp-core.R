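# FBA / MTF / FVA behaviour on the toy networks and the
# evidence-weighted gap-filling LP with its piecewise weight mapping.

test_that("FBA grows the complete draft and closes without carbon", {
  d <- rec_complete$draft
  s <- fba(d, medium = tw$media$m9_glc)
  expect_equal(s$status, "optimal")
  expect_gt(s$objective, 0.1)
  # steady state and bounds hold
  S <- model_S(apply_medium(d, tw$media$m9_glc))
  expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
  # no uptake at all: no growth
  s0 <- fba(d, medium = stats::setNames(numeric(0), character(0)))
  expect_lt(s0$objective, 1e-9)
  expect_error(fba(d, objective = "NOPE"), "absent")
})

test_that("MTF keeps the optimum while shrinking total flux", {
  d <- rec_complete$draft
  med <- tw$media$m9_glc
  s_fba <- fba(d, medium = med)
  s_mtf <- mtf(d, medium = med)
  expect_equal(s_mtf$objective, s_fba$objective, tolerance = 1e-6)
  expect_lte(attr(s_mtf, "total_flux"), sum(abs(s_fba$fluxes)) + 1e-6)
})

test_that("MTF silences zero-gain internal loops", {
  mets <- data.frame(id = c("s_e0", "a_c0", "b_c0"), name = "m",
                     formula = "C", charge = 0L,
                     compartment = c("e0", "c0", "c0"),
                     stringsAsFactors = FALSE)
  m <- new_metabolic_model("loop", mets, new_rxn_table(), list())
  m <- add_reaction(m, "EX_s_e0", c(s_e0 = -1), -10, 1000,
                    is_exchange = TRUE)
  m <- add_reaction(m, "T", c(s_e0 = -1, a_c0 = 1), 0, 1000)
  m <- add_reaction(m, "L1", c(a_c0 = -1, b_c0 = 1), -1000, 1000)
  m <- add_reaction(m, "L2", c(b_c0 = -1, a_c0 = 1), -1000, 1000)
  m <- add_reaction(m, "SINK", c(a_c0 = -1), 0, 1000)
  m <- set_objective(m, "SINK")
  s <- mtf(m, medium = c(s_e0 = 5))
  expect_equal(s$objective, 5, tolerance = 1e-6)
  expect_lt(abs(s$fluxes[["L1"]]), 1e-6)
  expect_lt(abs(s$fluxes[["L2"]]), 1e-6)
})

test_that("FVA brackets the MTF fluxes and reports blocked reactions", {
  d <- rec_complete$draft
  med <- tw$media$m9_glc_anaerobic
  s_mtf <- mtf(d, medium = med)
  fv <- fva(d, medium = med)
  v <- s_mtf$fluxes[fv$id]
  expect_true(all(fv$min <= v + 1e-5))
  expect_true(all(fv$max >= v - 1e-5))
  # oxygen uptake is blocked anaerobically
  o2row <- fv[fv$id == "DIFFo2", ]
  expect_equal(c(o2row$min, o2row$max), c(0, 0), tolerance = 1e-6)
})

test_that("the evidence weight mapping matches its printed defaults", {
  p <- gapfill_params()
  expect_identical(evidence_weight(30, FALSE, p), 100)
  expect_identical(evidence_weight(250, FALSE, p), 0.005)
  expect_equal(evidence_weight(125, FALSE, p), 50.0025)
  # continuity at both thresholds
  expect_equal(evidence_weight(p$l, FALSE, p), p$w_max)
  expect_equal(evidence_weight(p$l - 1e-9, FALSE, p), p$w_max)
  expect_equal(evidence_weight(p$u, FALSE, p), p$w_min)
  expect_equal(evidence_weight(p$u - 1e-6, FALSE, p), p$w_min,
               tolerance = 1e-3)
  # non-increasing over the whole scanned range; draft beats everything
  b <- seq(0, 400, by = 0.5)
  w <- evidence_weight(b, FALSE, p)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(evidence_weight(b, TRUE, p) == p$w_min))
  expect_identical(evidence_weight(NA_real_, FALSE, p), p$w_max)
})

test_that("gap-filling restores growth through the planted single gap", {
  uni <- tw_universal
  res <- weighted_gapfill_lp(
    merge_models(uni, rec_single_gap$draft),
    rec_single_gap$draft$rxns$id, rec_single_gap$evidence, "bio1",
    tw$media$m9_glc)
  expect_equal(res$added, "PGS")
  expect_gt(res$solution$objective, 1e-6)
})

test_that("the high-evidence route wins over the low-evidence route", {
  fx <- make_two_route_model()
  res <- weighted_gapfill_lp(fx$universal, fx$draft_ids, fx$evidence,
                             "bio", fx$medium)
  expect_true(all(fx$high_route %in% res$added))
  expect_false(any(fx$low_route %in% res$added))
})

test_that("a growing draft with maximally penalised alternatives adds nothing", {
  fx <- make_two_route_model()
  # make route A part of the draft: the draft grows, route B stays w_max
  draft_ids <- c(fx$draft_ids, fx$high_route)
  res <- weighted_gapfill_lp(fx$universal, draft_ids, NULL, "bio",
                             fx$medium)
  expect_length(res$added, 0)
})

test_that("the added set is weight-optimal (brute-force subset oracle)", {
  fx <- make_two_route_model()
  p <- gapfill_params()
  cand <- c("RA1", "RA2", "RB1", "RB2")
  b <- c(150, 150, 20, 20)
  w <- evidence_weight(b, FALSE, p)
  res <- weighted_gapfill_lp(fx$universal, fx$draft_ids, fx$evidence,
                             "bio", fx$medium)
  added_w <- sum(w[match(res$added, cand)])
  # enumerate all candidate subsets; none that restores growth is cheaper
  grows <- function(subset) {
    m <- subset_reactions(fx$universal, c(fx$draft_ids, subset))
    s <- fba(m, medium = fx$medium, objective = "bio")
    s$status == "optimal" && s$objective > 1e-6
  }
  for (mask in 0:(2^length(cand) - 1)) {
    subset <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0]
    if (grows(subset)) {
      expect_gte(sum(w[match(subset, cand)]), added_w - 1e-9)
    }
  }
})

test_that("an unreachable objective yields zero flux and no additions", {
  fx <- make_two_route_model()
  crippled <- remove_reactions(fx$universal,
                               c("RA1", "RB1", "RA2", "RB2"))
  res <- weighted_gapfill_lp(crippled, fx$draft_ids, NULL, "bio",
                             fx$medium)
  expect_lt(res$solution$objective, 1e-9)
  expect_length(res$added, 0)
})
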