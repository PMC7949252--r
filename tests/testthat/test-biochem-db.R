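# Database loading, mass/charge balance, universal model construction,
# dead-end pruning, and energy-cycle detection.

test_that("the exchange-format tables round-trip through load_reaction_db", {
  dir <- withr::local_tempdir()
  write_toy_world(tw, dir)
  db <- load_reaction_db(file.path(dir, "reactions.tsv"),
                         file.path(dir, "metabolites.tsv"))
  expect_equal(nrow(db$rxns), nrow(tw$db$rxns))
  expect_equal(nrow(db$mets), nrow(tw$db$mets))
  expect_equal(db$stoich[["HEX1"]], tw$db$stoich[["HEX1"]])
  expect_equal(db$rxns$lb, tw$db$rxns$lb)
})

test_that("an empty reactions table loads without error", {
  dir <- withr::local_tempdir()
  write_toy_world(tw, dir)
  writeLines(paste(c("id", "name", "stoichiometry", "reversibility",
                     "ec", "is_transport", "is_spontaneous"),
                   collapse = "\t"),
             file.path(dir, "empty.tsv"))
  db <- load_reaction_db(file.path(dir, "empty.tsv"),
                         file.path(dir, "metabolites.tsv"))
  expect_equal(nrow(db$rxns), 0)
})

test_that("dangling metabolite references are integrity errors naming the id", {
  dir <- withr::local_tempdir()
  write_toy_world(tw, dir)
  rx <- utils::read.delim(file.path(dir, "reactions.tsv"),
                          colClasses = "character")
  rx$stoichiometry[1] <- "cpdX:-1;g6p_c0:1"
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_reaction_db(file.path(dir, "reactions.tsv"),
                                file.path(dir, "metabolites.tsv")),
               "cpdX")
})

test_that("missing columns give format errors", {
  dir <- withr::local_tempdir()
  writeLines("id\tname", file.path(dir, "bad.tsv"))
  writeLines("id\tname\tformula\tcharge\tcompartment",
             file.path(dir, "mets.tsv"))
  expect_error(load_reaction_db(file.path(dir, "bad.tsv"),
                                file.path(dir, "mets.tsv")),
               "missing columns")
})

test_that("every database reaction is mass and charge balanced", {
  rep <- validate_db_balance(tw$db)
  expect_true(all(rep$status == "balanced"))
})

test_that("a hydrogen-dropped phosphorylation shows charge imbalance -1", {
  db <- tw$db
  sto <- db$stoich[["HEX1"]]
  db$stoich[["HEX1"]] <- sto[names(sto) != "h_c0"]
  r <- check_mass_charge_balance("HEX1", db)
  expect_equal(r$status, "unbalanced")
  expect_equal(unname(r$charge_imbalance), -1)
  expect_equal(unname(r$element_imbalance[["H"]]), -1)
})

test_that("exchanges are rejected and unknown formulas yield status unknown", {
  uni <- tw_universal
  expect_error(check_mass_charge_balance("EX_glc_e0", uni),
               "not balanceable")
  db <- tw$db
  db$mets$formula[db$mets$id == "glc_c0"] <- ""
  r <- check_mass_charge_balance("HEX1", db)
  expect_equal(r$status, "unknown")
  expect_true(is.na(r$balanced))
})

test_that("universal model adds one exchange per extracellular metabolite", {
  n_ex <- sum(tw$db$mets$compartment == "e0")
  expect_equal(nrow(tw_universal$rxns), nrow(tw$db$rxns) + n_ex)
  expect_equal(sum(tw_universal$rxns$is_exchange), n_ex)
  # byte-determinism of construction
  again <- build_universal_model(tw$db)
  expect_identical(tw_universal$rxns, again$rxns)
  expect_identical(tw_universal$stoich, again$stoich)
  # without extracellular metabolites the model equals the database set
  db2 <- tw$db
  keep <- db2$mets$compartment == "c0"
  db2$mets <- db2$mets[keep, ]
  cyto <- names(which(vapply(db2$stoich, function(s)
    all(names(s) %in% db2$mets$id), TRUE)))
  db2$rxns <- db2$rxns[db2$rxns$id %in% cyto, ]
  db2$stoich <- db2$stoich[db2$rxns$id]
  u2 <- build_universal_model(db2)
  expect_equal(sort(u2$rxns$id), sort(db2$rxns$id))
})

test_that("dead-end pruning removes unclosed chains and is idempotent", {
  mets <- data.frame(id = c("a_c0", "b_c0", "x_c0"),
                     name = c("a", "b", "x"), formula = "C",
                     charge = 0L, compartment = "c0",
                     stringsAsFactors = FALSE)
  m <- new_metabolic_model("chain", mets, new_rxn_table(), list())
  m <- add_reaction(m, "R1", c(a_c0 = -1, b_c0 = 1), 0, 1000)
  m <- add_reaction(m, "R2", c(b_c0 = -1, x_c0 = 1), 0, 1000)
  p <- prune_dead_ends(m)
  expect_equal(nrow(p$rxns), 0)   # no source for a, no sink for x
  # pruning never grows the model and is idempotent
  p1 <- prune_dead_ends(tw_universal)
  expect_lte(nrow(p1$rxns), nrow(tw_universal$rxns))
  p2 <- prune_dead_ends(p1)
  expect_identical(p1$rxns$id, p2$rxns$id)
})

test_that("the curated network generates no ATP in a closed system", {
  ec <- detect_energy_cycles(tw_universal, "ATPM")
  expect_lt(abs(ec$objective), 1e-9)
})

test_that("a planted erroneous uniporter creates a detectable energy cycle", {
  cw <- make_corrupted_world(tw)
  uc <- build_universal_model(cw$db)
  ec <- detect_energy_cycles(uc, "ATPM")
  expect_gt(ec$objective, 1)
  expect_true("ACt2bad" %in% ec$cycle_reactions)
  expect_true("ATPS" %in% ec$cycle_reactions)
})

test_that("a missing dissipation reaction is an error", {
  expect_error(detect_energy_cycles(tw_universal, "NOPE"), "absent")
})
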