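# TC-number parsing, transport-reaction classification (keywords and
# stoichiometric fallback), and candidate selection with class fallback.

test_that("TC numbers parse into class and substance", {
  r <- parse_tc_class("ref|3.A.1.2.1| D-ribose ABC transporter",
                      tw$substance_map)
  expect_equal(r$tc_class, 3)
  expect_equal(r$tc_number, "3.A.1.2.1")
  expect_equal(r$substance, "ribose")
  r <- parse_tc_class("ref|2.A.1.1.1| glucose uniporter", tw$substance_map)
  expect_equal(r$tc_class, 2)
  expect_equal(r$substance, "glucose")
  expect_error(parse_tc_class("ref|9.B.1.1.1| weird pump"), "unsupported")
  expect_error(parse_tc_class("no tc number here"), "TC number")
})

test_that("transport reactions classify by name keywords", {
  cands <- list(
    GLCpts = c(4L, "glc"),     # "PTS"
    RIBabc = c(3L, "rib"),     # "ABC"/"ATPase"
    LACt = c(2L, "lac"),       # "symport"/"permease"
    ETOHt = c(2L, "etoh"))
  for (rid in names(cands)) {
    tc <- classify_transport_reaction(rid, tw$db)
    expect_equal(tc$type, as.integer(cands[[rid]][1]), label = rid)
    expect_equal(tc$substance, cands[[rid]][2], label = rid)
  }
  expect_error(classify_transport_reaction("HEX1", tw$db),
               "not a transport")
})

test_that("the stoichiometric fallback recognises ABC, PTS, and symport", {
  db <- tw$db
  add_row <- function(db, id, sto) {
    db$rxns <- rbind(db$rxns, db$rxns[db$rxns$id == "LACt", ])
    db$rxns$id[nrow(db$rxns)] <- id
    db$rxns$name[nrow(db$rxns)] <- "unnamed reaction"
    db$stoich[[id]] <- sto
    db
  }
  db <- add_row(db, "TX1", c(rib_e0 = -1, atp_c0 = -1, h2o_c0 = -1,
                             rib_c0 = 1, adp_c0 = 1, pi_c0 = 1, h_c0 = 1))
  db <- add_row(db, "TX2", c(glc_e0 = -1, pep_c0 = -1, g6p_c0 = 1,
                             pyr_c0 = 1))
  db <- add_row(db, "TX3", c(lac_e0 = -1, h_e0 = -1, lac_c0 = 1, h_c0 = 1))
  expect_equal(classify_transport_reaction("TX1", db)$type, 3L)
  expect_equal(classify_transport_reaction("TX2", db)$type, 4L)
  expect_equal(classify_transport_reaction("TX3", db)$type, 2L)
  expect_equal(classify_transport_reaction("TX1", db)$source, "stoichiometry")
})

test_that("manual overrides win over keywords", {
  ov <- data.frame(reaction_id = "GLCpts", substance = "glc", type = 2L)
  tc <- classify_transport_reaction("GLCpts", tw$db, overrides = ov)
  expect_equal(tc$type, 2L)
  expect_equal(tc$source, "manual")
})

mk_thit <- function(cls, substance, bitscore = 300, coverage = 90) {
  data.frame(tc_class = cls, substance = substance, bitscore = bitscore,
             coverage_pct = coverage, identity_pct = 80,
             stringsAsFactors = FALSE)
}

test_that("candidates are selected by class and substance", {
  sel <- find_transporters(mk_thit(3, "ribose"), tw$substance_map, tw$db)
  expect_equal(as.character(sel), "RIBabc")
  # all selections are transport-flagged reactions
  expect_true(all(sel %in% tw$db$rxns$id[tw$db$rxns$is_transport]))
})

test_that("a missing class falls back to the other transporter types", {
  # class-1 glucose hit: no channel in the database, PTS gets selected
  sel <- find_transporters(mk_thit(1, "glucose"), tw$substance_map, tw$db)
  expect_equal(as.character(sel), "GLCpts")
  # fallback never fires when the detected class has a candidate
  sel2 <- find_transporters(mk_thit(2, "lactate"), tw$substance_map, tw$db)
  expect_equal(as.character(sel2), "LACt")
})

test_that("sub-threshold hits and unknown substances select nothing", {
  sel <- find_transporters(mk_thit(3, "ribose", bitscore = 150),
                           tw$substance_map, tw$db)
  expect_length(sel, 0)
  sel <- find_transporters(mk_thit(2, "unobtainium"), tw$substance_map,
                           tw$db)
  expect_length(sel, 0)
  expect_equal(attr(sel, "unresolved"), "unobtainium")
})

test_that("selection is invariant under hit order", {
  hits <- rbind(mk_thit(3, "ribose"), mk_thit(2, "lactate"),
                mk_thit(4, "glucose"))
  s1 <- find_transporters(hits, tw$substance_map, tw$db)
  s2 <- find_transporters(hits[c(3, 1, 2), ], tw$substance_map, tw$db)
  expect_equal(as.character(s1), as.character(s2))
})
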