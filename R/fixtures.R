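# Deterministic synthetic fixtures: a small but thermodynamically and
# stoichiometrically consistent toy biochemistry (glycolysis-like chain,
# compressed TCA cycle, aerobic respiratory chain, fermentation branches,
# transporters, diffusion compounds, Gram-specific biomass), pathway
# definitions, reference FASTA headers with subunit structure, and
# per-organism homology hit tables with planted ground truth.  Everything
# the rest of the package consumes can be generated from here; no
# downloads are involved.

toy_metabolites <- function() {
  # id base, name, formula (Hill), charge, compartments
  m <- rbind(
    c("glc",   "D-glucose",                 "C6H12O6",        0, "ce"),
    c("g6p",   "D-glucose 6-phosphate",     "C6H11O9P",      -2, "c"),
    c("f6p",   "D-fructose 6-phosphate",    "C6H11O9P",      -2, "c"),
    c("fru",   "D-fructose",                "C6H12O6",        0, "c"),
    c("pep",   "phosphoenolpyruvate",       "C3H2O6P",       -3, "c"),
    c("pyr",   "pyruvate",                  "C3H3O3",        -1, "c"),
    c("lac",   "L-lactate",                 "C3H5O3",        -1, "ce"),
    c("ac",    "acetate",                   "C2H3O2",        -1, "ce"),
    c("actp",  "acetyl phosphate",          "C2H3O5P",       -2, "c"),
    c("etoh",  "ethanol",                   "C2H6O",          0, "ce"),
    c("accoa", "acetyl-CoA",                "C23H34N7O17P3S", -4, "c"),
    c("coa",   "coenzyme A",                "C21H32N7O16P3S", -4, "c"),
    c("atp",   "ATP",                       "C10H12N5O13P3", -4, "c"),
    c("adp",   "ADP",                       "C10H12N5O10P2", -3, "c"),
    c("pi",    "orthophosphate",            "HO4P",          -2, "ce"),
    c("h",     "proton",                    "H",              1, "ce"),
    c("h2o",   "water",                     "H2O",            0, "ce"),
    c("nad",   "NAD+",                      "C21H26N7O14P2", -1, "c"),
    c("nadh",  "NADH",                      "C21H27N7O14P2", -2, "c"),
    c("qn",    "quinone (toy)",             "C9H10O2",        0, "c"),
    c("qh2",   "quinol (toy)",              "C9H12O2",        0, "c"),
    c("mqn",   "menaquinone (toy)",         "C11H8O2",        0, "c"),
    c("mqh2",  "menaquinol (toy)",          "C11H10O2",       0, "c"),
    c("co2",   "carbon dioxide",            "CO2",            0, "ce"),
    c("o2",    "dioxygen",                  "O2",             0, "ce"),
    c("nh3",   "ammonia",                   "H3N",            0, "ce"),
    c("h2",    "dihydrogen",                "H2",             0, "ce"),
    c("rib",   "D-ribose",                  "C5H10O5",        0, "ce"),
    c("r5p",   "ribose 5-phosphate",        "C5H9O8P",       -2, "c"),
    c("srb",   "sorbitol-like polyol",      "C6H14O6",        0, "ce"),
    c("ala",   "L-alanine",                 "C3H7NO2",        0, "ce"),
    c("glu",   "L-glutamate",               "C5H8NO4",       -1, "ce"),
    c("lip",   "palmitate-like lipid",      "C16H31O2",      -1, "c"),
    c("pgly",  "peptidoglycan unit (synthetic)", "C9H16NO10P", -2, "c"),
    c("wta",   "teichoic acid unit (synthetic)", "C12H21O21P3", -6, "c"),
    c("lps",   "lipopolysaccharide unit (synthetic)", "C22H42O14P2", -4, "c"),
    c("hco3",  "bicarbonate",               "CHO3",          -1, "c"),
    c("for",   "formate",                   "CHO2",          -1, "ce"))
  rows <- list()
  for (i in seq_len(nrow(m))) {
    comps <- strsplit(m[i, 5], "")[[1]]
    for (cc in comps) {
      cmp <- if (cc == "c") "c0" else "e0"
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(m[i, 1], "_", cmp), name = m[i, 2], formula = m[i, 3],
        charge = as.integer(m[i, 4]), compartment = cmp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

toy_reactions <- function() {
  sv <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  R <- list()
  add <- function(id, name, sto, rev, ec = "", transport = FALSE,
                  spont = FALSE) {
    R[[id]] <<- list(id = id, name = name, sto = sv(sto), rev = rev,
                     ec = ec, transport = transport, spont = spont)
  }
  # --- central carbon metabolism -------------------------------------
  add("HEX1", "glucokinase",
      c(glc_c0 = -1, atp_c0 = -1, g6p_c0 = 1, adp_c0 = 1, h_c0 = 1),
      ">", "2.7.1.2")
  add("PGI", "glucose-6-phosphate isomerase",
      c(g6p_c0 = -1, f6p_c0 = 1), "=", "5.3.1.9")
  add("GLYC1", "lower glycolysis (compressed)",
      c(g6p_c0 = -1, adp_c0 = -1, pi_c0 = -2, nad_c0 = -2,
        pep_c0 = 2, atp_c0 = 1, nadh_c0 = 2, h2o_c0 = 2, h_c0 = 3),
      ">", "1.2.1.12")
  add("PYK", "pyruvate kinase",
      c(pep_c0 = -1, adp_c0 = -1, h_c0 = -1, pyr_c0 = 1, atp_c0 = 1),
      ">", "2.7.1.40")
  add("PDH", "pyruvate dehydrogenase",
      c(pyr_c0 = -1, coa_c0 = -1, nad_c0 = -1,
        accoa_c0 = 1, co2_c0 = 1, nadh_c0 = 1), ">", "1.2.4.1")
  add("TCA", "citric acid cycle (compressed)",
      c(accoa_c0 = -1, nad_c0 = -3, qn_c0 = -1, adp_c0 = -1, pi_c0 = -1,
        h2o_c0 = -2, coa_c0 = 1, co2_c0 = 2, nadh_c0 = 3, qh2_c0 = 1,
        atp_c0 = 1, h_c0 = 2), ">", "1.3.5.1")
  # --- respiratory chain ---------------------------------------------
  add("NDH1", "NADH dehydrogenase (proton-pumping)",
      c(nadh_c0 = -1, qn_c0 = -1, h_c0 = -5, nad_c0 = 1, qh2_c0 = 1,
        h_e0 = 4), ">", "7.1.1.2")
  add("CYO", "cytochrome oxidase",
      c(qh2_c0 = -2, o2_c0 = -1, h_c0 = -4, qn_c0 = 2, h2o_c0 = 2,
        h_e0 = 4), ">", "7.1.1.3")
  add("NDH2", "NADH:menaquinone oxidoreductase",
      c(nadh_c0 = -1, mqn_c0 = -1, h_c0 = -1, nad_c0 = 1, mqh2_c0 = 1),
      ">", "1.6.5.9")
  add("ATPS", "ATP synthase",
      c(adp_c0 = -1, pi_c0 = -1, h_e0 = -4, atp_c0 = 1, h2o_c0 = 1,
        h_c0 = 3), "=", "7.1.2.2")
  # --- fermentation branches -----------------------------------------
  add("LDH", "L-lactate dehydrogenase",
      c(pyr_c0 = -1, nadh_c0 = -1, h_c0 = -1, lac_c0 = 1, nad_c0 = 1),
      "=", "1.1.1.27")
  add("PTA", "phosphotransacetylase",
      c(accoa_c0 = -1, pi_c0 = -1, actp_c0 = 1, coa_c0 = 1),
      "=", "2.3.1.8")
  add("ACK", "acetate kinase",
      c(actp_c0 = -1, adp_c0 = -1, ac_c0 = 1, atp_c0 = 1), "=", "2.7.2.1")
  add("PFL", "pyruvate formate-lyase",
      c(pyr_c0 = -1, coa_c0 = -1, accoa_c0 = 1, for_c0 = 1),
      ">", "2.3.1.54")
  add("ADHE", "aldehyde-alcohol dehydrogenase (compressed)",
      c(accoa_c0 = -1, nadh_c0 = -2, h_c0 = -2, etoh_c0 = 1, coa_c0 = 1,
        nad_c0 = 2), ">", "1.2.1.10")
  # --- pentose and polyol routes -------------------------------------
  add("RBK", "ribokinase",
      c(rib_c0 = -1, atp_c0 = -1, r5p_c0 = 1, adp_c0 = 1, h_c0 = 1),
      ">", "2.7.1.15")
  add("PPP", "non-oxidative pentose interconversion (compressed)",
      c(r5p_c0 = -6, h2o_c0 = -1, g6p_c0 = 5, pi_c0 = 1), "=", "2.2.1.1")
  add("SBDH", "polyol dehydrogenase",
      c(srb_c0 = -1, nad_c0 = -1, fru_c0 = 1, nadh_c0 = 1, h_c0 = 1),
      ">", "1.1.1.14")
  add("FRK", "fructokinase",
      c(fru_c0 = -1, atp_c0 = -1, f6p_c0 = 1, adp_c0 = 1, h_c0 = 1),
      ">", "2.7.1.4")
  # --- amino acids and biomass components ----------------------------
  add("ALADH", "alanine dehydrogenase",
      c(pyr_c0 = -1, nh3_c0 = -1, nadh_c0 = -1, h_c0 = -2, ala_c0 = 1,
        nad_c0 = 1, h2o_c0 = 1), ">", "1.4.1.1")
  add("GLUS", "glutamate synthesis (compressed)",
      c(pyr_c0 = -2, nh3_c0 = -1, nad_c0 = -1, glu_c0 = 1, co2_c0 = 1,
        nadh_c0 = 1), ">", "1.4.1.13")
  add("FAS", "fatty acid synthesis (compressed)",
      c(accoa_c0 = -8, nadh_c0 = -14, h_c0 = -13, lip_c0 = 1, coa_c0 = 8,
        nad_c0 = 14, h2o_c0 = 6), ">", "2.3.1.85")
  add("PGS", "peptidoglycan unit synthase",
      c(g6p_c0 = -1, ala_c0 = -1, atp_c0 = -1, pgly_c0 = 1, adp_c0 = 1,
        pi_c0 = 1, h_c0 = 1), ">", "6.3.2.8")
  add("WTAS", "teichoic acid unit synthase",
      c(g6p_c0 = -2, atp_c0 = -1, wta_c0 = 1, adp_c0 = 1, h_c0 = 1),
      ">", "2.7.8.33")
  add("LPSS", "lipopolysaccharide unit synthase",
      c(g6p_c0 = -1, lip_c0 = -1, atp_c0 = -1, lps_c0 = 1, adp_c0 = 1),
      ">", "2.4.1.182")
  add("ATPM", "ATP maintenance hydrolysis",
      c(atp_c0 = -1, h2o_c0 = -1, adp_c0 = 1, pi_c0 = 1, h_c0 = 1),
      ">", "3.6.1.3")
  add("CAH", "carbonic anhydride hydration (spontaneous)",
      c(co2_c0 = -1, h2o_c0 = -1, hco3_c0 = 1, h_c0 = 1), "=",
      "4.2.1.1", spont = TRUE)
  # --- transporters ---------------------------------------------------
  add("GLCpts", "D-glucose PTS transporter",
      c(glc_e0 = -1, pep_c0 = -1, g6p_c0 = 1, pyr_c0 = 1), ">",
      "2.7.1.199", transport = TRUE)
  add("LACt", "L-lactate proton symport permease",
      c(lac_e0 = -1, h_e0 = -1, lac_c0 = 1, h_c0 = 1), "=",
      "", transport = TRUE)
  add("ACt", "acetate proton symport permease",
      c(ac_e0 = -1, h_e0 = -1, ac_c0 = 1, h_c0 = 1), "=",
      "", transport = TRUE)
  add("RIBabc", "D-ribose ABC transporter ATPase",
      c(rib_e0 = -1, atp_c0 = -1, h2o_c0 = -1, rib_c0 = 1, adp_c0 = 1,
        pi_c0 = 1, h_c0 = 1), ">", "7.5.2.7", transport = TRUE)
  add("FORt", "formate proton symport permease",
      c(for_e0 = -1, h_e0 = -1, for_c0 = 1, h_c0 = 1), "=",
      "", transport = TRUE)
  add("PIt", "phosphate proton symport permease",
      c(pi_e0 = -1, h_e0 = -1, pi_c0 = 1, h_c0 = 1), "=",
      "", transport = TRUE)
  add("SRBt", "polyol proton symport permease",
      c(srb_e0 = -1, h_e0 = -1, srb_c0 = 1, h_c0 = 1), "=",
      "", transport = TRUE)
  add("ETOHt", "ethanol uniport permease",
      c(etoh_e0 = -1, etoh_c0 = 1), "=", "", transport = TRUE)
  add("ALAt", "L-alanine proton symport permease",
      c(ala_e0 = -1, h_e0 = -1, ala_c0 = 1, h_c0 = 1), ">",
      "", transport = TRUE)
  add("GLUt", "L-glutamate proton symport permease",
      c(glu_e0 = -1, h_e0 = -1, glu_c0 = 1, h_c0 = 1), ">",
      "", transport = TRUE)
  # --- membrane diffusion --------------------------------------------
  for (d in c("o2", "co2", "nh3", "h2o", "h2")) {
    add(paste0("DIFF", d), paste(d, "membrane diffusion"),
        stats::setNames(c(-1, 1), paste0(d, c("_e0", "_c0"))), "=",
        "", transport = TRUE)
  }
  R
}

toy_db_from_tables <- function(mets, rlist, bound = DEFAULT_BOUND) {
  rows <- lapply(rlist, function(r) {
    bnd <- bounds_from_reversibility(r$rev, bound)
    data.frame(id = r$id, name = r$name, lb = bnd[1], ub = bnd[2],
               reversibility = r$rev, ec = r$ec,
               is_transport = r$transport, is_spontaneous = r$spont,
               is_exchange = FALSE, gpr = "", gs_origin = NA_integer_,
               evidence_bitscore = NA_real_, stringsAsFactors = FALSE)
  })
  structure(list(mets = mets, rxns = do.call(rbind, rows),
                 stoich = lapply(rlist, `[[`, "sto"),
                 compartments = c("c0", "e0")),
            class = "reaction_db")
}

toy_pathways <- function() {
  e <- function(rid, key = 0, spont = 0, has_seq = 1, ec = "") {
    data.frame(reaction_id = rid, ec = ec, key = key == 1,
               spontaneous = spont == 1, has_seq = has_seq == 1,
               stringsAsFactors = FALSE)
  }
  list(
    pwy_glyc = list(id = "pwy_glyc", name = "glycolysis (toy)",
      entries = rbind(e("HEX1"), e("PGI"), e("GLYC1"), e("PYK"), e("PDH"))),
    pwy_tca_ox = list(id = "pwy_tca_ox",
      name = "TCA cycle and aerobic respiration (toy)",
      entries = rbind(e("TCA", key = 1), e("PDH", key = 1), e("NDH1"),
                      e("CYO"), e("ATPS"), e("NDH2"))),
    pwy_ferm = list(id = "pwy_ferm", name = "mixed-acid fermentation (toy)",
      entries = rbind(e("LDH"), e("PTA"), e("ACK"), e("ADHE"))),
    pwy_rib = list(id = "pwy_rib", name = "ribose catabolism (toy)",
      entries = rbind(e("RBK", key = 1), e("PPP"),
                      e("RXN-UNKNOWN1", has_seq = 0, ec = "9.9.1.1"))),
    pwy_srb = list(id = "pwy_srb", name = "polyol catabolism (toy)",
      entries = rbind(e("SBDH"), e("FRK"), e("PGI"), e("GLYC1"),
                      e("RXN-UNKNOWN2", has_seq = 0, ec = "9.9.1.2"))),
    pwy_ala = list(id = "pwy_ala",
      name = "alanine and glutamate biosynthesis (toy)",
      entries = rbind(e("ALADH"), e("GLUS"), e("CAH", spont = 1))))
}

toy_biomass_templates <- function() {
  shared <- c(ala_c0 = 0.5, glu_c0 = 0.3, g6p_c0 = 0.2, r5p_c0 = 0.1,
              lip_c0 = 0.1)
  list(
    negative = list(components = c(shared, pgly_c0 = 0.15, lps_c0 = 0.05),
                    energy_atp = 40),
    positive = list(components = c(shared, pgly_c0 = 0.25, wta_c0 = 0.05),
                    energy_atp = 40))
}

toy_substance_map <- function() {
  data.frame(
    name = c("glucose", "ribose", "sorbitol", "lactate", "acetate",
             "ethanol", "formate", "alanine", "glutamate"),
    synonyms = c("d-glucose;dextrose", "d-ribose", "srbX;d-sorbitol",
                 "l-lactate", "", "", "", "l-alanine", "l-glutamate"),
    metabolite_id = c("glc", "rib", "srb", "lac", "ac", "etoh", "for",
                      "ala", "glu"),
    exchange_id = paste0("EX_", c("glc", "rib", "srb", "lac", "ac",
                                  "etoh", "for", "ala", "glu"), "_e0"),
    stringsAsFactors = FALSE)
}

toy_media <- function() {
  m9_base <- c(nh3_e0 = 100, pi_e0 = 100, h2o_e0 = 1000, h_e0 = 100)
  list(complete = c("*" = 100),
       m9_glc = c(glc_e0 = 10, o2_e0 = 20, m9_base),
       m9_glc_anaerobic = c(glc_e0 = 10, m9_base))
}

toy_ref_headers <- function() {
  list(
    ATPS = c(paste0("ATPS_ref", 1:6, " ATP synthase subunit alpha"),
             paste0("ATPS_ref", 7:12, " ATP synthase subunit beta"),
             paste0("ATPS_ref", 13:18, " ATP synthase subunit gamma")),
    PGS = c(paste0("PGS_ref", 1:5, " peptidoglycan unit synthase subunit 1"),
            paste0("PGS_ref", 6:10, " peptidoglycan unit synthase subunit 2")))
}

#' Generate the toy world
#'
#' Builds the complete synthetic study system: the reaction/metabolite
#' database, pathway definitions, biomass templates, substance map,
#' growth media, reference FASTA headers for the two protein complexes,
#' and their subunit catalogs.  Output is fully deterministic: equal
#' seeds give identical worlds (the world itself carries no sampling;
#' the seed is recorded and propagated to organism generation).
#'
#' @param seed integer seed recorded in the world.
#' @return A list of class \code{toy_world} with elements \code{db},
#'   \code{pathway_db}, \code{biomass_templates}, \code{substance_map},
#'   \code{media}, \code{ref_headers}, \code{catalogs},
#'   \code{substances}, \code{seed}.
#' @export
make_toy_world <- function(seed = 1L) {
  db <- toy_db_from_tables(toy_metabolites(), toy_reactions())
  headers <- toy_ref_headers()
  catalogs <- lapply(names(headers), function(rid)
    parse_subunits(headers[[rid]], rid))
  names(catalogs) <- names(headers)
  structure(list(db = db,
                 pathway_db = toy_pathways(),
                 biomass_templates = toy_biomass_templates(),
                 substance_map = toy_substance_map(),
                 media = toy_media(),
                 ref_headers = headers,
                 catalogs = catalogs,
                 substances = toy_substance_map()$name,
                 seed = as.integer(seed)),
            class = "toy_world")
}

#' Corrupt the toy world with a planted energy-generating cycle
#'
#' Adds an erroneous acetate uniport reaction to the database.  Together
#' with the correct acetate/proton symporter and the ATP synthase this
#' closes a proton-motive loop that generates ATP without any nutrient
#' input -- the class of thermodynamically infeasible cycle that database
#' curation must detect and remove.
#'
#' @param world a \code{toy_world}.
#' @return The corrupted world; the planted reaction id is
#'   \code{"ACt2bad"}.
#' @export
make_corrupted_world <- function(world) {
  db <- world$db
  db$rxns <- rbind(db$rxns, data.frame(
    id = "ACt2bad", name = "acetate uniport (erroneous)",
    lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND, reversibility = "=",
    ec = "", is_transport = TRUE, is_spontaneous = FALSE,
    is_exchange = FALSE, gpr = "", gs_origin = NA_integer_,
    evidence_bitscore = NA_real_, stringsAsFactors = FALSE))
  db$stoich[["ACt2bad"]] <- c(ac_e0 = -1, ac_c0 = 1)
  world$db <- db
  world
}

# Hit-table row helper.
toy_hit <- function(gene, rxn, bitscore, coverage, identity = 80,
                    subunit = "") {
  data.frame(ref_seq_id = gene, reaction_ids = rxn, bitscore = bitscore,
             coverage_pct = coverage, identity_pct = identity,
             subunit_label = subunit, stringsAsFactors = FALSE)
}

# The full strong-evidence hit set of the "complete" organism.
toy_hits_complete <- function(rng) {
  strong <- function(gene, rxn, subunit = "") {
    toy_hit(gene, rxn, bitscore = round(250 + rng() * 100, 1),
            coverage = round(80 + rng() * 15, 1), subunit = subunit)
  }
  weak <- function(gene, rxn, b) {
    toy_hit(gene, rxn, bitscore = b, coverage = round(78 + rng() * 10, 1))
  }
  single <- c("HEX1", "PGI", "GLYC1", "PYK", "PDH", "PFL", "TCA", "NDH1",
              "PTA", "ACK", "RBK", "PPP", "ALADH", "GLUS", "FAS",
              "LPSS", "WTAS", "GLCpts", "LACt", "ACt", "RIBabc", "PIt",
              "FORt", "ETOHt", "ALAt", "GLUt")
  rows <- lapply(single, function(r) strong(paste0("g", r), r))
  rows <- c(rows, list(
    strong("gLDH1", "LDH"), strong("gLDH2", "LDH"),
    strong("atpA", "ATPS", subunit = "subunit 1"),
    strong("atpB", "ATPS", subunit = "subunit 2"),
    strong("gPGS1", "PGS", subunit = "subunit 1"),
    strong("gPGS2", "PGS", subunit = "subunit 2"),
    weak("gSBDH", "SBDH", 120), weak("gFRK", "FRK", 120),
    weak("gSRBt", "SRBt", 130)))
  do.call(rbind, rows)
}

#' Generate a toy organism with planted ground truth
#'
#' Profiles:
#' \describe{
#'   \item{complete}{strong evidence for the full aerobic heterotroph;
#'     its draft grows on glucose minimal medium without gap-filling.}
#'   \item{single_gap}{as complete, but the peptidoglycan synthase
#'     evidence falls just below the match cutoff (bitscore 150), so the
#'     draft cannot grow; gap-filling step 1 must add exactly PGS.}
#'   \item{fermenter}{anaerobe: no respiratory chain evidence; grows by
#'     mixed-acid fermentation (Gram-positive template).}
#'   \item{auxotroph}{alanine synthesis only core-supported (bitscore
#'     120, resolvable in step 2); glutamate synthesis entirely absent
#'     (auxotrophy remains); both amino acids importable.}
#'   \item{fragmented}{the complete hit table with each row dropped
#'     independently with probability \code{p} (genome incompleteness).}
#' }
#'
#' @param world a \code{toy_world}.
#' @param profile one of the profiles above.
#' @param seed integer seed driving all randomness (bitscore jitter,
#'   hit dropout).
#' @param p dropout probability for \code{profile = "fragmented"}.
#' @return A list of class \code{toy_organism}: \code{id},
#'   \code{profile}, \code{gram}, \code{medium} (gap-fill medium name),
#'   \code{hits}, and the planted \code{truth} list.
#' @export
make_toy_organism <- function(world, profile = "complete", seed = 1L,
                              p = 0.3) {
  profiles <- c("complete", "single_gap", "fermenter", "auxotroph",
                "fragmented")
  if (!profile %in% profiles) {
    stop("unknown profile '", profile, "' (use: ",
         paste(profiles, collapse = ", "), ")", call. = FALSE)
  }
  rng <- function() stats::runif(1)
  set.seed(seed)
  hits <- toy_hits_complete(rng)
  gram <- "negative"
  medium <- "m9_glc"
  truth <- list()
  if (profile == "complete") {
    truth <- list(
      present_pathways = c("pwy_ala", "pwy_glyc", "pwy_rib", "pwy_tca_ox"),
      absent_pathways = c("pwy_ferm", "pwy_srb"),
      origin_examples = c(GLCpts = 0L, CAH = 0L, bio1 = 6L, ATPM = 6L,
                          EX_glc_e0 = 7L, DIFFo2 = 8L, CYO = 9L,
                          NDH2 = 9L),
      draft_absent = c("ADHE", "SBDH", "FRK", "SRBt"),
      essential_genes = c("gALADH", "gFAS", "gGLCpts", "gGLUS",
                          "gGLYC1", "gLPSS", "gPGS1", "gPGS2",
                          "gPIt", "gPPP", "gPYK"),
      nonessential_genes = c("atpA", "atpB", "gHEX1", "gLDH1", "gLDH2",
                             "gPDH", "gPFL", "gTCA"),
      carbon_sources_positive = c("glucose", "ribose"),
      carbon_sources_negative = c("sorbitol"),
      step3_added = c("SBDH", "FRK", "SRBt"),
      anaerobic_product = "EX_lac_e0",
      aerobic_nonproduct = "EX_lac_e0")
  } else if (profile == "single_gap") {
    near <- hits$reaction_ids == "PGS"
    hits$bitscore[near] <- 150
    truth <- list(gap_reaction = "PGS", step1_added = "PGS")
  } else if (profile == "fermenter") {
    # no respiration, but the F1F0 ATPase is retained: fermenting
    # bacteria use it in reverse for proton extrusion
    drop <- c("TCA", "NDH1", "LPSS", "SBDH", "FRK", "SRBt")
    hits <- hits[!hits$reaction_ids %in% drop, , drop = FALSE]
    hits <- rbind(hits, toy_hit("gADHE", "ADHE",
                                round(250 + stats::runif(1) * 100, 1),
                                round(80 + stats::runif(1) * 15, 1)))
    gram <- "positive"
    medium <- "m9_glc_anaerobic"
    truth <- list(
      present_pathways_include = c("pwy_ferm", "pwy_glyc"),
      absent_pathways_include = c("pwy_tca_ox"),
      fermentation_products_nonempty = TRUE)
  } else if (profile == "auxotroph") {
    hits$bitscore[hits$reaction_ids == "ALADH"] <- 120
    hits <- hits[hits$reaction_ids != "GLUS", , drop = FALSE]
    medium <- "complete"
    truth <- list(step2_added = "ALADH",
                  unresolved_component = "glu_c0")
  } else if (profile == "fragmented") {
    keep <- stats::runif(nrow(hits)) >= p
    hits <- hits[keep, , drop = FALSE]
    truth <- list(p = p)
  }
  rownames(hits) <- NULL
  structure(list(id = paste0("org_", profile, "_s", seed),
                 profile = profile, gram = gram, medium = medium,
                 hits = hits, truth = truth, seed = as.integer(seed)),
            class = "toy_organism")
}

#' Run the full reconstruction pipeline on toy-world inputs
#'
#' Convenience driver used by tests and the command-line interface:
#' evidence table, complex calls, pathway calls, transporter selection,
#' draft assembly.
#'
#' @param world a \code{toy_world}.
#' @param organism a \code{toy_organism}.
#' @param thresholds a \code{\link{match_thresholds}} object.
#' @return List with \code{evidence}, \code{complex_calls},
#'   \code{pathway_calls}, \code{transporters}, \code{draft}.
#' @export
reconstruct_draft <- function(world, organism,
                              thresholds = match_thresholds()) {
  evidence <- build_evidence_table(organism$hits, thresholds)
  complex_calls <- predict_complexes(organism$hits, world$catalogs,
                                     thresholds)
  pathway_calls <- predict_pathways(world$pathway_db, evidence,
                                    complex_calls)
  # Transporter evidence: transport-reaction hits re-expressed as
  # TC-style hits via the known class/substance of each toy transporter.
  tmap <- list(GLCpts = c(4, "glucose"), LACt = c(2, "lactate"),
               ACt = c(2, "acetate"), RIBabc = c(3, "ribose"),
               PIt = c(2, "phosphate"), SRBt = c(2, "sorbitol"),
               FORt = c(2, "formate"),
               ETOHt = c(2, "ethanol"), ALAt = c(2, "alanine"),
               GLUt = c(2, "glutamate"))
  rows <- list()
  for (i in seq_len(nrow(organism$hits))) {
    rid <- organism$hits$reaction_ids[i]
    if (rid %in% names(tmap)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tc_class = as.integer(tmap[[rid]][1]),
        substance = tmap[[rid]][2],
        bitscore = organism$hits$bitscore[i],
        coverage_pct = organism$hits$coverage_pct[i],
        identity_pct = organism$hits$identity_pct[i],
        stringsAsFactors = FALSE)
    }
  }
  thits <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(tc_class = integer(), substance = character(),
               bitscore = numeric(), coverage_pct = numeric(),
               identity_pct = numeric())
  transporters <- find_transporters(thits, world$substance_map, world$db,
                                    thresholds)
  draft <- assemble_draft(pathway_calls, evidence, transporters,
                          world$db, gram = organism$gram,
                          biomass_templates = world$biomass_templates,
                          complex_calls = complex_calls,
                          model_id = organism$id)
  list(evidence = evidence, complex_calls = complex_calls,
       pathway_calls = pathway_calls, transporters = transporters,
       draft = draft)
}

#' Minimal planted two-route gap fixture
#'
#' A tiny universal network in which the biomass precursor can be made
#' through two alternative routes whose supporting evidence differs
#' (default bitscores 150 vs 20), while the draft contains neither.  Used
#' to demonstrate that the evidence-weighted gap-filler prefers the
#' high-evidence route.
#'
#' @param b_high,b_low bitscores of the two routes.
#' @return List with \code{universal} (model incl. biomass objective
#'   \code{bio}), \code{draft_ids}, \code{evidence}, \code{medium},
#'   \code{high_route}, \code{low_route}.
#' @export
make_two_route_model <- function(b_high = 150, b_low = 20) {
  mets <- data.frame(
    id = c("s_e0", "s_c0", "m1_c0", "m2_c0", "x_c0"),
    name = c("substrate (ext)", "substrate", "intermediate A",
             "intermediate B", "precursor"),
    formula = c("C6H12O6", "C6H12O6", "C6H12O6", "C6H12O6", "C6H12O6"),
    charge = 0L,
    compartment = c("e0", "c0", "c0", "c0", "c0"),
    stringsAsFactors = FALSE)
  rxns <- new_rxn_table()
  model <- new_metabolic_model("two_route", mets, rxns, list())
  model <- add_reaction(model, "EX_s_e0", c(s_e0 = -1), -10, 1000,
                        is_exchange = TRUE)
  model <- add_reaction(model, "St", c(s_e0 = -1, s_c0 = 1), 0, 1000,
                        is_transport = TRUE)
  model <- add_reaction(model, "RA1", c(s_c0 = -1, m1_c0 = 1), 0, 1000)
  model <- add_reaction(model, "RA2", c(m1_c0 = -1, x_c0 = 1), 0, 1000)
  model <- add_reaction(model, "RB1", c(s_c0 = -1, m2_c0 = 1), 0, 1000)
  model <- add_reaction(model, "RB2", c(m2_c0 = -1, x_c0 = 1), 0, 1000)
  model <- add_reaction(model, "bio", c(x_c0 = -1), 0, 1000)
  model <- set_objective(model, "bio")
  hits <- rbind(
    toy_hit("gA1", "RA1", b_high, 85), toy_hit("gA2", "RA2", b_high, 85),
    toy_hit("gB1", "RB1", b_low, 85), toy_hit("gB2", "RB2", b_low, 85))
  list(universal = model,
       draft_ids = c("EX_s_e0", "St", "bio"),
       evidence = build_evidence_table(hits),
       medium = c(s_e0 = 10),
       high_route = c("RA1", "RA2"),
       low_route = c("RB1", "RB2"))
}

#' Write the toy world to disk in the package's exchange formats
#'
#' Emits \code{reactions.tsv}, \code{metabolites.tsv},
#' \code{pathways.tsv}, \code{biomass_templates.tsv},
#' \code{substance_map.tsv}, \code{media/<name>.csv} and
#' \code{seq/<reaction>.fasta} under \code{dir}.
#'
#' @param world a \code{toy_world}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_toy_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- world$db
  rx <- data.frame(id = db$rxns$id, name = db$rxns$name,
                   stoichiometry = vapply(db$stoich[db$rxns$id],
                                          format_stoich_string, ""),
                   reversibility = db$rxns$reversibility, ec = db$rxns$ec,
                   is_transport = as.integer(db$rxns$is_transport),
                   is_spontaneous = as.integer(db$rxns$is_spontaneous),
                   stringsAsFactors = FALSE)
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(db$mets, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pw <- do.call(rbind, lapply(world$pathway_db, function(p)
    data.frame(pathway_id = p$id, name = p$name,
               reaction_id = p$entries$reaction_id, ec = p$entries$ec,
               key = as.integer(p$entries$key),
               spontaneous = as.integer(p$entries$spontaneous),
               has_seq = as.integer(p$entries$has_seq),
               stringsAsFactors = FALSE)))
  utils::write.table(pw, file.path(dir, "pathways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bt <- do.call(rbind, lapply(names(world$biomass_templates), function(g) {
    tpl <- world$biomass_templates[[g]]
    rbind(data.frame(gram = g, metabolite_id = names(tpl$components),
                     coefficient = unname(tpl$components)),
          data.frame(gram = g, metabolite_id = "ATP_ENERGY",
                     coefficient = tpl$energy_atp))
  }))
  utils::write.table(bt, file.path(dir, "biomass_templates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$substance_map,
                     file.path(dir, "substance_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "media"), showWarnings = FALSE)
  for (nm in names(world$media)) {
    write_medium(world$media[[nm]], file.path(dir, "media",
                                              paste0(nm, ".csv")))
  }
  dir.create(file.path(dir, "seq"), showWarnings = FALSE)
  for (rid in names(world$ref_headers)) {
    writeLines(paste0(">", world$ref_headers[[rid]]),
               file.path(dir, "seq", paste0(rid, ".fasta")))
  }
  invisible(dir)
}

#' Write a hit table in the native TSV dialect
#' @param hits hit data frame.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
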