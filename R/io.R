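# Serialisation: growth-medium CSV, SBML Level 3 export/import (with
# flux bounds, objective, and provenance annotations), and loading of a
# data directory holding the exchange-format tables.

#' Read a growth medium CSV
#'
#' Columns: \code{compound_id} (extracellular metabolite id, or
#' \code{"*"} for a complete medium), \code{name}, \code{maxFlux}
#' (maximal uptake rate, mmol/gDW/h).
#'
#' @param path CSV path.
#' @return Named numeric uptake vector.
#' @export
read_medium <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "maxFlux")
  if (!all(need %in% names(raw))) {
    stop("medium file missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(raw$maxFlux), raw$compound_id)
}

#' Write a growth medium CSV
#' @param medium named numeric uptake vector.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_medium <- function(medium, path) {
  utils::write.csv(data.frame(compound_id = names(medium),
                              name = names(medium),
                              maxFlux = unname(medium)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_attr <- function(x) sprintf("%.12g", x)

#' Export a model as SBML Level 3
#'
#' Writes SBML Level 3 Version 1 with flux-bound parameters, species
#' charge/formula attributes, an active maximisation objective, and the
#' package's provenance fields (gs_origin, evidence_bitscore, gpr, flags)
#' in each reaction's notes.  Serialisation is fully deterministic:
#' identical models produce byte-identical files.
#'
#' @param model a \code{metabolic_model} with an objective.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
export_sbml <- function(model, path) {
  if (is.na(model$objective)) {
    stop("model has no objective reaction; refusing to export", call. = FALSE)
  }
  L <- character()
  p <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  p("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  p("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
    "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
    "level=\"3\" version=\"1\" fbc:required=\"false\">")
  p("  <model id=\"", xml_escape(model$id), "\" fbc:strict=\"true\">")
  p("    <listOfCompartments>")
  for (cmp in sort(unique(model$mets$compartment))) {
    p("      <compartment id=\"", cmp, "\" constant=\"true\"/>")
  }
  p("    </listOfCompartments>")
  p("    <listOfSpecies>")
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    p("      <species id=\"M_", m$id, "\" name=\"", xml_escape(m$name),
      "\" compartment=\"", m$compartment,
      "\" constant=\"false\" boundaryCondition=\"false\" ",
      "hasOnlySubstanceUnits=\"false\" fbc:charge=\"", m$charge,
      "\" fbc:chemicalFormula=\"", m$formula, "\"/>")
  }
  p("    </listOfSpecies>")
  p("    <listOfParameters>")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    p("      <parameter id=\"P_lb_", r$id, "\" value=\"", num_attr(r$lb),
      "\" constant=\"true\"/>")
    p("      <parameter id=\"P_ub_", r$id, "\" value=\"", num_attr(r$ub),
      "\" constant=\"true\"/>")
  }
  p("    </listOfParameters>")
  p("    <listOfReactions>")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    p("      <reaction id=\"R_", r$id, "\" name=\"", xml_escape(r$name),
      "\" reversible=\"", if (r$lb < 0) "true" else "false",
      "\" fast=\"false\" fbc:lowerFluxBound=\"P_lb_", r$id,
      "\" fbc:upperFluxBound=\"P_ub_", r$id, "\">")
    p("        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">")
    p("          <p>gs_origin: ",
      if (is.na(r$gs_origin)) "NA" else r$gs_origin, "</p>")
    p("          <p>evidence_bitscore: ",
      if (is.na(r$evidence_bitscore)) "NA" else num_attr(r$evidence_bitscore),
      "</p>")
    p("          <p>gpr: ", xml_escape(r$gpr), "</p>")
    p("          <p>ec: ", xml_escape(r$ec), "</p>")
    p("          <p>flags: ", as.integer(r$is_transport),
      as.integer(r$is_spontaneous), as.integer(r$is_exchange), "</p>")
    p("        </body></notes>")
    sto <- model$stoich[[r$id]]
    reac <- sto[sto < 0]
    prod <- sto[sto > 0]
    if (length(reac) > 0) {
      p("        <listOfReactants>")
      for (mid in names(reac)) {
        p("          <speciesReference species=\"M_", mid,
          "\" stoichiometry=\"", num_attr(-reac[[mid]]),
          "\" constant=\"true\"/>")
      }
      p("        </listOfReactants>")
    }
    if (length(prod) > 0) {
      p("        <listOfProducts>")
      for (mid in names(prod)) {
        p("          <speciesReference species=\"M_", mid,
          "\" stoichiometry=\"", num_attr(prod[[mid]]),
          "\" constant=\"true\"/>")
      }
      p("        </listOfProducts>")
    }
    p("      </reaction>")
  }
  p("    </listOfReactions>")
  p("    <fbc:listOfObjectives fbc:activeObjective=\"obj\">")
  p("      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">")
  p("        <fbc:listOfFluxObjectives>")
  p("          <fbc:fluxObjective fbc:reaction=\"R_", model$objective,
    "\" fbc:coefficient=\"1\"/>")
  p("        </fbc:listOfFluxObjectives>")
  p("      </fbc:objective>")
  p("    </fbc:listOfObjectives>")
  p("  </model>")
  p("</sbml>")
  writeLines(unlist(L), path)
  invisible(path)
}

# notes are a list of "<key>: <value>" paragraph texts
note_field <- function(notes, key) {
  hit <- notes[startsWith(notes, paste0(key, ": "))]
  if (length(hit) == 0) return(NA_character_)
  sub(paste0(key, ": "), "", hit[1], fixed = TRUE)
}

#' Import a model from SBML written by \code{\link{export_sbml}}
#'
#' @param path SBML file path.
#' @return A \code{metabolic_model}; export-import round trips are
#'   exact (ids, stoichiometry, bounds, GPR, annotations).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp, "id")),
    name = xml2::xml_attr(sp, "name"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = as.integer(xml2::xml_attr(sp, "charge")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rows <- vector("list", length(rx))
  stoich <- list()
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    rid <- sub("^R_", "", xml2::xml_attr(node, "id"))
    notes <- xml2::xml_text(
      xml2::xml_find_all(node, ".//s:notes//x:p",
                         c(ns, x = "http://www.w3.org/1999/xhtml")))
    flags <- note_field(notes, "flags")
    gs <- note_field(notes, "gs_origin")
    bs <- note_field(notes, "evidence_bitscore")
    lb <- pval[[paste0("P_lb_", rid)]]
    ub <- pval[[paste0("P_ub_", rid)]]
    reac <- xml2::xml_find_all(node, ".//s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, ".//s:listOfProducts/s:speciesReference", ns)
    sto <- c(stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                             sub("^M_", "", xml2::xml_attr(reac, "species"))),
             stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                             sub("^M_", "", xml2::xml_attr(prod, "species"))))
    stoich[[rid]] <- sto
    rows[[i]] <- data.frame(
      id = rid, name = xml2::xml_attr(node, "name"), lb = lb, ub = ub,
      reversibility = if (lb < 0 && ub > 0) "=" else if (ub <= 0) "<" else ">",
      ec = note_field(notes, "ec"),
      is_transport = substr(flags, 1, 1) == "1",
      is_spontaneous = substr(flags, 2, 2) == "1",
      is_exchange = substr(flags, 3, 3) == "1",
      gpr = note_field(notes, "gpr"),
      gs_origin = if (gs == "NA") NA_integer_ else as.integer(gs),
      evidence_bitscore = if (bs == "NA") NA_real_ else as.numeric(bs),
      stringsAsFactors = FALSE)
  }
  rxns <- if (length(rows) > 0) do.call(rbind, rows) else new_rxn_table()
  rxns$ec[is.na(rxns$ec)] <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  obj <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns), "reaction")
  new_metabolic_model(xml2::xml_attr(mdl, "id"), mets, rxns, stoich,
                      objective = sub("^R_", "", obj))
}

#' Load a data directory in the package's exchange formats
#'
#' Reads the layout written by \code{\link{write_toy_world}}:
#' \code{reactions.tsv}, \code{metabolites.tsv}, \code{pathways.tsv},
#' \code{biomass_templates.tsv}, \code{substance_map.tsv},
#' \code{media/*.csv}, and reference FASTA headers under \code{seq/}.
#'
#' @param dir directory path.
#' @return A list with the same shape as \code{\link{make_toy_world}}.
#' @export
load_data_dir <- function(dir) {
  db <- load_reaction_db(file.path(dir, "reactions.tsv"),
                         file.path(dir, "metabolites.tsv"))
  pathway_db <- load_pathway_db(file.path(dir, "pathways.tsv"))
  templates <- load_biomass_templates(file.path(dir, "biomass_templates.tsv"))
  smap <- load_substance_map(file.path(dir, "substance_map.tsv"))
  media <- list()
  mdir <- file.path(dir, "media")
  if (dir.exists(mdir)) {
    for (f in sort(list.files(mdir, pattern = "\\.csv$"))) {
      media[[sub("\\.csv$", "", f)]] <- read_medium(file.path(mdir, f))
    }
  }
  headers <- list()
  sdir <- file.path(dir, "seq")
  if (dir.exists(sdir)) {
    for (f in sort(list.files(sdir, pattern = "\\.fasta$"))) {
      rid <- sub("\\.fasta$", "", f)
      lines <- readLines(file.path(sdir, f))
      headers[[rid]] <- sub("^>", "", lines[startsWith(lines, ">")])
    }
  }
  catalogs <- lapply(names(headers), function(rid)
    parse_subunits(headers[[rid]], rid))
  names(catalogs) <- names(headers)
  list(db = db, pathway_db = pathway_db, biomass_templates = templates,
       substance_map = smap, media = media, ref_headers = headers,
       catalogs = catalogs, substances = smap$name)
}
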