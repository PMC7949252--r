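# Transporter prediction: TC-number parsing from reference headers,
# transporter-type classification of database transport reactions, and
# selection of candidate transport reactions by type and substance.

TC_CLASS_NAMES <- c("1" = "channel/pore",
                    "2" = "electrochemical potential-driven",
                    "3" = "primary active",
                    "4" = "group translocator")

normalise_substance <- function(x) {
  x <- tolower(trimws(x))
  gsub("^[dl]-", "", x)
}

#' Parse TC number, class, and substance from a reference FASTA header
#'
#' Expects a TC number token (e.g. \code{"3.A.1.2.1"}, typically between
#' pipes) and a trailing substance annotation.  Supported transporter
#' classes: 1 channels and pores, 2 electrochemical potential-driven
#' transporters, 3 primary active transporters, 4 group translocators.
#'
#' @param fasta_header header line (with or without leading \code{">"}).
#' @param substance_map optional substance table (see
#'   \code{\link{load_substance_map}}); when given, the substance is
#'   resolved against its names and synonyms.
#' @return List with \code{tc_number}, \code{tc_class} (integer),
#'   \code{substance} (normalised name, or NA when unresolvable).
#' @export
parse_tc_class <- function(fasta_header, substance_map = NULL) {
  h <- sub("^>", "", fasta_header)
  m <- regmatches(h, regexpr("[0-9]+\\.[A-Za-z]+\\.[0-9]+\\.[0-9]+\\.[0-9]+", h))
  if (length(m) == 0) stop("no TC number token in header: ", h, call. = FALSE)
  tc <- m[1]
  cls <- as.integer(sub("\\..*$", "", tc))
  if (!cls %in% 1:4) {
    stop("unsupported transporter class ", cls, " (TC ", tc, ")", call. = FALSE)
  }
  # Substance: annotation text after the TC token.
  rest <- sub(paste0(".*", gsub("\\.", "\\\\.", tc), "\\|?"), "", h)
  rest <- normalise_substance(gsub("\\b(abc|pts|transporter|transport|uniporter|symporter|antiporter|permease|channel|porter)\\b", "", tolower(rest)))
  rest <- trimws(gsub("\\s+", " ", rest))
  substance <- if (is.null(substance_map)) {
    if (nzchar(rest)) rest else NA_character_
  } else {
    resolve_substance(rest, substance_map)
  }
  list(tc_number = tc, tc_class = cls, substance = substance)
}

#' Load the substance map
#'
#' TSV with columns \code{name}, \code{synonyms} (semicolon-separated,
#' may be empty), \code{metabolite_id} (cytosolic metabolite id base) and
#' \code{exchange_id}.
#'
#' @param path path to the TSV file.
#' @return Data frame with an attached lookup environment.
#' @export
load_substance_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "synonyms", "metabolite_id", "exchange_id")
  if (!all(need %in% names(map))) {
    stop("substance map missing columns: ",
         paste(setdiff(need, names(map)), collapse = ", "), call. = FALSE)
  }
  map
}

# Resolve free-text substance against the map (exact normalised name or
# synonym; no fuzzy matching).  Returns the canonical name or NA.
resolve_substance <- function(text, substance_map) {
  if (is.null(text) || !nzchar(text)) return(NA_character_)
  t <- normalise_substance(text)
  for (i in seq_len(nrow(substance_map))) {
    cand <- c(substance_map$name[i],
              strsplit(substance_map$synonyms[i], ";", fixed = TRUE)[[1]])
    cand <- normalise_substance(cand[nzchar(cand)])
    if (t %in% cand || any(vapply(cand, function(cn)
      grepl(paste0("\\b", cn, "\\b"), t), TRUE))) {
      return(substance_map$name[i])
    }
  }
  NA_character_
}

met_base_name <- function(met_id) sub("_(c0|e0)$", "", met_id)
met_compartment <- function(met_id) sub("^.*_(c0|e0)$", "\\1", met_id)

#' Classify a transport reaction by type and transported substance
#'
#' Type from reaction-name keywords (1: channel/pore; 2: uniport/
#' symport/antiport/permease/gradient; 3: ABC/ATPase/ATP; 4: PTS); when
#' no keyword matches, a stoichiometric fallback is used: ATP hydrolysis
#' coupling implies type 3, PEP-to-pyruvate coupling type 4, and proton
#' or sodium counter-movement type 2.  The transported substance is the
#' metabolite appearing on both sides of the reaction in different
#' compartments (currency metabolites excluded).  A manual override
#' table, when provided, wins over both.
#'
#' @param reaction_id a reaction with the transport flag set.
#' @param db \code{reaction_db} or \code{metabolic_model} containing it.
#' @param overrides optional data frame (reaction_id, substance, type).
#' @return A \code{transport_candidate}: list with \code{reaction_id},
#'   \code{type} (integer 1-4 or NA), \code{substance} (metabolite base
#'   name or NA), \code{source} ("keyword", "stoichiometry" or "manual").
#' @export
classify_transport_reaction <- function(reaction_id, db, overrides = NULL) {
  row <- db$rxns[db$rxns$id == reaction_id, ]
  if (nrow(row) == 0) stop("unknown reaction: ", reaction_id, call. = FALSE)
  if (!isTRUE(row$is_transport)) {
    stop("not a transport reaction: ", reaction_id, call. = FALSE)
  }
  if (!is.null(overrides)) {
    k <- match(reaction_id, overrides$reaction_id)
    if (!is.na(k)) {
      return(structure(list(reaction_id = reaction_id,
                            type = as.integer(overrides$type[k]),
                            substance = overrides$substance[k],
                            source = "manual"),
                       class = "transport_candidate"))
    }
  }
  sto <- db$stoich[[reaction_id]]
  name <- tolower(row$name)
  type <- NA_integer_
  source <- "keyword"
  if (grepl("\\b(channel|pore)\\b", name)) type <- 1L
  else if (grepl("\\b(uniport\\w*|symport\\w*|antiport\\w*|permease|gradient)\\b", name)) type <- 2L
  else if (grepl("\\b(abc|atpase|atp)\\b", name)) type <- 3L
  else if (grepl("\\bpts\\b", name)) type <- 4L
  if (is.na(type)) {
    source <- "stoichiometry"
    base <- met_base_name(names(sto))
    consumed <- names(sto)[sto < 0]
    produced <- names(sto)[sto > 0]
    if ("atp_c0" %in% consumed && "adp_c0" %in% produced) type <- 3L
    else if ("pep_c0" %in% consumed && "pyr_c0" %in% produced) type <- 4L
    else if (any(base[match(consumed, names(sto))] %in% c("h", "na")) &&
             any(base[match(produced, names(sto))] %in% c("h", "na"))) type <- 2L
  }
  # Transported substance: base name present in both compartments.
  base <- met_base_name(names(sto))
  comp <- met_compartment(names(sto))
  currency <- c("h", "h2o", "atp", "adp", "pi", "pep", "pyr", "na")
  cross <- unique(base[duplicated(base) | duplicated(base, fromLast = TRUE)])
  cross <- setdiff(cross, currency)
  # PTS: the sugar arrives phosphorylated; relate e.g. glc_e0 -> g6p_c0 by
  # explicit convention "<x>" vs "<x>6p"/"<x>p".
  if (length(cross) == 0) {
    ext <- setdiff(base[comp == "e0"], currency)
    for (s in ext) {
      phospho <- c(paste0(s, c("6p", "p")), paste0(substr(s, 1, 1), "6p"))
      if (any(base[comp == "c0"] %in% phospho)) {
        cross <- s
        break
      }
    }
  }
  substance <- if (length(cross) >= 1) cross[1] else NA_character_
  structure(list(reaction_id = reaction_id, type = type,
                 substance = substance, source = source),
            class = "transport_candidate")
}

#' Select transport reactions matching transporter evidence
#'
#' For every passing transporter hit (bitscore/coverage thresholds), a
#' candidate transport reaction of the detected TC class moving the
#' annotated substance is selected from the database.  If the detected
#' class has no candidate, the remaining classes are tried in ascending
#' class number (the paper-level behaviour "other transporter types are
#' considered"); hits whose substance cannot be resolved are skipped.
#'
#' @param hits data frame of transporter hits: columns \code{tc_class},
#'   \code{substance}, \code{bitscore}, \code{coverage_pct},
#'   \code{identity_pct} (e.g. built by applying
#'   \code{\link{parse_tc_class}} to reference headers).
#' @param substance_map see \code{\link{load_substance_map}}.
#' @param db \code{reaction_db} or \code{metabolic_model}.
#' @param thresholds a \code{\link{match_thresholds}} object.
#' @param overrides optional manual override table.
#' @return Sorted unique character vector of selected transport reaction
#'   ids; attribute \code{"unresolved"} lists skipped substances.
#' @export
find_transporters <- function(hits, substance_map, db,
                              thresholds = match_thresholds(),
                              overrides = NULL) {
  trans_ids <- db$rxns$id[db$rxns$is_transport]
  cands <- lapply(trans_ids, classify_transport_reaction, db = db,
                  overrides = overrides)
  cand_type <- vapply(cands, function(x) as.integer(x$type), 1L)
  cand_sub <- vapply(cands, function(x) as.character(x$substance), "")
  selected <- character()
  unresolved <- character()
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      hit <- hits[i, ]
      if (!call_match(hit, thresholds)) next
      subst <- resolve_substance(hit$substance, substance_map)
      if (is.na(subst)) {
        unresolved <- c(unresolved, as.character(hit$substance))
        next
      }
      met_base <- substance_map$metabolite_id[match(subst, substance_map$name)]
      cls_order <- unique(c(hit$tc_class, 1:4))
      for (cls in cls_order) {
        match_idx <- which(cand_type == cls & cand_sub == met_base)
        if (length(match_idx) > 0) {
          selected <- c(selected, trans_ids[match_idx])
          break
        }
      }
    }
  }
  out <- sort(unique(selected), method = "radix")
  attr(out, "unresolved") <- unique(unresolved)
  out
}
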