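# Biochemistry database: loading, validation, curation utilities, and
# construction of the universal model used as the gap-filling source.

#' Parse a Hill-notation chemical formula
#'
#' @param formula formula string such as \code{"C6H12O6"}; element symbols
#'   are one capital letter optionally followed by a lowercase letter,
#'   each followed by an optional integer count.
#' @return Named numeric vector element -> count, or \code{NULL} when the
#'   formula is missing/empty (unknown composition).
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("unparseable formula: '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(ifelse(grepl("[0-9]$", toks),
                          sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(ct, el, sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}

parse_stoich_string <- function(s) {
  if (is.na(s) || !nzchar(s)) stop("empty stoichiometry", call. = FALSE)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed stoichiometry term: ", parts[bad][1], call. = FALSE)
  coef <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  if (anyNA(coef)) stop("non-numeric stoichiometric coefficient in: ", s, call. = FALSE)
  stats::setNames(coef, vapply(kv, `[`, "", 1L))
}

format_stoich_string <- function(sto) {
  paste(sprintf("%s:%g", names(sto), unname(sto)), collapse = ";")
}

#' Load a reaction/metabolite database from TSV tables
#'
#' Reactions table columns: \code{id}, \code{name}, \code{stoichiometry}
#' (\code{"cpd:coef;cpd:coef"}, negative = consumed), \code{reversibility}
#' (\code{>} forward, \code{<} backward, \code{=} reversible), \code{ec}
#' (comma-separated), \code{is_transport}, \code{is_spontaneous} (0/1).
#' Metabolites table columns: \code{id}, \code{name}, \code{formula}
#' (Hill notation, empty = unknown), \code{charge}, \code{compartment}.
#'
#' @param reactions_path,metabolites_path paths to the TSV tables.
#' @param compartments declared compartment set.
#' @param bound default flux-bound magnitude (mmol/gDW/h).
#' @return An object of class \code{reaction_db}: list with \code{mets},
#'   \code{rxns}, \code{stoich}, \code{compartments}.
#' @export
load_reaction_db <- function(reactions_path, metabolites_path,
                             compartments = c("c0", "e0"),
                             bound = DEFAULT_BOUND) {
  met_raw <- utils::read.delim(metabolites_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  need <- c("id", "name", "formula", "charge", "compartment")
  if (!all(need %in% names(met_raw))) {
    stop("metabolites table missing columns: ",
         paste(setdiff(need, names(met_raw)), collapse = ", "), call. = FALSE)
  }
  rxn_raw <- utils::read.delim(reactions_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  need <- c("id", "name", "stoichiometry", "reversibility", "ec",
            "is_transport", "is_spontaneous")
  if (!all(need %in% names(rxn_raw))) {
    stop("reactions table missing columns: ",
         paste(setdiff(need, names(rxn_raw)), collapse = ", "), call. = FALSE)
  }

  mets <- new_met_table()
  if (nrow(met_raw) > 0) {
    charge <- suppressWarnings(as.integer(met_raw$charge))
    bad <- which(is.na(charge) & nzchar(met_raw$charge))
    if (length(bad) > 0) {
      stop("metabolites row ", bad[1] + 1L, ": non-integer charge", call. = FALSE)
    }
    bad <- which(!met_raw$compartment %in% compartments)
    if (length(bad) > 0) {
      stop("metabolites row ", bad[1] + 1L, ": compartment '",
           met_raw$compartment[bad[1]], "' not in declared set", call. = FALSE)
    }
    for (i in seq_len(nrow(met_raw))) parse_formula(met_raw$formula[i])  # validate
    mets <- data.frame(id = met_raw$id, name = met_raw$name,
                       formula = met_raw$formula, charge = charge,
                       compartment = met_raw$compartment,
                       stringsAsFactors = FALSE)
    if (anyDuplicated(mets$id)) {
      stop("duplicate metabolite ids: ",
           paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
           call. = FALSE)
    }
  }

  rxns <- new_rxn_table()
  stoich <- list()
  if (nrow(rxn_raw) > 0) {
    if (anyDuplicated(rxn_raw$id)) {
      stop("duplicate reaction ids: ",
           paste(unique(rxn_raw$id[duplicated(rxn_raw$id)]), collapse = ", "),
           call. = FALSE)
    }
    rows <- vector("list", nrow(rxn_raw))
    for (i in seq_len(nrow(rxn_raw))) {
      sto <- tryCatch(parse_stoich_string(rxn_raw$stoichiometry[i]),
                      error = function(e) {
                        stop("reactions row ", i + 1L, " (", rxn_raw$id[i],
                             "): ", conditionMessage(e), call. = FALSE)
                      })
      dangling <- setdiff(names(sto), mets$id)
      if (length(dangling) > 0) {
        stop("reactions row ", i + 1L, " (", rxn_raw$id[i],
             "): unknown metabolite(s) ", paste(dangling, collapse = ", "),
             call. = FALSE)
      }
      bnd <- bounds_from_reversibility(rxn_raw$reversibility[i], bound)
      rows[[i]] <- data.frame(
        id = rxn_raw$id[i], name = rxn_raw$name[i],
        lb = bnd[1], ub = bnd[2], reversibility = rxn_raw$reversibility[i],
        ec = rxn_raw$ec[i],
        is_transport = rxn_raw$is_transport[i] == "1",
        is_spontaneous = rxn_raw$is_spontaneous[i] == "1",
        is_exchange = FALSE, gpr = "",
        gs_origin = NA_integer_, evidence_bitscore = NA_real_,
        stringsAsFactors = FALSE)
      stoich[[rxn_raw$id[i]]] <- sto
    }
    rxns <- do.call(rbind, rows)
  }

  structure(list(mets = mets, rxns = rxns, stoich = stoich,
                 compartments = compartments),
            class = "reaction_db")
}

#' @export
print.reaction_db <- function(x, ...) {
  cat("reaction_db: ", nrow(x$rxns), " reactions, ", nrow(x$mets),
      " metabolites, compartments {", paste(x$compartments, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Check mass and charge balance of a database reaction
#'
#' Sums elemental composition and charge over the reaction stoichiometry.
#' Exchange and biomass reactions are rejected (they are boundary/pseudo
#' reactions and not balanceable); metabolites of unknown composition
#' yield status \code{"unknown"} rather than a pass/fail verdict.
#'
#' @param reaction_id reaction to check.
#' @param db a \code{reaction_db} or \code{metabolic_model} containing it.
#' @return A \code{balance_report}: list with \code{reaction_id},
#'   \code{status} (\code{"balanced"}, \code{"unbalanced"},
#'   \code{"unknown"}), \code{element_imbalance} (named numeric, nonzero
#'   entries only), \code{charge_imbalance}, \code{balanced} flag (NA for
#'   unknown composition).
#' @export
check_mass_charge_balance <- function(reaction_id, db) {
  if (!reaction_id %in% db$rxns$id) {
    stop("unknown reaction: ", reaction_id, call. = FALSE)
  }
  row <- db$rxns[db$rxns$id == reaction_id, ]
  if (isTRUE(row$is_exchange) || grepl("^EX_", reaction_id) ||
      grepl("biomass", reaction_id, ignore.case = TRUE)) {
    stop("exchange/biomass reaction not balanceable: ", reaction_id,
         call. = FALSE)
  }
  sto <- db$stoich[[reaction_id]]
  elems <- numeric()
  charge <- 0
  unknown <- FALSE
  for (mid in names(sto)) {
    mrow <- db$mets[db$mets$id == mid, ]
    comp <- parse_formula(mrow$formula)
    if (is.null(comp)) { unknown <- TRUE; break }
    for (el in names(comp)) {
      elems[el] <- (if (el %in% names(elems)) elems[el] else 0) +
        sto[[mid]] * comp[[el]]
    }
    charge <- charge + sto[[mid]] * mrow$charge
  }
  if (unknown) {
    return(structure(list(reaction_id = reaction_id, status = "unknown",
                          element_imbalance = NULL, charge_imbalance = NA,
                          balanced = NA), class = "balance_report"))
  }
  elems <- elems[abs(elems) > 1e-9]
  ok <- length(elems) == 0 && abs(charge) < 1e-9
  structure(list(reaction_id = reaction_id,
                 status = if (ok) "balanced" else "unbalanced",
                 element_imbalance = elems, charge_imbalance = charge,
                 balanced = ok), class = "balance_report")
}

#' Validate mass/charge balance over a whole database
#'
#' @param db a \code{reaction_db}.
#' @return Data frame: reaction id, status, charge imbalance.
#' @export
validate_db_balance <- function(db) {
  ids <- db$rxns$id[!grepl("^EX_", db$rxns$id) &
                    !grepl("biomass", db$rxns$id, ignore.case = TRUE)]
  reps <- lapply(ids, check_mass_charge_balance, db = db)
  data.frame(id = ids,
             status = vapply(reps, `[[`, "", "status"),
             charge_imbalance = vapply(reps, function(r)
               as.numeric(if (is.na(r$balanced)) NA else r$charge_imbalance), 1),
             stringsAsFactors = FALSE)
}

#' Build the universal model from a database
#'
#' The universal model contains every database reaction and metabolite
#' plus an exchange reaction \code{EX_<met>} for every extracellular
#' metabolite.  No dead-end pruning is applied: the universal network is
#' intentionally kept complete so the gap-filler can reach rarely used
#' routes.  Reactions are emitted in lexicographic id order so two builds
#' are byte-identical.
#'
#' @param db a \code{reaction_db}.
#' @param bound default exchange bound magnitude.
#' @return A \code{metabolic_model} without objective.
#' @export
build_universal_model <- function(db, bound = DEFAULT_BOUND) {
  ord <- order(db$rxns$id, method = "radix")
  rxns <- db$rxns[ord, , drop = FALSE]
  stoich <- db$stoich[rxns$id]
  model <- new_metabolic_model("universal", db$mets, rxns, stoich)
  ex_mets <- sort(db$mets$id[db$mets$compartment == "e0"], method = "radix")
  for (mid in ex_mets) {
    model <- add_reaction(model, exchange_id_for(mid),
                          stats::setNames(-1, mid), lb = -bound, ub = bound,
                          name = paste("exchange of", mid),
                          is_exchange = TRUE, gs_origin = 7L)
  }
  model
}

#' Iteratively prune dead-end metabolites and their reactions
#'
#' A metabolite is a dead end when, over the current reaction set, it can
#' only be produced or only be consumed (reversible reactions count as
#' both).  Dead-end metabolites and every reaction touching them are
#' removed; the procedure iterates to a fixed point.  Pruning is an
#' explicit utility: no other function in the package prunes implicitly.
#'
#' @param model a \code{metabolic_model}.
#' @return The pruned model (metabolite table also restricted).
#' @export
prune_dead_ends <- function(model) {
  repeat {
    S <- model_S(model)
    if (nrow(S) == 0 || ncol(S) == 0) break
    rev <- model$rxns$lb < 0 & model$rxns$ub > 0
    producible <- consumable <- rep(FALSE, nrow(S))
    for (j in seq_len(ncol(S))) {
      pos <- S[, j] > 0
      neg <- S[, j] < 0
      if (rev[j]) {
        producible <- producible | pos | neg
        consumable <- consumable | pos | neg
      } else {
        fwd_ok <- model$rxns$ub[j] > 0
        bwd_ok <- model$rxns$lb[j] < 0
        if (fwd_ok) { producible <- producible | pos; consumable <- consumable | neg }
        if (bwd_ok) { producible <- producible | neg; consumable <- consumable | pos }
      }
    }
    used <- rowSums(S != 0) > 0
    dead <- used & (producible != consumable)  # one-sided only
    dead <- dead | (used & !producible & !consumable)
    if (!any(dead)) {
      # also drop never-referenced metabolites once stable
      model$mets <- model$mets[used | model$mets$id %in% unlist(lapply(model$stoich, names)), , drop = FALSE]
      break
    }
    dead_ids <- rownames(S)[dead]
    drop_rxn <- model$rxns$id[vapply(model$stoich, function(s)
      any(names(s) %in% dead_ids), TRUE)]
    model <- remove_reactions(model, drop_rxn)
    model$mets <- model$mets[!model$mets$id %in% dead_ids, , drop = FALSE]
    rownames(model$mets) <- NULL
  }
  model
}

#' Detect energy-generating cycles
#'
#' Closes all exchange uptake bounds (lower bound 0) and maximises flux
#' through a named energy-dissipation reaction (e.g. ATP hydrolysis,
#' ATP + H2O -> ADP + Pi + H+).  Any positive optimum indicates a
#' thermodynamically infeasible energy-generating cycle in the network; the
#' reactions carrying flux in the optimal solution localise it.
#'
#' @param model a \code{metabolic_model} containing the dissipation reaction.
#' @param energy_dissipation_reaction_id its id.
#' @param tol flux tolerance for reporting cycle members (default 1e-9).
#' @return List with \code{objective} (maximum dissipation flux) and
#'   \code{cycle_reactions} (ids with |flux| > tol, dissipation excluded).
#' @export
detect_energy_cycles <- function(model, energy_dissipation_reaction_id,
                                 tol = 1e-9) {
  if (!energy_dissipation_reaction_id %in% model$rxns$id) {
    stop("dissipation reaction absent: ", energy_dissipation_reaction_id,
         call. = FALSE)
  }
  ex <- model$rxns$is_exchange
  model$rxns$lb[ex] <- pmax(model$rxns$lb[ex], 0)
  model <- set_objective(model, energy_dissipation_reaction_id)
  sol <- fba(model, medium = NULL)
  if (sol$status != "optimal") {
    stop("energy-cycle LP not optimal: ", sol$status, call. = FALSE)
  }
  carriers <- names(sol$fluxes)[abs(sol$fluxes) > tol]
  carriers <- setdiff(carriers, energy_dissipation_reaction_id)
  list(objective = sol$objective, cycle_reactions = sort(carriers))
}
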