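# Core containers: reaction database and metabolic model.
#
# A `reaction_db` is the curated biochemistry: metabolite and reaction
# tables plus explicit stoichiometries.  A `metabolic_model` is a
# simulatable network: the same tables restricted to one organism (or the
# full universal network), plus exchange reactions, an objective, and
# per-reaction provenance (gs_origin) and evidence annotations.

DEFAULT_BOUND <- 1000   # mmol/gDW/h, community convention for "unbounded"

# gs_origin provenance codes (code 5 reserved/unused):
# 0 direct sequence evidence, 1-4 gap-filling steps, 6 biomass,
# 7 exchange, 8 diffusion, 9 pathway completion, 10 manual adaptation.
GS_ORIGIN_CODES <- c(0L, 1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L, 10L)

new_rxn_table <- function() {
  data.frame(id = character(), name = character(),
             lb = numeric(), ub = numeric(),
             reversibility = character(), ec = character(),
             is_transport = logical(), is_spontaneous = logical(),
             is_exchange = logical(), gpr = character(),
             gs_origin = integer(), evidence_bitscore = numeric(),
             stringsAsFactors = FALSE)
}

new_met_table <- function() {
  data.frame(id = character(), name = character(), formula = character(),
             charge = integer(), compartment = character(),
             stringsAsFactors = FALSE)
}

bounds_from_reversibility <- function(rev, bound = DEFAULT_BOUND) {
  if (!rev %in% c(">", "<", "=")) {
    stop("invalid reversibility code: ", rev, call. = FALSE)
  }
  switch(rev,
         ">" = c(0, bound),
         "<" = c(-bound, 0),
         "=" = c(-bound, bound))
}

#' Construct a metabolic model
#'
#' Low-level constructor used by \code{\link{build_universal_model}},
#' \code{\link{assemble_draft}} and the SBML importer.
#'
#' @param id model identifier.
#' @param mets metabolite table (id, name, formula, charge, compartment).
#' @param rxns reaction table (id, name, lb, ub, reversibility, ec,
#'   is_transport, is_spontaneous, is_exchange, gpr, gs_origin,
#'   evidence_bitscore).
#' @param stoich named list: reaction id -> named numeric vector of
#'   signed stoichiometric coefficients over metabolite ids.
#' @param objective id of the objective reaction or \code{NA}.
#' @return An object of class \code{metabolic_model}.
#' @export
new_metabolic_model <- function(id, mets, rxns, stoich, objective = NA_character_) {
  stopifnot(is.data.frame(mets), is.data.frame(rxns), is.list(stoich))
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
         call. = FALSE)
  }
  stoich <- stoich[rxns$id]
  refd <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  missing_mets <- setdiff(refd, mets$id)
  if (length(missing_mets) > 0) {
    stop("reactions reference unknown metabolites: ",
         paste(missing_mets, collapse = ", "), call. = FALSE)
  }
  if (!is.na(objective) && !objective %in% rxns$id) {
    stop("objective reaction not in model: ", objective, call. = FALSE)
  }
  rownames(mets) <- NULL
  rownames(rxns) <- NULL
  structure(list(id = id, mets = mets, rxns = rxns, stoich = stoich,
                 objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$id, "': ", nrow(x$rxns), " reactions, ",
      nrow(x$mets), " metabolites", sep = "")
  if (!is.na(x$objective)) cat(", objective = ", x$objective, sep = "")
  cat("\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{metabolic_model}.
#' @return Dense numeric matrix (metabolites x reactions) with dimnames.
#' @export
model_S <- function(model) {
  S <- matrix(0, nrow(model$mets), nrow(model$rxns),
              dimnames = list(model$mets$id, model$rxns$id))
  for (j in seq_along(model$stoich)) {
    sto <- model$stoich[[j]]
    S[names(sto), j] <- sto
  }
  S
}

#' Add a reaction to a model
#'
#' @param model a \code{metabolic_model}.
#' @param id new reaction id (must be unused).
#' @param stoich named numeric vector over existing metabolite ids.
#' @param lb,ub flux bounds.
#' @param name,ec,gpr optional annotations.
#' @param is_transport,is_spontaneous,is_exchange flags.
#' @param gs_origin provenance code or \code{NA}.
#' @param evidence_bitscore best supporting bitscore or \code{NA}.
#' @return The modified model.
#' @export
add_reaction <- function(model, id, stoich, lb, ub, name = id, ec = "",
                         is_transport = FALSE, is_spontaneous = FALSE,
                         is_exchange = FALSE, gpr = "",
                         gs_origin = NA_integer_,
                         evidence_bitscore = NA_real_) {
  if (id %in% model$rxns$id) stop("reaction already in model: ", id, call. = FALSE)
  unknown <- setdiff(names(stoich), model$mets$id)
  if (length(unknown) > 0) {
    stop("unknown metabolites in stoichiometry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rev <- if (lb < 0 && ub > 0) "=" else if (ub <= 0) "<" else ">"
  model$rxns <- rbind(model$rxns, data.frame(
    id = id, name = name, lb = lb, ub = ub, reversibility = rev, ec = ec,
    is_transport = is_transport, is_spontaneous = is_spontaneous,
    is_exchange = is_exchange, gpr = gpr,
    gs_origin = as.integer(gs_origin),
    evidence_bitscore = evidence_bitscore, stringsAsFactors = FALSE))
  model$stoich[[id]] <- stoich
  model
}

#' Remove reactions from a model
#'
#' Metabolites left unreferenced are retained (models keep their full
#' metabolite table; use \code{\link{prune_dead_ends}} for pruning).
#'
#' @param model a \code{metabolic_model}.
#' @param ids reaction ids to drop (silently ignores absent ids).
#' @return The modified model.
#' @export
remove_reactions <- function(model, ids) {
  keep <- !model$rxns$id %in% ids
  model$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$stoich <- model$stoich[model$rxns$id]
  if (!is.na(model$objective) && !model$objective %in% model$rxns$id) {
    model$objective <- NA_character_
  }
  model
}

#' Restrict a model to a reaction subset
#'
#' @param model a \code{metabolic_model}.
#' @param rxn_ids reactions to keep.
#' @return The restricted model (full metabolite table retained).
#' @export
subset_reactions <- function(model, rxn_ids) {
  remove_reactions(model, setdiff(model$rxns$id, rxn_ids))
}

#' Set the objective reaction
#' @param model a \code{metabolic_model}.
#' @param rxn_id id of an existing reaction.
#' @return The modified model.
#' @export
set_objective <- function(model, rxn_id) {
  if (!rxn_id %in% model$rxns$id) {
    stop("objective reaction not in model: ", rxn_id, call. = FALSE)
  }
  model$objective <- rxn_id
  model
}

#' Gene identifiers appearing in a model's GPR expressions
#' @param model a \code{metabolic_model}.
#' @return Character vector of gene ids (sorted, unique).
#' @export
model_genes <- function(model) {
  gprs <- model$rxns$gpr
  gprs <- gprs[!is.na(gprs) & nzchar(gprs)]
  sort(unique(unlist(lapply(gprs, gpr_gene_ids))))
}

exchange_ids <- function(model) model$rxns$id[model$rxns$is_exchange]

#' Exchange reaction id for a metabolite
#'
#' Follows the naming convention \code{EX_<metabolite id>} used
#' throughout the package (uptake = negative flux, secretion = positive).
#'
#' @param met_id extracellular metabolite id.
#' @return The exchange reaction id string.
#' @export
exchange_id_for <- function(met_id) paste0("EX_", met_id)
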