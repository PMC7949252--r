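# Constraint-based analysis: FBA, minimisation of total flux (MTF/pFBA),
# flux variability analysis (FVA), and the evidence-weighted gap-filling
# linear program.
#
# All LPs share the steady-state constraint S v = 0 with flux bounds
# lb <= v <= ub; |v| terms are linearised with nonnegative split
# variables v = v+ - v-.

#' Gap-filling and flux-analysis parameters
#'
#' Bundles the defaults of the evidence-weighted gap-filling LP and the
#' flux tolerances used across the package.
#'
#' @param c scalar weight of the summed weighted absolute fluxes in the
#'   gap-filling objective (default 0.001).
#' @param w_min minimum reaction weight, assigned to draft reactions and
#'   to reactions with bitscore >= \code{u} (default 0.005).
#' @param w_max maximum reaction weight, assigned to reactions with
#'   bitscore < \code{l} or without any evidence (default 100).
#' @param l,u lower/upper bitscore thresholds of the linear ramp
#'   (defaults 50 and 200 bits).
#' @param core_bitscore bitscore threshold defining core reactions for
#'   gap-filling steps 2-4 (default 50; strict "greater than").
#' @param flux_tol absolute flux magnitude counting as "carries flux"
#'   (default 1e-6).
#' @param exempt_exchanges if TRUE, exchange reactions get weight 0 in the
#'   gap-filling objective instead of their evidence-derived weight.
#' @return A list of class \code{gapfill_params}.
#' @export
gapfill_params <- function(c = 0.001, w_min = 0.005, w_max = 100,
                           l = 50, u = 200, core_bitscore = 50,
                           flux_tol = 1e-6, exempt_exchanges = FALSE) {
  stopifnot(c > 0, w_min > 0, w_min < w_max, l < u, core_bitscore >= 0)
  structure(list(c = c, w_min = w_min, w_max = w_max, l = l, u = u,
                 core_bitscore = core_bitscore, flux_tol = flux_tol,
                 exempt_exchanges = exempt_exchanges),
            class = "gapfill_params")
}

#' Evidence-to-weight mapping of the gap-filling LP
#'
#' Piecewise-linear mapping from a reaction's best supporting bitscore to
#' its penalty weight: draft reactions and reactions with bitscore >=
#' \code{u} get \code{w_min}; reactions with bitscore < \code{l} (or no
#' evidence at all) get \code{w_max}; in between the weight falls
#' linearly from \code{w_max} at \code{l} to \code{w_min} at \code{u}.
#'
#' @param b_i best supporting bitscore (bits); \code{NA} = no evidence.
#' @param in_draft is the reaction already part of the draft network?
#' @param params a \code{\link{gapfill_params}} object.
#' @return The weight (vectorised over \code{b_i} and \code{in_draft}).
#' @export
evidence_weight <- function(b_i, in_draft = FALSE, params = gapfill_params()) {
  n <- max(length(b_i), length(in_draft))
  b_i <- rep_len(as.numeric(b_i), n)
  in_draft <- rep_len(in_draft, n)
  b_i[is.na(b_i)] <- -Inf                    # absent evidence -> b < l branch
  w <- ifelse(in_draft | b_i >= params$u, params$w_min,
        ifelse(b_i < params$l, params$w_max,
               (b_i - params$u) * (params$w_min - params$w_max) /
                 (params$u - params$l) + params$w_min))
  w
}

#' Apply a growth medium to a model
#'
#' Sets every exchange reaction's lower bound to 0 (no uptake) and opens
#' uptake (lower bound = -rate) for the medium compounds.  Secretion
#' bounds are left untouched.  Medium compounds lacking an exchange
#' reaction in the model are skipped with a warning-free log attribute.
#'
#' @param model a \code{metabolic_model}.
#' @param medium named numeric vector: extracellular metabolite id ->
#'   maximal uptake rate (mmol/gDW/h); the single name \code{"*"} opens
#'   all exchanges at the given rate (complete medium).  \code{NULL}
#'   leaves bounds untouched.
#' @return The re-constrained model; attribute \code{"missing_exchanges"}
#'   lists medium compounds without exchange reaction.
#' @export
apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  stopifnot(is.numeric(medium), !is.null(names(medium)), all(medium >= 0))
  ex <- model$rxns$is_exchange
  model$rxns$lb[ex] <- 0
  missing <- character()
  if ("*" %in% names(medium)) {
    model$rxns$lb[ex] <- -abs(medium[["*"]])
    medium <- medium[names(medium) != "*"]
  }
  for (cpd in names(medium)) {
    exid <- exchange_id_for(cpd)
    k <- which(model$rxns$id == exid)
    if (length(k) == 0) { missing <- c(missing, cpd); next }
    model$rxns$lb[k] <- -abs(medium[[cpd]])
  }
  attr(model, "missing_exchanges") <- missing
  model
}

flux_solution <- function(status, objective = NA_real_, fluxes = NULL) {
  structure(list(status = status, objective = objective, fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution: status =", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective))
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises flux through the objective reaction subject to steady-state
#' mass balance (S v = 0) and flux bounds.
#'
#' @param model a \code{metabolic_model} with an objective (or use
#'   \code{objective=}).
#' @param medium growth medium passed to \code{\link{apply_medium}};
#'   \code{NULL} uses the model's current bounds.
#' @param objective objective reaction id, or several ids whose summed
#'   flux is maximised (default: the model objective).
#' @return A \code{flux_solution}: \code{status}, \code{objective} value,
#'   named \code{fluxes} vector.
#' @export
fba <- function(model, medium = NULL, objective = model$objective) {
  if (any(is.na(objective)) || !all(objective %in% model$rxns$id)) {
    stop("objective reaction absent: ",
         paste(objective, collapse = "+"), call. = FALSE)
  }
  model <- apply_medium(model, medium)
  S <- model_S(model)
  n <- ncol(S)
  obj <- as.numeric(model$rxns$id %in% objective)
  res <- solve_lp(S, numeric(nrow(S)), obj, model$rxns$lb, model$rxns$ub,
                  maximize = TRUE)
  if (res$status != "optimal") return(flux_solution(res$status))
  out <- flux_solution("optimal", res$objective,
                       stats::setNames(res$x, model$rxns$id))
  out
}

# Shared split-variable machinery: returns the LP pieces for variables
# [v+; v-] of a model whose objective flux is fixed to >= target.
split_lp_pieces <- function(model, fix_objective = NULL) {
  S <- model_S(model)
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  if (!is.null(fix_objective)) {
    k <- which(model$rxns$id == fix_objective$id)
    lo <- fix_objective$value
    lb[k] <- max(lb[k], lo - abs(lo) * 1e-9 - 1e-12)
  }
  list(A = cbind(S, -S),
       lb = c(pmax(0, lb), pmax(0, -ub)),
       ub = c(pmax(0, ub), pmax(0, -lb)),
       n = ncol(S))
}

#' Minimisation of total flux at the FBA optimum (pFBA/MTF)
#'
#' Fixes the objective flux at \code{optimum_fraction} times the FBA
#' optimum (with a 1e-9 relative slack) and minimises the summed absolute
#' flux, removing loops and gratuitous fluxes from the solution.
#'
#' @inheritParams fba
#' @param optimum_fraction fraction of the FBA optimum to retain (default 1).
#' @return A \code{flux_solution}; \code{objective} is the retained
#'   objective flux, attribute \code{"total_flux"} holds the minimised sum.
#' @export
mtf <- function(model, medium = NULL, objective = model$objective,
                optimum_fraction = 1.0) {
  model <- apply_medium(model, medium)
  base <- fba(model, medium = NULL, objective = objective)
  if (base$status != "optimal") return(base)
  pieces <- split_lp_pieces(model, fix_objective = list(
    id = objective, value = base$objective * optimum_fraction))
  n <- pieces$n
  res <- solve_lp(pieces$A, numeric(nrow(pieces$A)), rep(1, 2 * n),
                  pieces$lb, pieces$ub, maximize = FALSE)
  if (res$status != "optimal") return(flux_solution(res$status))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- model$rxns$id
  out <- flux_solution("optimal", v[[objective]], v)
  attr(out, "total_flux") <- res$objective
  out
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimum and maximum feasible flux
#' with the objective constrained to at least \code{optimum_fraction}
#' times its FBA optimum.
#'
#' @inheritParams mtf
#' @param reactions reaction ids to scan (default: all).
#' @return Data frame with columns \code{id}, \code{min}, \code{max}.
#' @export
fva <- function(model, medium = NULL, objective = model$objective,
                optimum_fraction = 1.0, reactions = model$rxns$id) {
  model <- apply_medium(model, medium)
  base <- fba(model, medium = NULL, objective = objective)
  if (base$status != "optimal") {
    stop("FVA requires a feasible FBA solution; status: ", base$status,
         call. = FALSE)
  }
  S <- model_S(model)
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  k <- which(model$rxns$id == objective)
  lo <- base$objective * optimum_fraction
  lb[k] <- max(lb[k], lo - abs(lo) * 1e-9 - 1e-12)
  idx <- match(reactions, model$rxns$id)
  if (anyNA(idx)) {
    stop("unknown reactions in FVA request: ",
         paste(reactions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mins <- maxs <- numeric(length(idx))
  for (q in seq_along(idx)) {
    obj <- numeric(ncol(S)); obj[idx[q]] <- 1
    r1 <- solve_lp(S, numeric(nrow(S)), obj, lb, ub, maximize = FALSE)
    r2 <- solve_lp(S, numeric(nrow(S)), obj, lb, ub, maximize = TRUE)
    mins[q] <- if (r1$status == "optimal") r1$objective else NA_real_
    maxs[q] <- if (r2$status == "optimal") r2$objective else NA_real_
  }
  data.frame(id = reactions, min = mins, max = maxs, stringsAsFactors = FALSE)
}

#' Merge draft-only reactions into the universal model
#'
#' Returns the universal model extended by reactions that exist only in
#' the draft (biomass, organism-specific additions); shared reactions
#' keep the universal definition.  Metabolite tables are unioned.
#'
#' @param universal,draft \code{metabolic_model}s.
#' @return The merged model, objective taken from the draft.
#' @export
merge_models <- function(universal, draft) {
  extra_mets <- draft$mets[!draft$mets$id %in% universal$mets$id, , drop = FALSE]
  if (nrow(extra_mets) > 0) universal$mets <- rbind(universal$mets, extra_mets)
  extra <- setdiff(draft$rxns$id, universal$rxns$id)
  for (rid in extra) {
    row <- draft$rxns[draft$rxns$id == rid, ]
    universal <- add_reaction(universal, rid, draft$stoich[[rid]],
                              lb = row$lb, ub = row$ub, name = row$name,
                              ec = row$ec, is_transport = row$is_transport,
                              is_spontaneous = row$is_spontaneous,
                              is_exchange = row$is_exchange, gpr = row$gpr,
                              gs_origin = row$gs_origin,
                              evidence_bitscore = row$evidence_bitscore)
  }
  if (!is.na(draft$objective)) universal$objective <- draft$objective
  universal
}

#' Evidence-weighted gap-filling LP
#'
#' Solves  max  v_j - c * sum_i w_i |v_i|  over the universal network
#' (steady state, flux bounds), where the weights w_i derive from each
#' reaction's best supporting bitscore via \code{\link{evidence_weight}}.
#' Reactions outside the draft that carry flux above the tolerance in the
#' optimal solution are the proposed additions.  Formulated as a pure LP
#' (no integer variables): |v_i| is linearised with split variables.
#'
#' @param universal universal \code{metabolic_model} already containing
#'   the objective reaction (see \code{\link{merge_models}}).
#' @param draft_ids reaction ids already in the draft network (weight
#'   \code{w_min}; never reported as additions).
#' @param evidence an \code{evidence_table} (see
#'   \code{\link{build_evidence_table}}) or \code{NULL} for no evidence.
#' @param objective objective reaction id (e.g. the biomass reaction).
#' @param medium growth medium (see \code{\link{apply_medium}}).
#' @param params a \code{\link{gapfill_params}} object.
#' @param candidates optional restriction: reaction ids outside the draft
#'   that may carry flux (all others are closed); \code{NULL} = all.
#' @return List with \code{solution} (a \code{flux_solution} over the
#'   universal reactions), \code{added} (sorted ids of flux-carrying
#'   non-draft reactions), \code{weights} (named vector used).
#' @export
weighted_gapfill_lp <- function(universal, draft_ids, evidence, objective,
                                medium, params = gapfill_params(),
                                candidates = NULL) {
  if (!all(objective %in% universal$rxns$id)) {
    stop("objective reaction absent from universal model: ",
         paste(objective, collapse = "+"), call. = FALSE)
  }
  model <- apply_medium(universal, medium)
  ord <- order(model$rxns$id, method = "radix")   # deterministic variable order
  model$rxns <- model$rxns[ord, , drop = FALSE]
  model$stoich <- model$stoich[model$rxns$id]
  ids <- model$rxns$id
  if (!is.null(candidates)) {
    closed <- !(ids %in% draft_ids) & !(ids %in% candidates) &
      !(ids %in% objective)
    model$rxns$lb[closed] <- 0
    model$rxns$ub[closed] <- 0
  }
  b <- evidence_bitscores(evidence, ids)
  w <- evidence_weight(b, in_draft = ids %in% draft_ids, params = params)
  names(w) <- ids
  if (params$exempt_exchanges) w[model$rxns$is_exchange] <- 0

  pieces <- split_lp_pieces(model)
  n <- pieces$n
  obj <- rep(-params$c * w, 2)
  k <- which(ids %in% objective)
  obj[k] <- obj[k] + 1
  obj[n + k] <- obj[n + k] - 1
  res <- solve_lp(pieces$A, numeric(nrow(pieces$A)), obj,
                  pieces$lb, pieces$ub, maximize = TRUE)
  if (res$status != "optimal") {
    stop("gap-filling LP not optimal (", res$status,
         "): objective may be unreachable even in the universal model",
         call. = FALSE)
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- ids
  sol <- flux_solution("optimal", sum(v[objective]), v)
  attr(sol, "lp_objective") <- res$objective
  added <- sort(ids[abs(v) > params$flux_tol & !(ids %in% draft_ids)])
  list(solution = sol, added = added, weights = w)
}

# Best bitscore per reaction id, NA where absent; tolerant of NULL tables.
evidence_bitscores <- function(evidence, ids) {
  if (is.null(evidence) || nrow(evidence$table) == 0) {
    return(rep(NA_real_, length(ids)))
  }
  evidence$table$best_bitscore[match(ids, evidence$table$reaction_id)]
}
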