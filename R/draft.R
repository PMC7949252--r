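# Draft model assembly: reactions enter the draft by direct sequence
# evidence, pathway completion, transporter selection, spontaneity or
# diffusion, with gs_origin provenance codes; a Gram-specific biomass
# reaction becomes the objective.

#' Load biomass templates
#'
#' TSV with columns \code{gram} ("positive"/"negative"),
#' \code{metabolite_id}, \code{coefficient} (mmol consumed per gDW,
#' positive numbers).  The special metabolite id \code{ATP_ENERGY} gives
#' the growth-associated ATP hydrolysis requirement (mmol ATP per gDW).
#'
#' @param path path to the TSV file.
#' @return Named list per gram type: list with \code{components} (named
#'   numeric) and \code{energy_atp}.
#' @export
load_biomass_templates <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gram", "metabolite_id", "coefficient")
  if (!all(need %in% names(raw))) {
    stop("biomass template missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  if (any(raw$coefficient <= 0)) {
    stop("biomass template coefficients must be > 0", call. = FALSE)
  }
  out <- list()
  for (g in unique(raw$gram)) {
    sub <- raw[raw$gram == g, , drop = FALSE]
    en <- sub$coefficient[sub$metabolite_id == "ATP_ENERGY"]
    comp <- sub[sub$metabolite_id != "ATP_ENERGY", , drop = FALSE]
    out[[g]] <- list(components = stats::setNames(comp$coefficient,
                                                  comp$metabolite_id),
                     energy_atp = if (length(en) > 0) en[1] else 0)
  }
  out
}

#' Attach a biomass reaction and set it as objective
#'
#' Adds an (intentionally unbalanced) pseudo-reaction consuming the
#' template components in mmol per gram dry weight, plus the
#' growth-associated ATP hydrolysis (ATP + H2O -> ADP + Pi + H+), and
#' makes it the model objective.  Its gs_origin code is 6.
#'
#' @param model a \code{metabolic_model}.
#' @param gram \code{"positive"} or \code{"negative"}.
#' @param template_db result of \code{\link{load_biomass_templates}}.
#' @param id biomass reaction id (default \code{"bio1"}).
#' @return The model with biomass attached.
#' @export
attach_biomass <- function(model, gram, template_db, id = "bio1") {
  if (!gram %in% names(template_db)) {
    stop("no biomass template for gram = '", gram, "' (have: ",
         paste(names(template_db), collapse = ", "), ")", call. = FALSE)
  }
  tpl <- template_db[[gram]]
  missing <- setdiff(names(tpl$components), model$mets$id)
  if (length(missing) > 0) {
    stop("biomass components absent from database: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sto <- -tpl$components
  if (tpl$energy_atp > 0) {
    gam <- tpl$energy_atp
    en <- c(atp_c0 = -gam, h2o_c0 = -gam, adp_c0 = gam, pi_c0 = gam,
            h_c0 = gam)
    for (m in names(en)) {
      sto[m] <- (if (m %in% names(sto)) sto[[m]] else 0) + en[[m]]
    }
  }
  model <- add_reaction(model, id, sto, lb = 0, ub = DEFAULT_BOUND,
                        name = paste0("biomass (gram-", gram, ")"),
                        gs_origin = 6L)
  set_objective(model, id)
}

# OR-join of passing reference sequences; complexes AND-join subunit
# groups (OR within each label's passing sequences).
build_gpr_for_reaction <- function(rid, evidence, complex_calls, thresholds) {
  if (is.null(evidence) || nrow(evidence$hits) == 0) return("")
  sub <- evidence$hits[evidence$hits$reaction_id == rid, , drop = FALSE]
  if (nrow(sub) == 0) return("")
  pass <- vapply(seq_len(nrow(sub)), function(i)
    call_match(sub[i, ], thresholds), TRUE)
  sub <- sub[pass, , drop = FALSE]
  if (nrow(sub) == 0) return("")
  cc <- complex_calls[[rid]]
  if (!is.null(cc) && cc$n_subunits_recognized > 0) {
    labs <- sort(unique(sub$subunit_label[nzchar(sub$subunit_label)]))
    groups <- character()
    for (l in labs) {
      seqs <- sort(unique(sub$ref_seq_id[sub$subunit_label == l]))
      if (length(seqs) > 0) {
        groups <- c(groups, if (length(seqs) == 1) seqs
                    else paste0("(", paste(seqs, collapse = " or "), ")"))
      }
    }
    if (length(groups) == 0) return("")
    return(paste(groups, collapse = " and "))
  }
  seqs <- sort(unique(sub$ref_seq_id))
  paste(seqs, collapse = " or ")
}

#' Assemble a draft genome-scale model from the prediction results
#'
#' Reaction inclusion and provenance (gs_origin): directly matched
#' enzymes, present complexes, selected transporters and spontaneous
#' reactions get code 0; reactions of present pathways that were not
#' directly matched get 9 (pathway completion); diffusion reactions 8;
#' exchange reactions (one per extracellular metabolite) 7; the biomass
#' reaction 6.  When a reaction qualifies under several rules the lowest
#' code wins.  The best supporting bitscore is recorded per reaction and
#' GPR strings are assembled from the passing reference sequences (one
#' pseudo-gene per sequence; complex subunits AND-joined).
#'
#' @param pathway_calls named list of \code{pathway_call}s.
#' @param evidence an \code{evidence_table}.
#' @param transporter_selection character vector of selected transport
#'   reaction ids (see \code{\link{find_transporters}}).
#' @param db the \code{reaction_db}.
#' @param gram \code{"positive"} or \code{"negative"}.
#' @param biomass_templates see \code{\link{load_biomass_templates}}.
#' @param complex_calls named list of \code{complex_call}s (optional);
#'   reactions with a negative complex call are never direct matches.
#' @param diffusion_ids reaction ids crossing the membrane by diffusion
#'   (default: db transport reactions whose name contains "diffusion").
#' @param maintenance_ids non-growth-associated energy maintenance
#'   reactions (ATP hydrolysis), always included with the biomass code 6
#'   (default: db reactions whose name contains "maintenance").
#' @param model_id id for the resulting model.
#' @return A \code{metabolic_model} with biomass objective.
#' @export
assemble_draft <- function(pathway_calls, evidence, transporter_selection,
                           db, gram = "negative", biomass_templates,
                           complex_calls = NULL, diffusion_ids = NULL,
                           maintenance_ids = NULL, model_id = "draft") {
  if (!gram %in% c("positive", "negative")) {
    stop("gram must be 'positive' or 'negative', got '", gram, "'",
         call. = FALSE)
  }
  if (is.null(diffusion_ids)) {
    diffusion_ids <- db$rxns$id[grepl("diffusion", db$rxns$name,
                                      ignore.case = TRUE)]
  }
  if (is.null(maintenance_ids)) {
    maintenance_ids <- db$rxns$id[grepl("maintenance", db$rxns$name,
                                        ignore.case = TRUE)]
  }
  origin <- integer()   # named by reaction id; lowest code wins

  claim <- function(ids, code) {
    for (rid in ids) {
      if (!rid %in% db$rxns$id) next
      cur <- origin[rid]
      if (is.na(cur) || length(cur) == 0 || code < cur) origin[rid] <<- code
    }
  }

  # Direct matches (complex-aware), transporters, spontaneous: code 0.
  direct <- character()
  if (!is.null(evidence) && nrow(evidence$table) > 0) {
    for (i in seq_len(nrow(evidence$table))) {
      rid <- evidence$table$reaction_id[i]
      cc <- complex_calls[[rid]]
      ok <- if (!is.null(cc)) cc$present else evidence$table$matched[i]
      if (isTRUE(ok)) direct <- c(direct, rid)
    }
  }
  claim(direct, 0L)
  claim(transporter_selection, 0L)
  claim(db$rxns$id[db$rxns$is_spontaneous], 0L)
  claim(diffusion_ids, 8L)
  claim(maintenance_ids, 6L)

  # Pathway completion: remaining members of present pathways: code 9.
  for (cl in pathway_calls) {
    if (!isTRUE(cl$present)) next
    claim(names(cl$statuses), 9L)
  }

  ids <- sort(names(origin), method = "radix")
  rxns <- db$rxns[match(ids, db$rxns$id), , drop = FALSE]
  rxns$gs_origin <- unname(origin[ids])
  rxns$evidence_bitscore <- evidence_bitscores(evidence, ids)
  thr <- if (!is.null(evidence)) evidence$thresholds else match_thresholds()
  rxns$gpr <- vapply(ids, build_gpr_for_reaction, "", evidence = evidence,
                     complex_calls = complex_calls, thresholds = thr)
  model <- new_metabolic_model(model_id, db$mets, rxns, db$stoich[ids])

  ex_mets <- sort(db$mets$id[db$mets$compartment == "e0"], method = "radix")
  for (mid in ex_mets) {
    model <- add_reaction(model, exchange_id_for(mid),
                          stats::setNames(-1, mid),
                          lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND,
                          name = paste("exchange of", mid),
                          is_exchange = TRUE, gs_origin = 7L)
  }
  attach_biomass(model, gram, biomass_templates)
}
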