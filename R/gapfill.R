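# Four-step gap-filling protocol.  Step 1 makes the biomass reaction
# feasible on the gap-filling medium using the full universal reaction
# set; steps 2-4 improve biosynthetic, catabolic, and secretion
# capabilities using only core reactions (those with genomic sequence
# evidence above the core bitscore), which keeps the final model largely
# independent of the particular gap-filling medium.  Additions carry the
# step number as gs_origin provenance code (1-4).

#' Temporary electron-carrier recycling reactions (ESP1-3)
#'
#' The trio used by the energy-source tests and gap-filling step 3:
#' menaquinol -> menaquinone + 2H+, quinol -> quinone + 2H+, and
#' NADH -> NAD+ + H+.  They emulate the dye coupling of BIOLOG-style
#' carbon-source assays (electrons leave the system) and are always
#' removed again after use.
#'
#' @return Named list of stoichiometries.
#' @export
esp_reactions <- function() {
  list(ESP1 = c(mqh2_c0 = -1, mqn_c0 = 1, h_c0 = 2),
       ESP2 = c(qh2_c0 = -1, qn_c0 = 1, h_c0 = 2),
       ESP3 = c(nadh_c0 = -1, nad_c0 = 1, h_c0 = 1))
}

add_esp_reactions <- function(model) {
  for (nm in names(esp_reactions())) {
    sto <- esp_reactions()[[nm]]
    sto <- sto[names(sto) %in% model$mets$id]
    if (length(sto) < 2) next
    model <- add_reaction(model, nm, esp_reactions()[[nm]], 0,
                          DEFAULT_BOUND, name = paste(nm, "recycling (temporary)"))
  }
  model
}

#' Core reactions eligible for gap-filling steps 2-4
#'
#' Reactions whose best supporting bitscore is strictly greater than the
#' core threshold; only these carry genomic sequence evidence and may be
#' added by the sequence-restricted gap-filling steps.
#'
#' @param evidence an \code{evidence_table}.
#' @param params a \code{\link{gapfill_params}} object.
#' @return Character vector of reaction ids.
#' @export
core_reactions <- function(evidence, params = gapfill_params()) {
  if (is.null(evidence) || nrow(evidence$table) == 0) return(character())
  tab <- evidence$table
  sort(tab$reaction_id[tab$best_bitscore > params$core_bitscore],
       method = "radix")
}

# Copy reactions from the universal model into the draft, stamping the
# gap-filling provenance code and the supporting bitscore.
adopt_reactions <- function(model, universal, ids, code, evidence) {
  b <- evidence_bitscores(evidence, ids)
  for (i in seq_along(ids)) {
    rid <- ids[i]
    if (rid %in% model$rxns$id) next
    row <- universal$rxns[universal$rxns$id == rid, ]
    new_mets <- setdiff(names(universal$stoich[[rid]]), model$mets$id)
    if (length(new_mets) > 0) {
      model$mets <- rbind(model$mets,
                          universal$mets[universal$mets$id %in% new_mets, ])
    }
    model <- add_reaction(model, rid, universal$stoich[[rid]],
                          lb = row$lb, ub = row$ub, name = row$name,
                          ec = row$ec, is_transport = row$is_transport,
                          is_spontaneous = row$is_spontaneous,
                          is_exchange = row$is_exchange, gpr = row$gpr,
                          gs_origin = code, evidence_bitscore = b[i])
  }
  model
}

report_entry <- function(step, objective, medium_label, added, success,
                         note = "") {
  data.frame(step = step, objective = paste(objective, collapse = "+"),
             medium = medium_label,
             added = paste(added, collapse = ";"),
             n_added = length(added), success = success, note = note,
             stringsAsFactors = FALSE)
}

#' Gap-filling step 1: biomass production
#'
#' Makes the draft grow on the gap-filling medium by solving the
#' evidence-weighted LP over the full universal reaction set; flux-
#' carrying non-draft reactions are adopted with gs_origin code 1.
#'
#' @param draft draft \code{metabolic_model} with biomass objective.
#' @param universal universal \code{metabolic_model}.
#' @param medium gap-filling medium (named uptake vector).
#' @param evidence an \code{evidence_table}.
#' @param params a \code{\link{gapfill_params}} object.
#' @param medium_label label used in the report.
#' @return List with \code{model} and \code{report} (one-row data frame).
#' @export
gapfill_step1_biomass <- function(draft, universal, medium, evidence,
                                  params = gapfill_params(),
                                  medium_label = "gapfill") {
  merged <- merge_models(universal, draft)
  res <- weighted_gapfill_lp(merged, draft$rxns$id, evidence,
                             draft$objective, medium, params)
  model <- adopt_reactions(draft, merged, res$added, 1L, evidence)
  growth <- fba(model, medium = medium)
  success <- growth$status == "optimal" &&
    growth$objective > params$flux_tol
  if (!success) {
    stop("biomass unreachable after step 1 (growth ",
         format(growth$objective), "); the universal model cannot close ",
         "the remaining gaps on this medium", call. = FALSE)
  }
  list(model = model,
       report = report_entry(1L, draft$objective, medium_label,
                             res$added, success))
}

# Core-restricted gap-fill toward an objective; returns adopted model and
# the added set (empty when the objective stays infeasible/zero).
core_gapfill_once <- function(model, universal, core, evidence, objective,
                              medium, params, code) {
  merged <- merge_models(universal, model)
  res <- tryCatch(
    weighted_gapfill_lp(merged, model$rxns$id, evidence, objective,
                        medium, params, candidates = core),
    error = function(e) NULL)
  if (is.null(res) || res$solution$objective <= params$flux_tol) {
    return(list(model = model, added = character(), reached = FALSE))
  }
  list(model = adopt_reactions(model, merged, res$added, code, evidence),
       added = res$added, reached = TRUE)
}

#' Gap-filling step 2: individual biomass components
#'
#' For every biomass component, a temporary sink becomes the objective
#' on a minimal medium (with and without oxygen) and the gap-filler may
#' add core reactions only (gs_origin 2).  Components whose production
#' would require non-core reactions stay unresolved and are reported,
#' not fatal.
#'
#' @param model model after step 1.
#' @param universal universal model.
#' @param core core reaction ids (see \code{\link{core_reactions}}).
#' @param evidence an \code{evidence_table}.
#' @param minimal_medium M9-like minimal medium including a carbon
#'   source (glucose by convention).
#' @param params a \code{\link{gapfill_params}} object.
#' @return List with \code{model}, \code{report}, and
#'   \code{unresolved_components}.
#' @export
gapfill_step2_biomass_components <- function(model, universal, core,
                                             evidence, minimal_medium,
                                             params = gapfill_params()) {
  bio_sto <- model$stoich[[model$objective]]
  comps <- names(bio_sto)[bio_sto < 0]
  comps <- setdiff(comps, c("atp_c0", "h2o_c0"))   # growth ATP, not parts
  media <- list(aerobic = minimal_medium,
                anaerobic = minimal_medium[names(minimal_medium) != "o2_e0"])
  added_all <- character()
  unresolved <- character()
  for (comp in comps) {
    reached_any <- FALSE
    for (mlab in names(media)) {
      sink_id <- paste0("TMP_SINK_", comp)
      work <- add_reaction(model, sink_id, stats::setNames(-1, comp),
                           0, DEFAULT_BOUND, name = "temporary sink")
      r <- core_gapfill_once(work, universal, core, evidence, sink_id,
                             media[[mlab]], params, 2L)
      if (r$reached) {
        reached_any <- TRUE
        model <- remove_reactions(r$model, sink_id)
        model <- set_objective(model, "bio1")
        added_all <- union(added_all, r$added)
      }
    }
    if (!reached_any) unresolved <- c(unresolved, comp)
  }
  list(model = model,
       report = report_entry(2L, "biomass components", "minimal(+/-O2)",
                             sort(added_all), length(unresolved) == 0,
                             note = paste(unresolved, collapse = ";")),
       unresolved_components = unresolved)
}

#' Gap-filling step 3: alternative energy sources
#'
#' For each substance, the model is put on a minimal medium with that
#' substance as the only organic substrate, the three temporary
#' electron-carrier recycling reactions (ESP1-3) are inserted, and the
#' summed ESP flux is gap-filled using core reactions only (gs_origin
#' 3).  The temporary reactions are removed afterwards.
#'
#' @inheritParams gapfill_step2_biomass_components
#' @param substances character vector of substance names.
#' @param substance_map see \code{\link{load_substance_map}}.
#' @param mineral_medium the inorganic part of the minimal medium (no
#'   carbon source).
#' @param uptake_rate uptake rate granted to the focal substance.
#' @return List with \code{model}, \code{report}, \code{utilised}
#'   (substances whose ESP flux became positive).
#' @export
gapfill_step3_energy_sources <- function(model, universal, core, evidence,
                                         substances, substance_map,
                                         mineral_medium,
                                         params = gapfill_params(),
                                         uptake_rate = 10) {
  esp_ids <- names(esp_reactions())
  added_all <- character()
  utilised <- character()
  for (s in substances) {
    k <- match(s, substance_map$name)
    if (is.na(k)) next
    ex_met <- sub("^EX_", "", substance_map$exchange_id[k])
    if (!substance_map$exchange_id[k] %in% universal$rxns$id) next
    med <- c(mineral_medium, stats::setNames(uptake_rate, ex_met))
    work <- add_esp_reactions(model)
    r <- core_gapfill_once(work, add_esp_reactions(universal), core,
                           evidence, esp_ids, med, params, 3L)
    got <- setdiff(r$added, esp_ids)
    if (r$reached) {
      utilised <- c(utilised, s)
      model <- remove_reactions(r$model, esp_ids)
      model <- set_objective(model, "bio1")
      added_all <- union(added_all, got)
    }
  }
  list(model = model,
       report = report_entry(3L, "ESP1+ESP2+ESP3", "minimal+substance",
                             sort(added_all), TRUE,
                             note = paste(utilised, collapse = ";")),
       utilised = utilised)
}

#' Gap-filling step 4: metabolic products
#'
#' For each substance, secretion through its exchange reaction is
#' maximised on the original gap-filling medium; core reactions carrying
#' flux are adopted (gs_origin 4).
#'
#' @inheritParams gapfill_step3_energy_sources
#' @param medium the original gap-filling medium.
#' @return List with \code{model}, \code{report}, \code{producible}.
#' @export
gapfill_step4_products <- function(model, universal, core, evidence,
                                   substances, substance_map, medium,
                                   params = gapfill_params()) {
  added_all <- character()
  producible <- character()
  for (s in substances) {
    k <- match(s, substance_map$name)
    if (is.na(k)) next
    exid <- substance_map$exchange_id[k]
    if (!exid %in% universal$rxns$id) next
    r <- core_gapfill_once(model, universal, core, evidence, exid,
                           medium, params, 4L)
    if (r$reached) {
      producible <- c(producible, s)
      model <- r$model
      added_all <- union(added_all, r$added)
    }
  }
  list(model = model,
       report = report_entry(4L, "product exchanges", "gapfill",
                             sort(added_all), TRUE,
                             note = paste(producible, collapse = ";")),
       producible = producible)
}

#' Run the full gap-filling protocol
#'
#' Step 1 (biomass on the gap-filling medium, full universal source),
#' then, unless \code{biomass_only}, steps 2-4 restricted to core
#' reactions: individual biomass components (with and without O2),
#' alternative energy sources (ESP test), and product formation.
#'
#' @param draft draft model with biomass objective.
#' @param universal universal model.
#' @param evidence an \code{evidence_table}.
#' @param medium gap-filling medium; \code{NULL} means complete medium
#'   (all exchanges open at rate 100).
#' @param minimal_medium M9-like minimal medium for steps 2-3.
#' @param substances substance names for steps 3-4.
#' @param substance_map see \code{\link{load_substance_map}}.
#' @param params a \code{\link{gapfill_params}} object.
#' @param biomass_only run step 1 only (the driver's \code{-q} mode).
#' @return List with \code{model}, \code{report} (data frame over
#'   steps), \code{unresolved_components}, \code{utilised},
#'   \code{producible}.
#' @export
gapfill_protocol <- function(draft, universal, evidence, medium = NULL,
                             minimal_medium = NULL, substances = character(),
                             substance_map = NULL,
                             params = gapfill_params(),
                             biomass_only = FALSE) {
  if (is.null(medium)) medium <- c("*" = 100)
  s1 <- gapfill_step1_biomass(draft, universal, medium, evidence, params)
  model <- s1$model
  report <- s1$report
  unresolved <- character(); utilised <- character(); producible <- character()
  if (!biomass_only) {
    core <- core_reactions(evidence, params)
    if (is.null(minimal_medium)) minimal_medium <- medium
    s2 <- gapfill_step2_biomass_components(model, universal, core,
                                           evidence, minimal_medium, params)
    model <- s2$model
    report <- rbind(report, s2$report)
    unresolved <- s2$unresolved_components
    if (!is.null(substance_map) && length(substances) > 0) {
      # Inorganic base: the minimal medium stripped of oxygen and of any
      # substance-map compound (the focal substance is added per test).
      mineral <- minimal_medium[!names(minimal_medium) %in%
                                  c("o2_e0",
                                    sub("^EX_", "", substance_map$exchange_id))]
      s3 <- gapfill_step3_energy_sources(model, universal, core, evidence,
                                         substances, substance_map,
                                         mineral, params)
      model <- s3$model
      report <- rbind(report, s3$report)
      utilised <- s3$utilised
      s4 <- gapfill_step4_products(model, universal, core, evidence,
                                   substances, substance_map, medium,
                                   params)
      model <- s4$model
      report <- rbind(report, s4$report)
      producible <- s4$producible
    }
  }
  list(model = model, report = report,
       unresolved_components = unresolved,
       utilised = utilised, producible = producible)
}
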