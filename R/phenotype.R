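# Phenotype prediction on finished models: carbon-source utilisation
# (BIOLOG-like electron-sink test), fermentation product profiles
# (MTF + FVA), and single-gene-deletion essentiality via GPR evaluation.

#' Carbon-source utilisation test
#'
#' Inserts the three temporary electron-carrier recycling reactions
#' (ESP1-3, see \code{\link{esp_reactions}}), restricts uptake to the
#' mineral medium plus the focal substance, and maximises the summed
#' recycling flux.  The substance can serve as energy source when at
#' least one recycling reaction carries positive flux.  The input model
#' is not modified; all secretion bounds stay open.
#'
#' @param model a \code{metabolic_model}.
#' @param minimal_medium named uptake vector of the mineral base medium
#'   (no organic carbon source).
#' @param substance substance name resolvable in \code{substance_map}.
#' @param substance_map see \code{\link{load_substance_map}}.
#' @param uptake_rate uptake granted to the substance (default 10).
#' @param tol positive-flux tolerance (default 1e-6).
#' @return List with \code{utilisable} (flag), \code{esp_flux} (summed
#'   recycling flux) and \code{status}.
#' @export
test_carbon_source <- function(model, minimal_medium, substance,
                               substance_map, uptake_rate = 10,
                               tol = 1e-6) {
  k <- match(substance, substance_map$name)
  if (is.na(k)) stop("unknown substance: ", substance, call. = FALSE)
  exid <- substance_map$exchange_id[k]
  if (!exid %in% model$rxns$id) {
    stop("no exchange reaction for substance '", substance, "' (", exid,
         ")", call. = FALSE)
  }
  med <- c(minimal_medium,
           stats::setNames(uptake_rate, sub("^EX_", "", exid)))
  work <- add_esp_reactions(model)
  esp_present <- intersect(names(esp_reactions()), work$rxns$id)
  sol <- fba(work, medium = med, objective = esp_present)
  flux <- if (sol$status == "optimal") sol$objective else 0
  list(utilisable = sol$status == "optimal" && flux > tol,
       esp_flux = flux, status = sol$status)
}

#' Predict fermentation products
#'
#' Runs FBA coupled with minimisation of total flux (MTF) on the given
#' (typically anaerobic) medium; exchange reactions with positive flux
#' are the predicted products.  Release rates (mmol/gDW/h) are
#' normalised by the growth rate (1/h) to mmol per gram dry weight, and
#' flux variability analysis gives each product's maximal release across
#' all optimal solutions.
#'
#' @param model a \code{metabolic_model} with biomass objective.
#' @param medium named uptake vector.
#' @param tol product-reporting flux tolerance (default 1e-6).
#' @return A data frame (class \code{fermentation_profile}) with columns
#'   \code{exchange}, \code{metabolite}, \code{mtf_release_mmol_per_gDW},
#'   \code{fva_max_mmol_per_gDW}; attribute \code{"growth"} holds the
#'   growth rate (1/h).
#' @export
predict_fermentation_products <- function(model, medium, tol = 1e-6) {
  sol <- mtf(model, medium = medium)
  if (sol$status != "optimal") {
    stop("no feasible growth on the given medium (", sol$status, ")",
         call. = FALSE)
  }
  mu <- sol$fluxes[[model$objective]]
  if (mu < 1e-6) {
    stop("no growth; normalisation by growth rate undefined", call. = FALSE)
  }
  ex <- exchange_ids(model)
  pos <- ex[sol$fluxes[ex] > tol]
  fv <- if (length(pos) > 0) {
    fva(model, medium = medium, reactions = pos)
  } else {
    data.frame(id = character(), min = numeric(), max = numeric())
  }
  out <- data.frame(
    exchange = pos,
    metabolite = sub("^EX_", "", pos),
    mtf_release_mmol_per_gDW = unname(sol$fluxes[pos]) / mu,
    fva_max_mmol_per_gDW = fv$max[match(pos, fv$id)] / mu,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "growth") <- mu
  class(out) <- c("fermentation_profile", class(out))
  out
}

#' Single-gene deletion essentiality screen
#'
#' For every gene, all reactions whose GPR evaluates to FALSE under the
#' deletion are closed (both bounds zero) and growth is recomputed by
#' FBA.  A gene is conditionally essential on the given medium when the
#' growth rate drops below the threshold (default 0.01 1/h).
#'
#' @param model a \code{metabolic_model} with GPRs and biomass objective.
#' @param medium named uptake vector.
#' @param growth_threshold essentiality cutoff in 1/h (default 0.01).
#' @param genes genes to screen (default: all genes in the model).
#' @return Data frame with columns \code{gene}, \code{growth},
#'   \code{essential}; attribute \code{"wild_type_growth"}.
#' @export
single_gene_deletions <- function(model, medium,
                                  growth_threshold = 0.01,
                                  genes = model_genes(model)) {
  model <- apply_medium(model, medium)
  wt <- fba(model)
  wt_growth <- if (wt$status == "optimal") wt$objective else 0
  has_gpr <- which(nzchar(model$rxns$gpr))
  asts <- lapply(model$rxns$gpr[has_gpr], gpr_parse)
  growth <- numeric(length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    m <- model
    for (j in seq_along(has_gpr)) {
      gl <- gpr_ast_genes(asts[[j]])
      if (!g %in% gl) next
      present <- as.list(stats::setNames(gl != g, gl))
      if (!gpr_ast_eval(asts[[j]], present)) {
        k <- has_gpr[j]
        m$rxns$lb[k] <- 0
        m$rxns$ub[k] <- 0
      }
    }
    s <- fba(m)
    growth[gi] <- if (s$status == "optimal") s$objective else 0
  }
  out <- data.frame(gene = genes, growth = growth,
                    essential = growth < growth_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "wild_type_growth") <- wt_growth
  out
}

#' Contingency-table metrics for phenotype benchmarks
#'
#' @param predicted,observed logical vectors of equal length.
#' @return List with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{sensitivity}, \code{specificity}, \code{accuracy}.
#' @export
phenotype_confusion <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  tp <- sum(predicted & observed)
  fp <- sum(predicted & !observed)
  tn <- sum(!predicted & !observed)
  fn <- sum(!predicted & observed)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(predicted))
}
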