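# Network-similarity score for models built from fragmented
# (metagenome-derived) genomes against a panel of reference models:
# frequency-weighted recall of the gene-associated reference reactions.

# Gene-associated reactions: non-empty GPR; biomass, exchange and
# diffusion pseudo-reactions never carry one.
gene_associated_reactions <- function(model) {
  sort(model$rxns$id[nzchar(model$rxns$gpr) & !model$rxns$is_exchange],
       method = "radix")
}

#' Reference reaction frequencies over a model panel
#'
#' Over the union set of gene-associated reactions of the reference
#' models, the frequency of each reaction is the fraction of reference
#' models containing it.
#'
#' @param reference_models list of \code{metabolic_model}s (>= 1).
#' @return Named numeric vector b_i in (0, 1].
#' @export
reference_reaction_frequencies <- function(reference_models) {
  if (length(reference_models) == 0) {
    stop("empty reference panel", call. = FALSE)
  }
  sets <- lapply(reference_models, gene_associated_reactions)
  union_set <- sort(unique(unlist(sets)), method = "radix")
  counts <- vapply(union_set, function(r)
    sum(vapply(sets, function(s) r %in% s, TRUE)), 1)
  counts / length(reference_models)
}

#' Frequency-weighted network similarity score
#'
#' Computes  T = sum_i a_i b_i / sum_i b_i  over the union set of
#' gene-associated reference reactions, where b_i is the reaction's
#' frequency among the reference models and a_i indicates membership in
#' the query (SGB) model.  The score is 1 when the query covers the
#' whole union set and 0 when it covers none of it; reactions outside
#' the union set do not influence it.
#'
#' @param sgb_model the query \code{metabolic_model}.
#' @param reference_models list of reference models.
#' @return List of class \code{tsgb_result}: \code{score}, \code{b}
#'   (frequencies), \code{a} (membership 0/1), \code{union_size}.
#' @export
tsgb_score <- function(sgb_model, reference_models) {
  b <- reference_reaction_frequencies(reference_models)
  if (sum(b) == 0) stop("undefined score: sum of frequencies is zero",
                        call. = FALSE)
  a <- as.integer(names(b) %in% sgb_model$rxns$id)
  names(a) <- names(b)
  structure(list(score = sum(a * b) / sum(b), b = b, a = a,
                 union_size = length(b)),
            class = "tsgb_result")
}

#' @export
print.tsgb_result <- function(x, ...) {
  cat("T_SGB =", format(x$score, digits = 6), "over", x$union_size,
      "gene-associated union reactions\n")
  invisible(x)
}
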