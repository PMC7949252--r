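# Protein complex prediction: subunit structure is mined from reference
# FASTA headers; a complex counts as present when more than half of its
# recognised subunits have a passing hit (undefined-subunit hits break
# exact ties).

GREEK_LETTERS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                   "eta", "theta", "iota", "kappa", "lambda", "mu", "nu",
                   "xi", "omicron", "pi", "rho", "sigma", "tau", "upsilon",
                   "phi", "chi", "psi", "omega")
GREEK_UNICODE <- strsplit("αβγδεζηθικλμνξοπρστυφχψω", "")[[1]]
ROMAN_NUMERALS <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix",
                    "x", "xi", "xii", "xiii", "xiv", "xv", "xvi", "xvii",
                    "xviii", "xix", "xx")
SUBUNIT_KEYWORDS <- c("subunit", "chain", "polypeptide", "component")

#' Homogenise a subunit numbering fragment to a canonical label
#'
#' Roman numerals (I-XX), greek letters (spelled out or unicode), latin
#' letters A-H and arabic numerals all map onto the same arabic
#' canonical labels, so that e.g. "subunit II", "subunit beta" and
#' "subunit 2" are recognised as the same subunit.  Case-insensitive.
#'
#' @param raw_header_fragment text following a subunit keyword.
#' @return Canonical label \code{"subunit <n>"}, or \code{NA_character_}
#'   when the fragment carries no recognisable numbering.
#' @export
homogenise_subunit_label <- function(raw_header_fragment) {
  frag <- tolower(trimws(raw_header_fragment))
  tok <- regmatches(frag, regexpr("^[a-z0-9α-ω]+", frag))
  if (length(tok) == 0 || !nzchar(tok)) return(NA_character_)
  n <- NA_integer_
  if (grepl("^[0-9]+$", tok)) {
    n <- as.integer(tok)
  } else if (tok %in% ROMAN_NUMERALS) {
    n <- match(tok, ROMAN_NUMERALS)
  } else if (tok %in% GREEK_LETTERS) {
    n <- match(tok, GREEK_LETTERS)
  } else if (tok %in% GREEK_UNICODE) {
    n <- match(tok, GREEK_UNICODE)
  } else if (nchar(tok) == 1 && tok %in% letters[1:8]) {
    n <- match(tok, letters[1:8])
  }
  if (is.na(n) || n < 1) return(NA_character_)
  paste("subunit", n)
}

# Canonical label for one FASTA header, or NA.  The first keyword
# occurrence wins; matching is case-insensitive.
header_subunit_label <- function(header) {
  h <- tolower(header)
  pat <- paste0("\\b(", paste(SUBUNIT_KEYWORDS, collapse = "|"), ")\\b")
  m <- regexpr(pat, h)
  if (m < 0) return(NA_character_)
  frag <- substr(h, m + attr(m, "match.length"), nchar(h))
  homogenise_subunit_label(frag)
}

#' Extract the subunit catalog of a reaction's reference sequences
#'
#' Counts canonical subunit labels over the FASTA headers.  Labels seen
#' fewer than \code{min_count} times are demoted to the undefined pool
#' (text-matching artefact guard); if after that one label covers at
#' least \code{dominance} of the labelled entries, all other labels are
#' demoted too.  Unlabelled entries count as "undefined subunit" and do
#' not add to the total number of subunits.
#'
#' @param fasta_headers character vector of FASTA header lines (with or
#'   without the leading \code{">"}).
#' @param reaction_id the reaction the sequences support.
#' @param min_count minimum label frequency (default 5).
#' @param dominance dominance fraction (default 2/3), evaluated over
#'   labelled entries after the \code{min_count} demotion.
#' @return A \code{subunit_catalog}: list with \code{reaction_id},
#'   \code{counts} (named integer per kept label), \code{undefined_count},
#'   and per-header \code{labels} (kept canonical label or NA).
#' @export
parse_subunits <- function(fasta_headers, reaction_id,
                           min_count = 5, dominance = 2 / 3) {
  headers <- sub("^>", "", fasta_headers)
  labels <- vapply(headers, header_subunit_label, "", USE.NAMES = FALSE)
  lab <- labels[!is.na(labels)]
  counts <- table(lab)
  keep <- names(counts)[counts >= min_count]
  labels[!labels %in% keep] <- NA_character_
  counts <- counts[keep]
  if (length(counts) > 1) {
    tot <- sum(counts)
    domlab <- names(counts)[counts / tot >= dominance]
    if (length(domlab) >= 1) {
      keep <- domlab[1]
      labels[!is.na(labels) & labels != keep] <- NA_character_
      counts <- counts[keep]
    }
  }
  cnt <- stats::setNames(as.integer(counts), names(counts))
  if (length(cnt) > 0) cnt <- cnt[order(names(cnt))]
  structure(list(reaction_id = reaction_id,
                 counts = cnt,
                 undefined_count = sum(is.na(labels)),
                 labels = labels),
            class = "subunit_catalog")
}

#' Call protein-complex presence from per-subunit hits
#'
#' A subunit is "found" when its best hit passes
#' \code{\link{call_match}}.  The complex is present when more than 50%
#' of the recognised subunits are found, or exactly 50% are found and at
#' least one hit from the undefined-subunit pool also passes (undefined
#' hits tip the balance, but only as a positive signal).  With zero
#' recognised subunits the reaction falls back to ordinary
#' single-sequence matching: present iff any pool hit passes.
#'
#' @param catalog a \code{\link{parse_subunits}} result.
#' @param per_subunit_best_hits named list: canonical subunit label ->
#'   best hit (list/row with bitscore, coverage_pct, identity_pct), plus
#'   optional element \code{"undefined"} for the undefined pool; missing
#'   entries mean no hit.
#' @param thresholds a \code{\link{match_thresholds}} object.
#' @return A \code{complex_call}: list with \code{reaction_id},
#'   \code{n_subunits_recognized}, \code{n_subunits_found},
#'   \code{undefined_hit}, \code{present}.
#' @export
call_complex_presence <- function(catalog, per_subunit_best_hits,
                                  thresholds = match_thresholds()) {
  labs <- names(catalog$counts)
  pass <- function(h) !is.null(h) && call_match(h, thresholds)
  found <- vapply(labs, function(l) pass(per_subunit_best_hits[[l]]), TRUE)
  undef_hit <- pass(per_subunit_best_hits[["undefined"]])
  n_rec <- length(labs)
  n_found <- sum(found)
  present <- if (n_rec == 0) {
    undef_hit   # ordinary single-sequence matching fallback
  } else {
    frac <- n_found / n_rec
    frac > 0.5 || (frac == 0.5 && undef_hit)
  }
  structure(list(reaction_id = catalog$reaction_id,
                 n_subunits_recognized = n_rec,
                 n_subunits_found = n_found,
                 undefined_hit = undef_hit,
                 present = present),
            class = "complex_call")
}

#' Predict complex presence for all reactions with subunit-labelled hits
#'
#' Groups a hit table by reaction, treats the hits' subunit labels as the
#' catalog source, and calls presence per reaction.  Reactions whose hits
#' carry no subunit labels are skipped (ordinary matching applies).
#'
#' @param hits hit data frame (native dialect).
#' @param catalogs named list of \code{subunit_catalog}s by reaction id.
#' @param thresholds a \code{\link{match_thresholds}} object.
#' @return Named list of \code{complex_call}s by reaction id.
#' @export
predict_complexes <- function(hits, catalogs,
                              thresholds = match_thresholds()) {
  ex <- expand_hits(hits)
  out <- list()
  for (rid in names(catalogs)) {
    cat_r <- catalogs[[rid]]
    sub <- ex[ex$reaction_id == rid, , drop = FALSE]
    best <- list()
    pool_labels <- c(names(cat_r$counts), "undefined")
    for (l in pool_labels) {
      rows <- if (l == "undefined") {
        sub[is.na(sub$subunit_label) | !sub$subunit_label %in% names(cat_r$counts), , drop = FALSE]
      } else {
        sub[!is.na(sub$subunit_label) & sub$subunit_label == l, , drop = FALSE]
      }
      if (nrow(rows) > 0) best[[l]] <- rows[which.max(rows$bitscore), ]
    }
    out[[rid]] <- call_complex_presence(cat_r, best, thresholds)
  }
  out
}

#' Dump a subunit catalog as a data frame (inspection/TSV export)
#' @param catalog a \code{subunit_catalog}.
#' @return Data frame with label and count rows plus the undefined pool.
#' @export
catalog_as_table <- function(catalog) {
  data.frame(reaction_id = catalog$reaction_id,
             label = c(names(catalog$counts), "undefined subunit"),
             count = c(as.integer(catalog$counts), catalog$undefined_count),
             stringsAsFactors = FALSE)
}
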