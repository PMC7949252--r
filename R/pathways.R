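# Pathway/subsystem presence calling from per-reaction evidence:
# completeness thresholds, key-reaction relaxation, vague-reaction rule.

#' Pathway-calling parameters
#'
#' @param completeness_cutoff_no_hints completeness needed without key
#'   reactions (default 0.80).
#' @param completeness_cutoff completeness needed when all key reactions
#'   are found (default 2/3).
#' @param vague_cutoff if the vague fraction is strictly below this,
#'   vague reactions are excluded from the denominator instead of
#'   counting as missing (default 1/3).
#' @return A list of class \code{pathway_params}.
#' @export
pathway_params <- function(completeness_cutoff_no_hints = 0.80,
                           completeness_cutoff = 2 / 3,
                           vague_cutoff = 1 / 3) {
  stopifnot(completeness_cutoff_no_hints > 0,
            completeness_cutoff_no_hints <= 1,
            completeness_cutoff > 0, completeness_cutoff <= 1,
            vague_cutoff >= 0, vague_cutoff <= 1)
  structure(list(completeness_cutoff_no_hints = completeness_cutoff_no_hints,
                 completeness_cutoff = completeness_cutoff,
                 vague_cutoff = vague_cutoff),
            class = "pathway_params")
}

#' Load pathway definitions from TSV
#'
#' Columns: \code{pathway_id}, \code{name}, \code{reaction_id},
#' \code{ec}, \code{key} (0/1), \code{spontaneous} (0/1), \code{has_seq}
#' (0/1; 0 marks reactions without reference sequences, i.e. "vague").
#' One row per pathway entry.
#'
#' @param path path to the TSV file.
#' @return Named list of pathway definitions, each a list with
#'   \code{id}, \code{name}, \code{entries} (data frame).
#' @export
load_pathway_db <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("pathway_id", "name", "reaction_id", "ec", "key",
            "spontaneous", "has_seq")
  if (!all(need %in% names(raw))) {
    stop("pathway table missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (pid in unique(raw$pathway_id)) {
    sub <- raw[raw$pathway_id == pid, , drop = FALSE]
    entries <- data.frame(reaction_id = sub$reaction_id, ec = sub$ec,
                          key = sub$key == "1",
                          spontaneous = sub$spontaneous == "1",
                          has_seq = sub$has_seq == "1",
                          stringsAsFactors = FALSE)
    if (nrow(entries) == 0) stop("empty pathway: ", pid, call. = FALSE)
    out[[pid]] <- list(id = pid, name = sub$name[1], entries = entries)
  }
  out
}

#' Classify the evidence status of one pathway entry
#'
#' Spontaneous reactions are present in any case; entries without
#' reference sequences are "vague"; entries with a matching hit (single
#' sequence or complex presence) are "found"; everything else "missing".
#'
#' @param entry one row of a pathway definition (list or 1-row data
#'   frame with \code{reaction_id}, \code{spontaneous}, \code{has_seq}).
#' @param evidence an \code{evidence_table} or \code{NULL}.
#' @param complex_calls named list of \code{complex_call}s (optional).
#' @return One of \code{"spontaneous"}, \code{"vague"}, \code{"found"},
#'   \code{"missing"}.
#' @export
classify_reaction_status <- function(entry, evidence, complex_calls = NULL) {
  if (isTRUE(entry$spontaneous)) return("spontaneous")
  if (!isTRUE(entry$has_seq)) return("vague")
  rid <- entry$reaction_id
  cc <- complex_calls[[rid]]
  matched <- if (!is.null(cc)) {
    isTRUE(cc$present)
  } else {
    evidence_matched(evidence, rid)
  }
  if (matched) "found" else "missing"
}

#' Pathway completeness fraction
#'
#' Found and spontaneous entries count as present.  When the vague
#' fraction v/n is strictly below the vague cutoff, vague entries are
#' excluded from the denominator (they do not count as missing);
#' otherwise they stay in the denominator.
#'
#' @param statuses character vector of per-entry statuses.
#' @param params a \code{\link{pathway_params}} object.
#' @return Completeness in [0, 1].
#' @export
pathway_completeness <- function(statuses, params = pathway_params()) {
  n <- length(statuses)
  if (n == 0) stop("empty status vector", call. = FALSE)
  f <- sum(statuses %in% c("found", "spontaneous"))
  v <- sum(statuses == "vague")
  if (v / n < params$vague_cutoff && n > v) f / (n - v) else f / n
}

#' Call pathway presence
#'
#' Present when completeness reaches
#' \code{completeness_cutoff_no_hints}, or when the pathway has key
#' reactions, every key reaction has status "found" (strictly; vague or
#' spontaneous keys do not count), and completeness reaches the relaxed
#' \code{completeness_cutoff}.
#'
#' @param pwy a pathway definition (see \code{\link{load_pathway_db}}).
#' @param statuses per-entry statuses aligned with \code{pwy$entries}.
#' @param params a \code{\link{pathway_params}} object.
#' @return A \code{pathway_call}: list with \code{pathway_id},
#'   \code{statuses}, \code{completeness}, \code{keys_all_found},
#'   \code{present}.
#' @export
call_pathway_presence <- function(pwy, statuses, params = pathway_params()) {
  stopifnot(length(statuses) == nrow(pwy$entries))
  comp <- pathway_completeness(statuses, params)
  keys <- which(pwy$entries$key)
  keys_all_found <- length(keys) > 0 && all(statuses[keys] == "found")
  present <- comp >= params$completeness_cutoff_no_hints ||
    (keys_all_found && comp >= params$completeness_cutoff)
  structure(list(pathway_id = pwy$id,
                 statuses = stats::setNames(statuses, pwy$entries$reaction_id),
                 completeness = comp,
                 keys_all_found = keys_all_found,
                 present = present),
            class = "pathway_call")
}

#' Predict presence for every pathway in a database
#'
#' @param pathway_db named list from \code{\link{load_pathway_db}}.
#' @param evidence an \code{evidence_table} or \code{NULL}.
#' @param complex_calls named list of \code{complex_call}s (optional).
#' @param params a \code{\link{pathway_params}} object.
#' @return Named list of \code{pathway_call}s in lexicographic pathway
#'   id order.
#' @export
predict_pathways <- function(pathway_db, evidence, complex_calls = NULL,
                             params = pathway_params()) {
  out <- list()
  for (pid in sort(names(pathway_db), method = "radix")) {
    pwy <- pathway_db[[pid]]
    statuses <- vapply(seq_len(nrow(pwy$entries)), function(i)
      classify_reaction_status(pwy$entries[i, ], evidence, complex_calls),
      "")
    out[[pid]] <- call_pathway_presence(pwy, statuses, params)
  }
  out
}

#' Pathway calls as a summary table
#'
#' Mirrors a "find"-style prediction output: pathway, presence status,
#' completeness, found/total counts and whether all keys were found.
#'
#' @param calls named list of \code{pathway_call}s.
#' @return Data frame, one row per pathway.
#' @export
pathway_calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(pathway = cl$pathway_id,
               status = if (cl$present) "present" else "absent",
               completeness = cl$completeness,
               found = sum(cl$statuses %in% c("found", "spontaneous")),
               total = length(cl$statuses),
               keys_found = cl$keys_all_found,
               stringsAsFactors = FALSE)
  }))
}
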