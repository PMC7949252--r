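# Homology evidence: hit tables, match calls, per-reaction evidence
# scores b_i feeding the gap-filling weights.

#' Matching thresholds for homology hits
#'
#' @param min_bitscore minimum bitscore for a match (default 200 bits).
#' @param min_coverage_pct minimum reference coverage (default 75%).
#' @param exceptions named list: reaction id -> list of additional
#'   per-reaction criteria (currently \code{min_identity_pct}).
#' @return A list of class \code{match_thresholds}.
#' @export
match_thresholds <- function(min_bitscore = 200, min_coverage_pct = 75,
                             exceptions = list()) {
  stopifnot(min_bitscore >= 0, min_coverage_pct >= 0)
  structure(list(min_bitscore = min_bitscore,
                 min_coverage_pct = min_coverage_pct,
                 exceptions = exceptions),
            class = "match_thresholds")
}

#' Parse a homology hit table
#'
#' Native dialect: TSV with columns \code{ref_seq_id},
#' \code{reaction_ids} (semicolon-separated), \code{bitscore},
#' \code{coverage_pct}, \code{identity_pct}, \code{subunit_label} (empty
#' = no recognised subunit).  Invalid rows (negative bitscore, coverage or
#' identity outside [0,100]) abort with the offending row number.
#'
#' @param path path to the TSV file.
#' @return Data frame of hits, one row per reference sequence.
#' @export
parse_hit_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("ref_seq_id", "reaction_ids", "bitscore", "coverage_pct",
            "identity_pct", "subunit_label")
  if (!all(need %in% names(raw))) {
    stop("hit table missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(data.frame(ref_seq_id = character(), reaction_ids = character(),
                      bitscore = numeric(), coverage_pct = numeric(),
                      identity_pct = numeric(), subunit_label = character(),
                      stringsAsFactors = FALSE))
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  hits <- data.frame(ref_seq_id = raw$ref_seq_id,
                     reaction_ids = raw$reaction_ids,
                     bitscore = num("bitscore"),
                     coverage_pct = num("coverage_pct"),
                     identity_pct = num("identity_pct"),
                     subunit_label = raw$subunit_label,
                     stringsAsFactors = FALSE)
  bad <- which(is.na(hits$bitscore) | hits$bitscore < 0 |
               is.na(hits$coverage_pct) | hits$coverage_pct < 0 |
               hits$coverage_pct > 100 |
               is.na(hits$identity_pct) | hits$identity_pct < 0 |
               hits$identity_pct > 100)
  if (length(bad) > 0) {
    stop("invalid hit table row(s): ",
         paste(bad + 1L, collapse = ", "),
         " (bitscore must be >= 0, coverage/identity within [0,100])",
         call. = FALSE)
  }
  hits
}

#' Parse 12-column tabular alignment output with a sidecar mapping
#'
#' Accepts the standard 12-column tabular alignment format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore).  The sidecar TSV maps query sequence ids to reaction ids
#' and gives the reference length used to compute coverage
#' (alignment length / reference length).
#'
#' @param path alignment file (no header, 12 tab-separated columns).
#' @param mapping_path sidecar TSV with columns \code{seq_id},
#'   \code{reaction_ids}, \code{ref_length}, and optional
#'   \code{subunit_label}.
#' @return Data frame in the native hit dialect (see
#'   \code{\link{parse_hit_table}}).
#' @export
parse_blast_table <- function(path, mapping_path) {
  aln <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(aln) != 12) {
    stop("expected 12 tab-separated columns, got ", ncol(aln), call. = FALSE)
  }
  names(aln) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  map <- utils::read.delim(mapping_path, stringsAsFactors = FALSE)
  need <- c("seq_id", "reaction_ids", "ref_length")
  if (!all(need %in% names(map))) {
    stop("mapping file missing columns: ",
         paste(setdiff(need, names(map)), collapse = ", "), call. = FALSE)
  }
  idx <- match(aln$qseqid, map$seq_id)
  if (anyNA(idx)) {
    stop("alignment queries missing from mapping: ",
         paste(unique(aln$qseqid[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  data.frame(ref_seq_id = aln$qseqid,
             reaction_ids = map$reaction_ids[idx],
             bitscore = aln$bitscore,
             coverage_pct = pmin(100, 100 * aln$length / map$ref_length[idx]),
             identity_pct = aln$pident,
             subunit_label = if ("subunit_label" %in% names(map))
               ifelse(is.na(map$subunit_label[idx]), "", map$subunit_label[idx])
             else "",
             stringsAsFactors = FALSE)
}

# One row per (hit, reaction) pair.
expand_hits <- function(hits) {
  if (nrow(hits) == 0) {
    return(cbind(hits[0, ], data.frame(reaction_id = character())))
  }
  rl <- strsplit(hits$reaction_ids, ";", fixed = TRUE)
  n <- vapply(rl, length, 1L)
  out <- hits[rep(seq_len(nrow(hits)), n), , drop = FALSE]
  out$reaction_id <- unlist(rl)
  rownames(out) <- NULL
  out
}

#' Decide whether a single hit is a match
#'
#' A hit matches when its bitscore and coverage reach the thresholds and,
#' for reactions with registered exceptions, every additional criterion
#' (e.g. minimum identity) also holds.
#'
#' @param hit a single-row data frame or list with \code{bitscore},
#'   \code{coverage_pct}, \code{identity_pct} and optionally
#'   \code{reaction_id} (needed for exception lookup).
#' @param thresholds a \code{\link{match_thresholds}} object.
#' @return Logical flag.
#' @export
call_match <- function(hit, thresholds = match_thresholds()) {
  ok <- hit$bitscore >= thresholds$min_bitscore &&
    hit$coverage_pct >= thresholds$min_coverage_pct
  rid <- if (!is.null(hit$reaction_id)) hit$reaction_id else NULL
  if (ok && !is.null(rid) && rid %in% names(thresholds$exceptions)) {
    exc <- thresholds$exceptions[[rid]]
    if (!is.null(exc$min_identity_pct)) {
      ok <- ok && !is.na(hit$identity_pct) &&
        hit$identity_pct >= exc$min_identity_pct
    }
  }
  isTRUE(ok)
}

#' Reduce hits to a per-reaction evidence table
#'
#' For every reaction mapped by at least one hit: \code{best_bitscore}
#' b_i is the maximum bitscore over all hits regardless of coverage
#' (coverage gates only the binary match call), and \code{matched} is
#' TRUE when at least one hit passes \code{\link{call_match}}.
#' Reference sequences mapping to several reactions contribute their
#' bitscore to each of them.
#'
#' @param hits data frame from \code{\link{parse_hit_table}}.
#' @param thresholds a \code{\link{match_thresholds}} object.
#' @return An object of class \code{evidence_table}: list with
#'   \code{table} (reaction_id, best_bitscore, matched, best_hit_seq),
#'   \code{hits} (expanded per-reaction hits), \code{thresholds}.
#' @export
build_evidence_table <- function(hits, thresholds = match_thresholds()) {
  ex <- expand_hits(hits)
  if (nrow(ex) == 0) {
    tab <- data.frame(reaction_id = character(), best_bitscore = numeric(),
                      matched = logical(), best_hit_seq = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, hits = ex, thresholds = thresholds),
                     class = "evidence_table"))
  }
  ids <- sort(unique(ex$reaction_id), method = "radix")
  rows <- lapply(ids, function(rid) {
    sub <- ex[ex$reaction_id == rid, , drop = FALSE]
    best <- which.max(sub$bitscore)
    passed <- vapply(seq_len(nrow(sub)), function(i)
      call_match(sub[i, ], thresholds), TRUE)
    data.frame(reaction_id = rid,
               best_bitscore = sub$bitscore[best],
               matched = any(passed),
               best_hit_seq = sub$ref_seq_id[best],
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), hits = ex,
                 thresholds = thresholds),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat("evidence_table:", nrow(x$table), "reactions,",
      sum(x$table$matched), "matched\n")
  invisible(x)
}

# Matched flag for a reaction id (FALSE when absent).
evidence_matched <- function(evidence, reaction_id) {
  if (is.null(evidence)) return(FALSE)
  k <- match(reaction_id, evidence$table$reaction_id)
  !is.na(k) && isTRUE(evidence$table$matched[k])
}
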