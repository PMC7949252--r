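# Gene-protein-reaction (GPR) boolean expressions: parsing, evaluation
# under gene deletions, and truth-table equivalence.

gpr_tokenise <- function(expr) {
  toks <- list()
  i <- 1L
  n <- nchar(expr)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(expr, i, n),
                    regexpr("^[A-Za-z0-9_.:-]+", substr(expr, i, n)))
    if (length(m) == 0) {
      stop("GPR parse error at position ", i, ": unexpected character '",
           ch, "'", call. = FALSE)
    }
    type <- if (tolower(m) %in% c("and", "or")) tolower(m) else "gene"
    toks[[length(toks) + 1L]] <- list(type = type, value = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

#' Parse a GPR expression into an AST
#'
#' Grammar: OR-expressions of AND-terms of gene ids or parenthesised
#' sub-expressions; \code{and}/\code{or} are case-insensitive.
#'
#' @param gpr expression string; empty/NA yields \code{NULL} (reaction
#'   not gene-controlled).
#' @return Nested list AST (\code{op} in \code{"and"}/\code{"or"} with
#'   \code{args}, or \code{gene} leaf), or \code{NULL}.
#' @export
gpr_parse <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  toks <- gpr_tokenise(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(t, what) {
    stop("GPR parse error at position ",
         if (is.null(t)) nchar(gpr) + 1L else t$pos, ": expected ", what,
         call. = FALSE)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) fail(t, "gene id or '('")
    if (t$type == "gene") { advance(); return(list(gene = t$value)) }
    if (t$type == "(") {
      advance()
      inner <- parse_or()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")") fail(t2, "')'")
      advance()
      return(inner)
    }
    fail(t, "gene id or '('")
  }
  ast <- parse_or()
  if (pos <= length(toks)) fail(toks[[pos]], "end of expression")
  ast
}

gpr_ast_genes <- function(ast) {
  if (is.null(ast)) return(character())
  if (!is.null(ast$gene)) return(ast$gene)
  unique(unlist(lapply(ast$args, gpr_ast_genes)))
}

#' Gene ids referenced by a GPR expression
#' @param gpr GPR string.
#' @return Character vector (empty for empty GPR).
#' @export
gpr_gene_ids <- function(gpr) gpr_ast_genes(gpr_parse(gpr))

gpr_ast_eval <- function(ast, present) {
  if (!is.null(ast$gene)) return(isTRUE(present[[ast$gene]]))
  vals <- vapply(ast$args, gpr_ast_eval, TRUE, present = present)
  if (ast$op == "and") all(vals) else any(vals)
}

#' Evaluate a GPR expression under gene deletions
#'
#' Deleted genes evaluate to FALSE, all others to TRUE.  An empty GPR
#' evaluates to TRUE (the reaction is not gene-controlled and cannot be
#' knocked out).
#'
#' @param gpr GPR string.
#' @param deleted_genes character vector of knocked-out gene ids.
#' @return Logical: is the reaction still catalysable?
#' @export
evaluate_gpr <- function(gpr, deleted_genes = character()) {
  ast <- gpr_parse(gpr)
  if (is.null(ast)) return(TRUE)
  genes <- gpr_ast_genes(ast)
  present <- stats::setNames(!(genes %in% deleted_genes), genes)
  gpr_ast_eval(ast, as.list(present))
}

#' Truth-table equivalence of two GPR expressions
#'
#' Two GPRs are equivalent when they return identical results for all
#' possible combinations of gene presence/knockout over the union of
#' their gene ids.  Exhaustive over 2^n assignments; n is capped.
#'
#' @param gpr_a,gpr_b GPR strings.
#' @param max_genes combinatorial cap (default 20).
#' @return Logical flag.
#' @export
gpr_equivalence <- function(gpr_a, gpr_b, max_genes = 20L) {
  ast_a <- gpr_parse(gpr_a)
  ast_b <- gpr_parse(gpr_b)
  if (is.null(ast_a) || is.null(ast_b)) {
    return(is.null(ast_a) && is.null(ast_b))
  }
  genes <- union(gpr_ast_genes(ast_a), gpr_ast_genes(ast_b))
  n <- length(genes)
  if (n > max_genes) {
    stop("GPR equivalence limited to ", max_genes, " distinct genes (got ",
         n, ")", call. = FALSE)
  }
  for (mask in 0:(2^n - 1)) {
    present <- as.list(stats::setNames(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0,
                                       genes))
    if (gpr_ast_eval(ast_a, present) != gpr_ast_eval(ast_b, present)) {
      return(FALSE)
    }
  }
  TRUE
}
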