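# Shared fixtures, built once per test run.  Everything derives from the
# deterministic toy world; no external files are needed.

tw <- make_toy_world(1)
tw_universal <- build_universal_model(tw$db)

org_complete <- make_toy_organism(tw, "complete", 1)
org_single_gap <- make_toy_organism(tw, "single_gap", 1)
org_fermenter <- make_toy_organism(tw, "fermenter", 1)
org_auxotroph <- make_toy_organism(tw, "auxotroph", 1)

rec_complete <- reconstruct_draft(tw, org_complete)
rec_single_gap <- reconstruct_draft(tw, org_single_gap)
rec_fermenter <- reconstruct_draft(tw, org_fermenter)
rec_auxotroph <- reconstruct_draft(tw, org_auxotroph)

# mineral base of the minimal medium (no carbon source, no oxygen)
tw_mineral <- tw$media$m9_glc[!names(tw$media$m9_glc) %in%
                                c("glc_e0", "o2_e0")]

# Independent brute-force LP oracle for tiny instances: enumerate all
# basis column subsets, solve the square system at active bounds, keep
# the best feasible vertex.  Exponential; only for m <= 5, n <= 10.
brute_force_lp <- function(A, b, obj, lb, ub, maximize = TRUE) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(n <= 12)
  best <- NULL
  combs <- utils::combn(n, m)
  nonbasic <- function(idx) setdiff(seq_len(n), idx)
  for (ci in seq_len(ncol(combs))) {
    bas <- combs[, ci]
    B <- A[, bas, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    for (mask in 0:(2^(n - m) - 1)) {
      nb <- nonbasic(bas)
      xn <- ifelse(bitwAnd(mask, 2^(seq_along(nb) - 1)) > 0, ub[nb], lb[nb])
      if (any(!is.finite(xn))) next
      rhs <- b - A[, nb, drop = FALSE] %*% xn
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n); x[bas] <- xb; x[nb] <- xn
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      val <- sum(obj * x)
      if (is.null(best) || (maximize && val > best) ||
          (!maximize && val < best)) best <- val
    }
  }
  best
}
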