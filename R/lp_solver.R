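# Bounded-variable primal simplex.
#
# Solves   max (or min)  c'x   s.t.  A x = b,  lb <= x <= ub
# with a two-phase scheme (artificial basis in phase 1).  Dense algebra;
# intended for the model sizes this package works with (tens to a few
# hundred variables), where a textbook simplex is fast and has no
# external dependencies.

#' Solve a linear program with equality constraints and variable bounds
#'
#' Maximises (or minimises) \code{obj \%*\% x} subject to \code{A x = b}
#' and \code{lb <= x <= ub} using a two-phase bounded-variable primal
#' simplex method.
#'
#' @param A constraint matrix (m x n), dense numeric.
#' @param b right-hand side vector (length m).
#' @param obj objective coefficient vector (length n).
#' @param lb,ub variable bounds (length n); entries may be \code{-Inf}/\code{Inf}.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol numeric tolerance for optimality and feasibility tests.
#' @param max_iter iteration cap; exceeded caps return status
#'   \code{"iteration_limit"}.
#'
#' @return A list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"} or \code{"iteration_limit"}),
#'   \code{objective} and \code{x} (primal solution, \code{NULL} unless
#'   optimal).
#' @export
solve_lp <- function(A, b, obj, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  sense <- if (maximize) 1 else -1
  cvec <- sense * as.numeric(obj)

  if (m == 0L) {
    # No constraints: each variable goes to its favourable bound.
    x <- ifelse(cvec > 0, ub, lb)
    x[cvec == 0] <- pmin(pmax(0, lb), ub)[cvec == 0]
    if (any(!is.finite(x) & cvec != 0)) {
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }
    return(list(status = "optimal", objective = sense * sum(cvec * x), x = x))
  }

  # Initial point: every structural variable rests exactly on a finite
  # bound (the one nearer zero); doubly unbounded variables start free at 0.
  x0 <- numeric(n)
  stat0 <- integer(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && (!is.finite(ub[j]) || abs(lb[j]) <= abs(ub[j]))) {
      x0[j] <- lb[j]; stat0[j] <- 1L
    } else if (is.finite(ub[j])) {
      x0[j] <- ub[j]; stat0[j] <- 2L
    } else {
      x0[j] <- 0; stat0[j] <- 3L                  # free nonbasic
    }
  }
  r <- b - as.numeric(A %*% x0)
  cap <- sum(abs(r)) + 1

  # Augment with artificial variables forming the starting basis.
  Aa <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(cap, m))
  ntot <- n + m
  art <- (n + 1L):ntot

  # Variable status: 0 = basic, 1 = nonbasic at lower, 2 = nonbasic at
  # upper, 3 = free nonbasic (value tracked explicitly).
  vstat <- integer(ntot)
  vstat[seq_len(n)] <- stat0
  xv <- c(x0, abs(r))
  basis <- art

  run_simplex <- function(cost, basis, vstat, xv, phase1) {
    degen <- 0L
    for (it in seq_len(max_iter)) {
      B <- Aa[, basis, drop = FALSE]
      Binv_t <- tryCatch(solve(t(B), cost[basis]),
                         error = function(e) NULL)
      if (is.null(Binv_t)) {
        return(list(status = "singular", basis = basis, vstat = vstat, xv = xv))
      }
      nb <- which(vstat != 0L)
      d <- cost[nb] - as.numeric(crossprod(Aa[, nb, drop = FALSE], Binv_t))
      st <- vstat[nb]
      viol <- (st == 1L & d > tol) | (st == 2L & d < -tol) |
              (st == 3L & abs(d) > tol)
      if (!any(viol)) {
        return(list(status = "optimal", basis = basis, vstat = vstat, xv = xv))
      }
      cand <- nb[viol]
      if (degen > 2L * ntot) {
        e <- cand[1L]                     # Bland's rule under degeneracy
      } else {
        e <- cand[which.max(abs(d[viol]))]
      }
      de <- d[match(e, nb)]
      sigma <- if (vstat[e] == 1L) 1 else if (vstat[e] == 2L) -1 else sign(de)
      w <- solve(B, Aa[, e])              # basic direction: x_B -= sigma * t * w
      # Ratio test: largest step t >= 0 keeping all basics within bounds,
      # capped by the entering variable's own bound span (bound flip).
      t_best <- if (vstat[e] == 3L) Inf else uba[e] - lba[e]
      leave <- 0L
      leave_to <- 0L
      for (k in seq_len(m)) {
        wk <- sigma * w[k]
        bi <- basis[k]
        tk <- Inf
        to <- 0L
        if (wk > 1e-10) {                 # x_Bk decreases -> may hit lower bound
          if (is.finite(lba[bi])) { tk <- (xv[bi] - lba[bi]) / wk; to <- 1L }
        } else if (wk < -1e-10) {         # x_Bk increases -> may hit upper bound
          if (is.finite(uba[bi])) { tk <- (uba[bi] - xv[bi]) / (-wk); to <- 2L }
        }
        if (to == 0L) next
        tk <- max(tk, 0)
        if (tk < t_best - 1e-12 ||
            (tk <= t_best + 1e-12 && leave != 0L && bi < basis[leave])) {
          t_best <- min(t_best, tk)
          leave <- k
          leave_to <- to
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis, vstat = vstat, xv = xv))
      }
      t_best <- max(t_best, 0)
      degen <- if (t_best <= tol) degen + 1L else 0L
      # Update values.
      xv[e] <- xv[e] + sigma * t_best
      xv[basis] <- xv[basis] - sigma * t_best * w
      if (leave == 0L) {
        # Bound flip (free variables never flip: t_best would be Inf).
        vstat[e] <- if (vstat[e] == 1L) 2L else 1L
        xv[e] <- if (vstat[e] == 1L) lba[e] else uba[e]
      } else {
        lv <- basis[leave]
        vstat[lv] <- leave_to
        xv[lv] <- if (leave_to == 1L) lba[lv] else uba[lv]
        basis[leave] <- e
        vstat[e] <- 0L
      }
    }
    list(status = "iteration_limit", basis = basis, vstat = vstat, xv = xv)
  }

  # Phase 1: minimise sum of artificials (maximise the negative).
  cost1 <- c(rep(0, n), rep(-1, m))
  res1 <- run_simplex(cost1, basis, vstat, xv, TRUE)
  if (res1$status %in% c("singular", "iteration_limit")) {
    return(list(status = "iteration_limit", objective = NA_real_, x = NULL))
  }
  if (sum(res1$xv[art]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # Freeze artificials at zero for phase 2.
  uba[art] <- 0
  res1$xv[art] <- pmin(res1$xv[art], 0)
  res1$xv[art][res1$xv[art] < 0] <- 0

  cost2 <- c(cvec, rep(0, m))
  res2 <- run_simplex(cost2, res1$basis, res1$vstat, res1$xv, FALSE)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  if (res2$status %in% c("singular", "iteration_limit")) {
    return(list(status = "iteration_limit", objective = NA_real_, x = NULL))
  }
  x <- res2$xv[seq_len(n)]
  # Clean tiny residues against bounds.
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", objective = sense * sum(cvec * x), x = x)
}
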