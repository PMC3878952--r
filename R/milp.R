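## Branch-and-bound for mixed 0/1 linear programs over the simplex kernel in
## lp.R.  Depth-first search, most-fractional branching, nearest-integer child
## explored first, pruning against the incumbent.  Optimality is proven (the
## whole tree is fathomed); there is no MIP gap.

#' Solve a mixed 0/1 linear program
#'
#' Minimises \code{obj \%*\% x} subject to \code{A x (dir) rhs},
#' \code{0 <= x <= ub}, with the variables indexed by \code{bin} restricted
#' to \{0, 1\}.
#'
#' @param obj,A,dir,rhs,ub as in the LP layer.
#' @param bin integer indices of the binary variables.
#' @param int_tol integrality tolerance on the relaxation solution.
#' @param opt_tol absolute pruning tolerance against the incumbent.
#' @param max_nodes safety cap on explored nodes.
#' @return list with \code{status} (\code{"optimal"} or \code{"infeasible"}),
#'   \code{objval}, \code{x} (binaries rounded), and \code{nodes} explored.
#' @keywords internal
#' @noRd
solve_milp <- function(obj, A, dir, rhs, ub = NULL, bin = integer(0),
                       int_tol = 1e-9, opt_tol = 1e-7, max_nodes = 500000L) {
  n <- length(obj)
  if (is.null(ub)) ub <- rep(Inf, n)
  ub[bin] <- pmin(ub[bin], 1)
  lb0 <- rep(0, n)

  best_x <- NULL
  best_obj <- Inf
  nodes <- 0L
  stack <- list(list(lb = lb0, ub = ub))

  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > max_nodes) {
      stop("branch-and-bound node limit exceeded (", max_nodes, ")")
    }
    rel <- solve_lp(obj, A, dir, rhs, lb = nd$lb, ub = nd$ub)
    if (rel$status %in% c("numfail", "maxit")) {
      stop("linear-programming relaxation failed numerically (",
           rel$status, ")")
    }
    if (rel$status != "optimal") next
    if (rel$objval >= best_obj - opt_tol) next

    xb <- rel$x[bin]
    fr <- pmin(xb, 1 - xb)
    if (!length(bin) || max(fr) <= int_tol) {
      x <- rel$x
      x[bin] <- round(x[bin])
      best_x <- x
      best_obj <- rel$objval
      next
    }
    j <- bin[which.max(fr)]
    lo <- nd; lo$ub[j] <- 0
    hi <- nd; hi$lb[j] <- 1
    if (rel$x[j] >= 0.5) {
      stack <- c(stack, list(lo, hi))   # LIFO: hi explored first
    } else {
      stack <- c(stack, list(hi, lo))
    }
  }

  if (is.null(best_x)) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL,
                nodes = nodes))
  }
  ## polish: re-solve the winning configuration's continuous problem with
  ## the exact (lexicographic, refactorising) routine.  Incumbent values
  ## from the fast pass can carry small numerical slack; on the
  ## integer-data models solved here the true optima are well-separated
  ## rationals, so this recovers the exact optimum and a clean solution.
  if (length(bin)) {
    lbp <- rep(0, n)
    ubp <- ub
    fixed <- round(best_x[bin])
    lbp[bin] <- fixed
    ubp[bin] <- fixed
    pol <- solve_lp(obj, A, dir, rhs, lb = lbp, ub = ubp, careful = TRUE)
    if (pol$status != "optimal") {
      pol <- solve_lp(obj, A, dir, rhs, lb = lbp, ub = ubp)
    }
    if (pol$status == "optimal") {
      best_x <- pol$x
      best_obj <- pol$objval
    }
  }
  list(status = "optimal", objval = best_obj, x = best_x, nodes = nodes)
}
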