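## Dense two-phase primal simplex.
##
## Small linear programs arise here in two places: the relaxations inside the
## branch-and-bound solver (see milp.R) and the per-path balancing problems of
## the brute-force reference implementation.  Problems are desk-scale (tens of
## variables and rows), so a dense tableau is adequate -- but long pivot
## sequences on degenerate bases accumulate round-off, so the tableau is
## periodically refactorised from the original data (x_B = B^{-1} b via a
## fresh linear solve) and optimality/unboundedness are only ever declared on
## freshly refactorised numbers.  Pricing is Dantzig with a switch to Bland's
## rule after a generous budget to rule out cycling; min-ratio ties are broken
## toward the largest pivot element.

#' Solve a linear program
#'
#' Minimises \code{obj \%*\% x} subject to \code{A x (dir) rhs} and bound
#' constraints \code{lb <= x <= ub}.
#'
#' @param obj numeric objective coefficients.
#' @param A constraint matrix (dense, one row per constraint).
#' @param dir character vector of \code{"<="}, \code{">="} or \code{"="}.
#' @param rhs right-hand sides.
#' @param lb,ub variable bounds; defaults 0 and \code{Inf}.  Finite upper
#'   bounds are handled as additional rows after shifting out \code{lb}.
#' @param tol pivot/feasibility tolerance.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"} or \code{"numfail"}), \code{objval} and primal
#'   solution \code{x}.
#' @keywords internal
#' @noRd
solve_lp <- function(obj, A, dir, rhs, lb = NULL, ub = NULL, tol = 1e-9,
                     careful = FALSE) {
  n <- length(obj)
  if (is.null(dim(A))) A <- matrix(A, ncol = n)
  stopifnot(ncol(A) == n, nrow(A) == length(rhs), length(dir) == length(rhs))
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  if (any(ub < lb - 1e-12)) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  }

  ## shift x = lb + y so that y >= 0
  rhs2 <- rhs - as.numeric(A %*% lb)
  objconst <- sum(obj * lb)
  ub2 <- ub - lb

  ## fixed variables (ub == lb) drop out entirely
  free <- which(ub2 > tol)
  xfix <- lb
  if (length(free) == 0L) {
    ok <- check_rows(rhs2, rep(0, length(rhs2)), dir, tol = 1e-7)
    if (!ok) return(list(status = "infeasible", objval = NA_real_, x = NULL))
    return(list(status = "optimal", objval = objconst, x = xfix))
  }
  Af <- A[, free, drop = FALSE]
  cf <- obj[free]
  ubf <- ub2[free]

  ## finite upper bounds become rows
  fin <- which(is.finite(ubf))
  if (length(fin)) {
    Bu <- matrix(0, length(fin), length(free))
    Bu[cbind(seq_along(fin), fin)] <- 1
    Af <- rbind(Af, Bu)
    rhs2 <- c(rhs2, ubf[fin])
    dir <- c(dir, rep("<=", length(fin)))
  }

  res <- simplex_core(cf, Af, dir, rhs2, tol = tol, careful = careful)
  if (res$status != "optimal") {
    return(list(status = res$status, objval = NA_real_, x = NULL))
  }
  x <- xfix
  x[free] <- x[free] + res$x
  list(status = "optimal", objval = res$objval + objconst, x = x)
}

## residual check used when every variable is fixed
check_rows <- function(rhs, lhs, dir, tol) {
  d <- lhs - rhs
  all(ifelse(dir == "<=", d <= tol, ifelse(dir == ">=", d >= -tol, abs(d) <= tol)))
}

## Two-phase simplex on min c'y, A y (dir) b, y >= 0.
simplex_core <- function(cc, A, dir, b, tol = 1e-9, careful = FALSE) {
  m <- nrow(A)
  n <- ncol(A)

  ## power-of-two equilibration (exact in binary floating point); big-M
  ## linking rows otherwise mix coefficients of order 1 and order N and
  ## degrade the basis conditioning badly.  Columns first (a change of
  ## variable units, undone on the returned solution), then rows.
  cmax <- apply(abs(A), 2, max)
  cmax[cmax == 0] <- 1
  cs <- 2^(-round(log2(cmax)))
  A <- sweep(A, 2, cs, "*")
  cc <- cc * cs
  rmax <- apply(abs(A), 1, max)
  rmax[rmax == 0] <- 1
  scale <- 2^(-round(log2(rmax)))
  A <- A * scale
  b <- b * scale

  ## normalise to b >= 0
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    dir[flip] <- ifelse(dir[flip] == "<=", ">=", ifelse(dir[flip] == ">=", "<=", "="))
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  n_eq <- sum(dir == "=")
  n_slack <- n_le + n_ge            # slack (+1) for <=, surplus (-1) for >=
  n_art <- n_ge + n_eq
  ntot <- n + n_slack + n_art

  Astd <- cbind(A, matrix(0, m, n_slack + n_art))
  basis <- integer(m)
  sl <- n
  ar <- n + n_slack
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      sl <- sl + 1
      Astd[i, sl] <- 1
      basis[i] <- sl
    } else if (dir[i] == ">=") {
      sl <- sl + 1
      Astd[i, sl] <- -1
      ar <- ar + 1
      Astd[i, ar] <- 1
      basis[i] <- ar
      art_cols <- c(art_cols, ar)
    } else {
      ar <- ar + 1
      Astd[i, ar] <- 1
      basis[i] <- ar
      art_cols <- c(art_cols, ar)
    }
  }

  basis_init <- basis
  cost <- c(cc, rep(0, n_slack + n_art))
  cost1 <- numeric(ntot)
  cost1[art_cols] <- 1

  ## run both phases against right-hand side `bv`, returning the terminal
  ## basis; the caller validates and extracts the solution against the
  ## true right-hand side
  run_phases <- function(careful, bv) {
    basis <- basis_init
    allowed <- rep(TRUE, ntot)
    if (n_art > 0) {
      ph1 <- run_simplex(Astd, bv, cost1, basis, allowed, tol,
                         careful = careful)
      if (ph1$status == "unbounded") return(list(status = "numfail"))
      if (ph1$status != "optimal") return(list(status = ph1$status))
      basis <- ph1$basis
      xB <- basis_solution(Astd, bv, basis)
      if (is.null(xB)) return(list(status = "numfail"))
      p1val <- sum(cost1[basis] * xB)
      ## phase 1 only terminates on a fresh-refactor optimality check, so
      ## its value is trustworthy to roughly red_tol * solution mass; a
      ## clearly positive optimum means the constraints cannot be met.
      ## Values in the narrow band below that are marginal: they are
      ## resolved by consensus across the perturbed retries (a degenerate
      ## stall would not reproduce under an rhs perturbation).
      if (p1val > 1e-6) return(list(status = "infeasible"))
      if (p1val > 1e-7) return(list(status = "suspect", p1val = p1val))
      ## drive remaining artificials out of the basis where possible
      for (i in which(basis %in% art_cols)) {
        Bm <- Astd[, basis, drop = FALSE]
        row_i <- tryCatch(solve(t(Bm), diag(m)[, i]),
                          error = function(e) NULL)
        if (is.null(row_i)) next
        cand <- setdiff(which(abs(as.numeric(t(Astd) %*% row_i)) > 1e-7),
                        art_cols)
        cand <- setdiff(cand, basis)
        if (length(cand)) basis[i] <- cand[1]
      }
      allowed[art_cols] <- FALSE
    }
    ph2 <- run_simplex(Astd, bv, cost, basis, allowed, tol,
                       careful = careful)
    if (ph2$status != "optimal") return(list(status = ph2$status))
    list(status = "optimal", basis = ph2$basis)
  }

  ## dual simplex pivots (with a fresh linear solve per step) restore
  ## primal feasibility of a dual-feasible terminal basis; used to repair
  ## the small primal violations the fast pass can leave behind
  dual_repair <- function(basis) {
    allowed <- rep(TRUE, ntot)
    if (n_art > 0) allowed[art_cols] <- FALSE
    for (it in seq_len(200L)) {
      sol <- tryCatch(solve(Astd[, basis, drop = FALSE], cbind(Astd, b)),
                      error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      xB <- sol[, ntot + 1L]
      r <- which.min(xB)
      if (xB[r] >= -1e-11) return(basis)
      rowr <- sol[r, seq_len(ntot)]
      red <- cost - as.numeric(cost[basis] %*% sol[, seq_len(ntot)])
      J <- which(allowed & rowr < -1e-9)
      J <- J[!(J %in% basis)]
      if (!length(J)) return(NULL)
      ratios <- red[J] / (-rowr[J])
      basis[r] <- J[which.min(ratios)]
    }
    NULL
  }

  ## validate a terminal basis against the true right-hand side: reduced
  ## costs do not involve b, so optimality transfers; feasibility must be
  ## re-established to near machine precision
  validate <- function(res) {
    if (res$status != "optimal") return(res)
    xB <- basis_solution(Astd, b, res$basis)
    if (is.null(xB)) return(list(status = "suspect"))
    ## with big-M dual prices even 1e-7 bound violations shift the
    ## objective visibly, so the accepted basis must be feasible to near
    ## machine precision; dual pivots repair small violations exactly
    if (min(xB) < -1e-11 && min(xB) > -1e-3) {
      repaired <- dual_repair(res$basis)
      if (!is.null(repaired)) {
        res$basis <- repaired
        xB <- basis_solution(Astd, b, res$basis)
        if (is.null(xB)) return(list(status = "suspect"))
      }
    }
    if (min(xB) < -2e-9) {
      return(list(status = "suspect"))
    }
    if (sum(cost1[res$basis] * pmax(xB, 0)) > 1e-7) {
      return(list(status = "suspect"))   # artificial crept back in
    }
    xB[xB < 0] <- 0
    x <- numeric(ntot)
    x[res$basis] <- xB
    list(status = "optimal", objval = sum(cost * x), x = x)
  }

  marginal <- numeric(0)   # marginal phase-1 optima seen across attempts
  note_marginal <- function(res) {
    if (identical(res$status, "suspect") && !is.null(res$p1val)) {
      marginal <<- c(marginal, res$p1val)
    }
    res
  }
  res <- if (careful) list(status = "suspect")
         else note_marginal(validate(run_phases(FALSE, b)))
  if (res$status %in% c("suspect", "numfail", "maxit")) {
    res <- note_marginal(validate(run_phases(TRUE, b)))
  }
  ## last resort: break degeneracy with a deterministic perturbation of b,
  ## then snap the optimal basis back to the true right-hand side
  att <- 0L
  while (res$status %in% c("suspect", "numfail", "maxit") && att < 3L) {
    att <- att + 1L
    u <- ((seq_len(m) * 2654435761 + att * 40503) %% 104729) / 104729
    bp <- b + 1e-9 * (0.5 + u) * (1 + abs(b))
    res <- note_marginal(validate(run_phases(FALSE, bp)))
    if (res$status %in% c("suspect", "numfail", "maxit")) {
      res <- note_marginal(validate(run_phases(TRUE, bp)))
    }
  }
  if (res$status %in% c("suspect", "numfail", "maxit") &&
      length(marginal) >= 2L && all(marginal > 1e-7)) {
    ## every attempt that reached a phase-1 verdict found a positive
    ## optimum, consistently: the constraints cannot be met
    res <- list(status = "infeasible")
  }
  if (res$status %in% c("suspect", "maxit")) res$status <- "numfail"
  if (res$status != "optimal") return(list(status = res$status))
  list(status = "optimal", objval = res$objval,
       x = res$x[seq_len(n)] * cs[seq_len(n)])
}

basis_solution <- function(Astd, b, basis) {
  tryCatch(as.numeric(solve(Astd[, basis, drop = FALSE], b)),
           error = function(e) NULL)
}

## Refactorised tableau for the current basis: rows B^{-1}[A | b] plus the
## reduced-cost row in (c - z) form (its rhs entry is minus the objective).
refactor_tableau <- function(Astd, b, cost, basis) {
  Bm <- Astd[, basis, drop = FALSE]
  rows <- tryCatch(solve(Bm, cbind(Astd, b)), error = function(e) NULL)
  if (is.null(rows)) return(NULL)
  objrow <- c(cost, 0) - as.numeric(cost[basis] %*% rows)
  rbind(rows, objrow)
}

## Run the simplex to proven optimality under `cost`.  Pivots happen on the
## tableau, but every `refac_every` pivots -- and before accepting any
## optimal/unbounded verdict -- the tableau is rebuilt from the original
## data for the current basis.
run_simplex <- function(Astd, b, cost, basis, allowed, tol,
                        refac_every = 15L, max_pivots = 50000L,
                        feas_tol = 1e-7, red_tol = 1e-9, careful = FALSE) {
  if (careful) {
    return(run_simplex_lex(Astd, b, cost, basis, allowed, tol, max_pivots))
  }
  m <- nrow(Astd)
  ntot <- ncol(Astd)
  bland_after <- 500L + 20L * (m + ntot)
  pivots <- 0L
  basis0 <- basis
  restarted <- FALSE
  repeat {
    T <- refactor_tableau(Astd, b, cost, basis)
    bad_basis <- is.null(T)
    if (!bad_basis) {
      ## feasibility can drift slightly; clamp small negatives
      rhs_col <- T[seq_len(m), ntot + 1L]
      ft <- feas_tol * (1 + max(abs(rhs_col)))
      rhs_col[rhs_col < 0 & rhs_col > -ft] <- 0
      bad_basis <- any(rhs_col < 0)
      if (!bad_basis) T[seq_len(m), ntot + 1L] <- rhs_col
    }
    if (bad_basis) {
      ## drifted into a singular or infeasible basis: hand the phase over
      ## to the exact lexicographic routine from its initial basis
      if (restarted) return(list(status = "numfail", basis = basis))
      restarted <- TRUE
      return(run_simplex_lex(Astd, b, cost, basis0, allowed, tol,
                             max_pivots))
    }
    for (step in seq_len(refac_every)) {
      red <- T[m + 1L, seq_len(ntot)]
      cand <- which(allowed & red < -red_tol)
      cand <- cand[!(cand %in% basis)]
      if (!length(cand)) {
        ## a verdict is only trusted straight after a refactor
        if (step == 1L) return(list(status = "optimal", basis = basis))
        break
      }
      bland <- pivots > bland_after
      enter <- if (bland) cand[1] else cand[which.min(red[cand])]
      colv <- T[seq_len(m), enter]
      pos <- which(colv > tol)
      if (!length(pos)) {
        if (step == 1L) return(list(status = "unbounded", basis = basis))
        break
      }
      pivots <- pivots + 1L
      if (pivots > max_pivots) return(list(status = "maxit", basis = basis))
      ## Harris-style two-pass ratio test: allow a feasibility-tolerance
      ## slack on the blocking bound, then take the largest pivot element
      ## among the rows it admits.  Degenerate rows may sit a hair below
      ## zero between refactors; a negative step would walk backwards, so
      ## they count as exactly binding.
      rhsv <- pmax(T[pos, ntot + 1L], 0)
      ratio <- rhsv / colv[pos]
      if (bland) {
        rmin <- min(ratio)
        ties <- pos[ratio <= rmin + 1e-12]
        leave <- ties[which.min(basis[ties])]
      } else {
        theta_max <- min((rhsv + 1e-9) / colv[pos])
        ok <- pos[ratio <= theta_max]
        leave <- ok[which.max(colv[ok])]
      }
      T <- do_pivot(T, leave, enter, m)
      basis[leave] <- enter
    }
  }
}

## Exact-arithmetic-style simplex: refactorise from the original data at
## every pivot and select the leaving row by the classical lexicographic
## rule (ratio ties broken on the rows of B^{-1}, which are linearly
## independent, so the choice is unique and cycling is impossible).  Slow,
## but every decision is made on freshly solved numbers and the basis stays
## feasible to machine precision.  Used as the fallback when the fast
## tableau pass reports trouble.
run_simplex_lex <- function(Astd, b, cost, basis, allowed, tol,
                            max_pivots = 50000L) {
  m <- nrow(Astd)
  ntot <- ncol(Astd)
  pivots <- 0L
  repeat {
    Bm <- Astd[, basis, drop = FALSE]
    sol <- tryCatch(solve(Bm, cbind(Astd, b, diag(m))),
                    error = function(e) NULL)
    if (is.null(sol)) return(list(status = "numfail", basis = basis))
    xB <- sol[, ntot + 1L]
    Binv <- sol[, ntot + 1L + seq_len(m), drop = FALSE]
    if (min(xB) < -1e-8 * (1 + max(abs(xB)))) {
      return(list(status = "numfail", basis = basis))
    }
    ## snap numerically-degenerate basics to zero: a tiny positive residue
    ## here turns into a tiny positive step, which an ill-conditioned
    ## entering column can amplify into a real infeasibility
    xB[abs(xB) < 1e-9 * (1 + max(abs(xB)))] <- 0
    red <- cost - as.numeric(cost[basis] %*% sol[, seq_len(ntot)])
    cand <- which(allowed & red < -tol)
    cand <- cand[!(cand %in% basis)]
    if (!length(cand)) return(list(status = "optimal", basis = basis))
    pivots <- pivots + 1L
    if (pivots > max_pivots) return(list(status = "maxit", basis = basis))
    enter <- cand[which.min(red[cand])]
    colv <- sol[, enter]
    pos <- which(colv > tol)
    if (!length(pos)) return(list(status = "unbounded", basis = basis))
    ratio <- xB[pos] / colv[pos]
    keep <- pos[ratio <= min(ratio) + 1e-12 * (1 + abs(min(ratio)))]
    j <- 0L
    while (length(keep) > 1L && j < m) {
      j <- j + 1L
      v <- Binv[keep, j] / colv[keep]
      keep <- keep[v <= min(v) + 1e-12 * (1 + abs(min(v)))]
    }
    leave <- keep[1]
    basis[leave] <- enter
  }
}

## Pivot row r, column c (vectorised full-tableau update).
do_pivot <- function(T, r, c, m) {
  T[r, ] <- T[r, ] / T[r, c]
  col <- T[, c]
  col[r] <- 0
  T <- T - outer(col, T[r, ])
  T[, c] <- 0
  T[r, c] <- 1
  T
}
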