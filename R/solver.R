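## Three-stage lexicographic solve and ranked enumeration.
##
## Stage 1 minimises total flux through lowly expressed reactions (set L),
## stage 2 total flux through medium/invariant reactions (set M) holding the
## stage-1 optimum, stage 3 the path length holding both.  Stage optima are
## carried forward as inequality caps, sum <= V * (1 + tol) + tol, rather
## than strict equalities: the staged objective can never go below its
## optimum, so the inequality preserves the lexicographic semantics while
## staying robust to floating-point round-off.  Ranked enumeration adds, for
## every accepted solution, a cut forbidding its full arc set; cuts
## accumulate across the whole enumeration.
##
## A classification with neither H nor L reactions carries no expression
## signal; the solver then reduces to the plain carbon-flux-path problem
## (length minimisation only) and reports V1 = V2 = 0.

## Cap carrying a stage optimum into the next stage.  The optimum is
## rounded first (staged optima are rationals with small denominators on
## integer-stoichiometry networks) and the slack kept tiny: any slack s
## can be converted into an objective reduction of up to N * s through the
## big-M flux/activity coupling, so a loose cap would bias later stages.
stage_cap <- function(v, tol) round(v, 9) * (1 + tol) + tol

solve_model_stage <- function(model, obj, extra) {
  A <- model$A
  dir <- model$dir
  rhs <- model$rhs
  if (length(extra$rows)) {
    A <- rbind(A, do.call(rbind, extra$rows))
    dir <- c(dir, extra$dir)
    rhs <- c(rhs, extra$rhs)
  }
  solve_milp(obj, A, dir, rhs, ub = model$ub, bin = model$bin)
}

add_extra <- function(extra, row, dir, rhs) {
  extra$rows <- c(extra$rows, list(row))
  extra$dir <- c(extra$dir, dir)
  extra$rhs <- c(extra$rhs, rhs)
  extra
}

#' Stage-1 solve: minimum total flux through lowly expressed reactions
#'
#' @param model a [build_cfp_model()] result.
#' @param extra optional list of accumulated extra constraints (used
#'   internally during enumeration).
#' @return the proven-optimal value V1.
#' @export
solve_stage1 <- function(model, extra = list(rows = list(), dir = character(0),
                                             rhs = numeric(0))) {
  res <- solve_model_stage(model, model$obj$stage1, extra)
  if (res$status != "optimal") stop_no_path("no feasible carbon flux path")
  res$objval
}

#' Stage-2 solve: minimum total M flux holding the stage-1 optimum
#'
#' @inheritParams solve_stage1
#' @param V1 stage-1 optimum to retain.
#' @return the proven-optimal value V2.
#' @export
solve_stage2 <- function(model, V1, extra = list(rows = list(),
                                                 dir = character(0),
                                                 rhs = numeric(0))) {
  tol <- model$query$stage_tol
  ex <- add_extra(extra, model$obj$stage1, "<=", stage_cap(V1, tol))
  res <- solve_model_stage(model, model$obj$stage2, ex)
  if (res$status != "optimal") {
    ## stage fixing can in principle cut off the optimum by round-off only;
    ## retry once with a 10x looser cap before giving up
    ex <- add_extra(extra, model$obj$stage1, "<=", stage_cap(V1, 10 * tol))
    res <- solve_model_stage(model, model$obj$stage2, ex)
    if (res$status != "optimal") stop("stage 2 infeasible under the stage-1 cap")
  }
  res$objval
}

#' Stage-3 solve: minimum path length holding both flux optima
#'
#' @inheritParams solve_stage2
#' @param V2 stage-2 optimum to retain.
#' @param skip_flux_stages plain-CFP mode (no expression signal): drop the
#'   V1/V2 caps and only minimise length.
#' @return an \code{icfp_path} solution.
#' @export
solve_stage3 <- function(model, V1 = 0, V2 = 0,
                         extra = list(rows = list(), dir = character(0),
                                      rhs = numeric(0)),
                         skip_flux_stages = FALSE) {
  tol <- model$query$stage_tol
  ex <- extra
  if (!skip_flux_stages) {
    ex <- add_extra(ex, model$obj$stage1, "<=", stage_cap(V1, tol))
    ex <- add_extra(ex, model$obj$stage2, "<=", stage_cap(V2, tol))
  }
  res <- solve_model_stage(model, model$obj$stage3, ex)
  if (res$status != "optimal" && !skip_flux_stages) {
    ex <- extra
    ex <- add_extra(ex, model$obj$stage1, "<=", stage_cap(V1, 10 * tol))
    ex <- add_extra(ex, model$obj$stage2, "<=", stage_cap(V2, 10 * tol))
    res <- solve_model_stage(model, model$obj$stage3, ex)
  }
  if (res$status != "optimal") {
    if (skip_flux_stages) stop_no_path("no feasible carbon flux path")
    stop("stage 3 infeasible under the stage caps")
  }
  x <- cleanup_fluxes(model, res$x, ex)
  extract_solution(model, x, V1, V2, !skip_flux_stages)
}

## Among the flux patterns realising the stage-3 solution (binaries fixed,
## stage caps kept), pick the one with minimum total flux.  The staged
## objectives are untouched -- this only removes the arbitrariness of the
## flux vertex the length minimisation happens to return.
cleanup_fluxes <- function(model, x, extra) {
  lb <- rep(0, model$nvar)
  ub <- model$ub
  fixed <- round(x[model$bin])
  lb[model$bin] <- fixed
  ub[model$bin] <- fixed
  obj <- numeric(model$nvar)
  obj[model$iv] <- 1
  A <- model$A
  dir <- model$dir
  rhs <- model$rhs
  if (length(extra$rows)) {
    A <- rbind(A, do.call(rbind, extra$rows))
    dir <- c(dir, extra$dir)
    rhs <- c(rhs, extra$rhs)
  }
  res <- solve_lp(obj, A, dir, rhs, lb = lb, ub = ub)
  if (res$status == "optimal") res$x else x
}

extract_solution <- function(model, x, V1, V2, expression_used) {
  v <- x[model$iv]
  z <- round(x[model$iz])
  u <- round(x[model$iu])
  names(v) <- model$rids
  if (any(v > 0.99 * model$query$big_m)) {
    warning("an optimal flux is within 1% of the N bound (", model$query$big_m,
            "); the flux scenario may be truncated -- consider a larger big_m")
  }
  arcs <- model$pairs[u > 0.5, , drop = FALSE]
  rownames(arcs) <- NULL
  ## order arcs along the walk from the source
  nodes <- model$query$source
  ord <- integer(0)
  cur <- model$query$source
  left <- rep(TRUE, nrow(arcs))
  while (any(left)) {
    nxt <- which(left & arcs$i == cur)
    if (!length(nxt)) break
    ord <- c(ord, nxt[1])
    left[nxt[1]] <- FALSE
    cur <- arcs$j[nxt[1]]
    nodes <- c(nodes, cur)
  }
  if (length(ord) == nrow(arcs)) {
    arcs <- arcs[ord, , drop = FALSE]
    rownames(arcs) <- NULL
  }
  structure(list(
    rank = NA_integer_,
    nodes = nodes,
    arcs = arcs,
    active_reactions = model$rids[z > 0.5],
    fluxes = v[v > 1e-9],
    staged_objective = c(V1 = round(V1, 6), V2 = round(V2, 6),
                         length = sum(u > 0.5)),
    expression_used = expression_used,
    states = model$states[model$rids[z > 0.5]]),
    class = "icfp_path")
}

#' Enumerate ranked carbon flux paths
#'
#' Runs the three-stage solve repeatedly; after each accepted solution a cut
#' forbidding its full arc set is added, so solutions are pairwise distinct
#' and their staged objective tuples (V1, V2, length) are lexicographically
#' non-decreasing.  Stops early (with a notice) when the solution space is
#' exhausted before \code{k} paths are found.
#'
#' @param net a solver-ready (irreversible) \code{icfp_network}.
#' @param query a [path_query()]; \code{query$k} paths are sought.
#' @param states reaction classification (see [build_cfp_model()]).
#' @param verify re-verify every solution with [check_solution()] and stop
#'   on any violation.
#' @return list of \code{icfp_path} solutions (possibly shorter than
#'   \code{k}), with attribute \code{exhausted}.
#' @export
enumerate_paths <- function(net, query, states = NULL, verify = TRUE) {
  model <- build_cfp_model(net, query, states)
  states_n <- model$states
  has_L <- any(states_n == "L")
  has_H <- any(states_n == "H")
  has_M <- any(states_n == "M")
  plain <- !has_L && !has_H      # no expression signal: plain CFP
  sols <- list()
  extra <- list(rows = list(), dir = character(0), rhs = numeric(0))
  exhausted <- FALSE
  for (k in seq_len(query$k)) {
    sol <- tryCatch({
      if (plain) {
        solve_stage3(model, extra = extra, skip_flux_stages = TRUE)
      } else {
        ## stage 1 doubles as the feasibility probe even when L is empty
        V1 <- solve_stage1(model, extra)
        V2 <- if (has_M) solve_stage2(model, V1, extra) else 0
        solve_stage3(model, V1, V2, extra)
      }
    }, icfp_no_path = function(e) NULL)
    if (is.null(sol)) {
      exhausted <- TRUE
      break
    }
    sol$rank <- k
    if (verify) {
      viol <- check_solution(net, query, states_n, sol)
      if (length(viol)) {
        stop("solver returned an invalid solution:\n  ",
             paste(viol, collapse = "\n  "))
      }
    }
    sols[[k]] <- sol
    ## elimination cut: the found arc set may never recur in full
    hit <- paste(model$pairs$i, model$pairs$j, sep = "\r") %in%
      paste(sol$arcs$i, sol$arcs$j, sep = "\r")
    row <- numeric(model$nvar)
    row[model$iu[hit]] <- 1
    extra <- add_extra(extra, row, "<=", sum(hit) - 1)
  }
  if (exhausted && length(sols) < query$k) {
    message("solution space exhausted after ", length(sols), " path(s)")
  }
  attr(sols, "exhausted") <- exhausted
  sols
}

#' Find expression-guided carbon flux paths
#'
#' The main entry point.  Classifies reactions (unless a classification is
#' supplied), prepares the network (medium, reversible splitting), builds
#' the path model and enumerates \code{k} ranked paths.
#'
#' @param net an \code{icfp_network} (raw or already split).
#' @param source,target metabolite ids.
#' @param k number of ranked paths to enumerate.
#' @param states optional reaction classification over \{"H","M","L"\}
#'   (named vector or [classify_reactions()] output).  \code{NULL} runs the
#'   expression-free carbon-flux-path model.
#' @param log2fc optional named vector of per-gene log2 fold changes; when
#'   given (and \code{states} is not), reactions are classified by the
#'   fold-change rule through the network's GPRs.
#' @param medium optional character vector declaring the growth medium
#'   (see [apply_medium()]).
#' @param big_m,flux_floor,stage_tol model parameters, see [path_query()].
#' @param verify re-verify every solution against the constraint set.
#' @return object of class \code{icfp}: the ranked solutions plus the
#'   query, classification and prepared network.
#' @examples
#' fx <- figure1_fixture()
#' fit <- icfp(fx$network, "A", "E", k = 2, states = fx$states)
#' fit
#' summary(fit)
#' @export
icfp <- function(net, source, target, k = 1, states = NULL, log2fc = NULL,
                 medium = NULL, big_m = 1000, flux_floor = 1,
                 stage_tol = 1e-12, verify = TRUE) {
  if (!inherits(net, "icfp_network")) stop("net must be an icfp_network")
  if (!is.null(medium)) net <- apply_medium(net, medium)
  if (is.null(states) && !is.null(log2fc)) {
    states <- map_to_reactions(net, classify_by_fold_change(log2fc))
  }
  net <- split_reversible(net)
  query <- path_query(source, target, k = k, big_m = big_m,
                      flux_floor = flux_floor, stage_tol = stage_tol)
  states_n <- normalize_states(net, states)
  sols <- enumerate_paths(net, query, states_n, verify = verify)
  structure(list(paths = sols, query = query, states = states_n,
                 network = net, exhausted = attr(sols, "exhausted"),
                 call = match.call()),
            class = "icfp")
}

#' @export
print.icfp_path <- function(x, ...) {
  cat(if (!is.na(x$rank)) paste0("[", x$rank, "] ") else "",
      paste(x$nodes, collapse = " -> "), "\n", sep = "")
  cat("  V1 (L flux) = ", format(x$staged_objective[["V1"]]),
      ", V2 (M flux) = ", format(x$staged_objective[["V2"]]),
      ", length = ", x$staged_objective[["length"]], "\n", sep = "")
  cat("  active: ",
      paste(paste0(x$active_reactions, " [", x$states, "]"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.icfp <- function(x, ...) {
  cat("Expression-guided carbon flux paths: ", x$query$source, " -> ",
      x$query$target, ", ", length(x$paths), " of ", x$query$k,
      " requested path(s)",
      if (x$exhausted) " (solution space exhausted)", "\n", sep = "")
  cl <- table(factor(x$states, levels = c("H", "M", "L")))
  cat("Classification: |H| = ", cl[["H"]], ", |M| = ", cl[["M"]],
      ", |L| = ", cl[["L"]], "\n\n", sep = "")
  for (p in x$paths) print(p)
  invisible(x)
}

#' @export
summary.icfp <- function(object, ...) {
  structure(list(fit = object, table = as.data.frame(object)),
            class = "summary.icfp")
}

#' @export
print.summary.icfp <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tabulate enumerated paths
#'
#' One row per path: rank, node sequence, staged objectives, and the active
#' reactions with their H/M/L tags and fluxes.
#' @param x an \code{icfp} object.
#' @param ... unused.
#' @export
as.data.frame.icfp <- function(x, ...) {
  if (!length(x$paths)) {
    return(data.frame(rank = integer(0), path = character(0),
                      V1 = numeric(0), V2 = numeric(0), length = integer(0),
                      active_reactions = character(0)))
  }
  do.call(rbind, lapply(x$paths, function(p) {
    data.frame(
      rank = p$rank,
      path = paste(p$nodes, collapse = "->"),
      V1 = p$staged_objective[["V1"]],
      V2 = p$staged_objective[["V2"]],
      length = p$staged_objective[["length"]],
      active_reactions = paste(
        sprintf("%s[%s]=%g", p$active_reactions, p$states,
                p$fluxes[p$active_reactions]), collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}

#' Plot the carbon-arc graph with a ranked path highlighted
#'
#' @param x an \code{icfp} object.
#' @param rank which enumerated path to highlight.
#' @param ... passed to \code{plot.igraph}.
#' @export
plot.icfp <- function(x, rank = 1, ...) {
  pairs <- unique(data.frame(i = x$network$arcs$substrate,
                             j = x$network$arcs$product,
                             stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(pairs, directed = TRUE,
                                     vertices = x$network$metabolites$id)
  ecol <- rep("grey70", igraph::ecount(g))
  ewid <- rep(1, igraph::ecount(g))
  if (length(x$paths) >= rank) {
    p <- x$paths[[rank]]
    key <- paste(pairs$i, pairs$j)
    onpath <- key %in% paste(p$arcs$i, p$arcs$j)
    ecol[onpath] <- "firebrick"
    ewid[onpath] <- 3
  }
  vcol <- ifelse(x$network$metabolites$id %in%
                   c(x$query$source, x$query$target),
                 "gold", "lightsteelblue")
  igraph::plot.igraph(g, edge.color = ecol, edge.width = ewid,
                      vertex.color = vcol, edge.arrow.size = 0.4, ...)
  invisible(x)
}

#' Write enumeration results to disk
#'
#' Produces \code{paths.tsv} and a mirroring \code{paths.json} in
#' \code{dir}.
#' @param x an \code{icfp} object.
#' @param dir output directory (created if needed).
#' @export
write_paths <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(x)
  utils::write.table(tab, file.path(dir, "paths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(x$paths, function(p) {
      list(rank = p$rank, nodes = p$nodes,
           arcs = p$arcs,
           V1 = p$staged_objective[["V1"]],
           V2 = p$staged_objective[["V2"]],
           length = p$staged_objective[["length"]],
           active = lapply(seq_along(p$active_reactions), function(i) {
             r <- p$active_reactions[i]
             list(reaction = r, state = unname(p$states[r]),
                  flux = unname(p$fluxes[r]))
           }))
    }),
    file.path(dir, "paths.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
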