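## Brute-force reference implementation.
##
## Enumerates every simple source->target path over the carbon-arc graph
## explicitly (no elimination cuts), then solves the two flux stages for
## each path with its arcs fixed -- off-path reactions remain free to carry
## balancing flux subject to the mass-balance, activity and reverse-pair
## constraints -- and ranks the feasible paths by (V1, V2, length)
## lexicographically.  Model construction here is independent of the
## incremental path model; only the low-level solver kernel is shared.

ORACLE_MAX_METS <- 12L

#' Brute-force ranked carbon flux paths
#'
#' @param net a (raw or irreversible) \code{icfp_network} with at most 12
#'   metabolites; larger networks are refused.
#' @param states reaction classification as in [build_cfp_model()].
#' @param source,target metabolite ids.
#' @param top_n number of ranked entries to return.
#' @param query optional [path_query()] carrying big_m/flux_floor/tolerance
#'   (source/target are taken from the explicit arguments).
#' @return list of entries \code{list(nodes, arcs, V1, V2, length)},
#'   lexicographically sorted; infeasible paths are dropped.
#' @export
brute_force_icfp <- function(net, states, source, target, top_n = 3,
                             query = NULL) {
  if (nrow(net$metabolites) > ORACLE_MAX_METS) {
    stop("brute-force reference refuses networks with more than ",
         ORACLE_MAX_METS, " metabolites")
  }
  net <- split_reversible(net)
  if (is.null(query)) query <- path_query(source, target)
  states <- normalize_states(net, states)
  plain <- !any(states == "L") && !any(states == "H")

  pairs <- unique(data.frame(i = net$arcs$substrate, j = net$arcs$product,
                             stringsAsFactors = FALSE))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  g <- igraph::graph_from_data_frame(pairs, directed = TRUE,
                                     vertices = net$metabolites$id)
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    mode = "out")
  entries <- list()
  for (p in paths) {
    nodes <- igraph::as_ids(p)
    arcs <- data.frame(i = nodes[-length(nodes)], j = nodes[-1],
                       stringsAsFactors = FALSE)
    st <- oracle_path_stages(net, states, arcs, query, plain = plain)
    if (is.null(st)) next
    entries[[length(entries) + 1L]] <-
      list(nodes = nodes, arcs = arcs, V1 = round(st$V1, 6),
           V2 = round(st$V2, 6), length = nrow(arcs))
  }
  if (!length(entries)) return(list())
  V1 <- vapply(entries, `[[`, numeric(1), "V1")
  V2 <- vapply(entries, `[[`, numeric(1), "V2")
  len <- vapply(entries, `[[`, numeric(1), "length")
  ord <- order(round(V1, 9), round(V2, 9), len)
  entries[ord][seq_len(min(top_n, length(entries)))]
}

## Stage values for one fixed arc set.  Variables v_r, z_r; constraints:
## mass balance (internal =0, non-medium external >=0), flux/activity
## linking, reverse-pair exclusion, and one arc-support cover per path arc.
## Returns list(V1, V2, v) or NULL if the path cannot be balanced.
oracle_path_stages <- function(net, states, arcs, query, plain = FALSE) {
  rids <- reaction_ids(net)
  nR <- length(rids)
  iv <- seq_len(nR)
  iz <- nR + seq_len(nR)
  nvar <- 2L * nR
  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add <- function(idx, coef, dir, b) {
    row <- numeric(nvar); row[idx] <- coef
    rows[[length(rows) + 1L]] <<- row
    dirs[length(dirs) + 1L] <<- dir
    rhs[length(rhs) + 1L] <<- b
  }
  mets <- net$metabolites
  for (ci in seq_len(nrow(mets))) {
    m <- mets$id[ci]
    coefs <- vapply(net$reactions, function(r) {
      s <- r$stoich[m]; if (is.na(s)) 0 else s
    }, numeric(1))
    nz <- which(coefs != 0)
    if (!length(nz)) next
    if (mets$is_internal[ci]) add(iv[nz], coefs[nz], "=", 0)
    else if (!mets$in_medium[ci]) add(iv[nz], coefs[nz], ">=", 0)
  }
  for (r in seq_len(nR)) {
    add(c(iz[r], iv[r]), c(query$flux_floor, -1), "<=", 0)
    add(c(iv[r], iz[r]), c(1, -query$big_m), "<=", 0)
  }
  seen <- character(0)
  for (r in net$reactions) {
    p <- r$reverse_partner
    if (!is.na(p) && p %in% rids && !(r$id %in% seen)) {
      add(iz[c(match(r$id, rids), match(p, rids))], c(1, 1), "<=", 1)
      seen <- c(seen, r$id, p)
    }
  }
  for (k in seq_len(nrow(arcs))) {
    wit <- net$arcs$reaction[net$arcs$substrate == arcs$i[k] &
                             net$arcs$product == arcs$j[k]]
    if (!length(wit)) return(NULL)
    add(iz[match(unique(wit), rids)], rep(1, length(unique(wit))), ">=", 1)
  }
  A <- do.call(rbind, rows)
  ub <- c(rep(query$big_m, nR), rep(1, nR))
  obj1 <- numeric(nvar); obj1[iv[states[rids] == "L"]] <- 1
  obj2 <- numeric(nvar); obj2[iv[states[rids] == "M"]] <- 1

  if (plain) {
    feas <- solve_milp(numeric(nvar), A, dirs, rhs, ub = ub, bin = iz)
    if (feas$status != "optimal") return(NULL)
    return(list(V1 = 0, V2 = 0, v = feas$x[iv]))
  }
  s1 <- solve_milp(obj1, A, dirs, rhs, ub = ub, bin = iz)
  if (s1$status != "optimal") return(NULL)
  V1 <- s1$objval
  A2 <- rbind(A, obj1)
  s2 <- solve_milp(obj2, A2, c(dirs, "<="),
                   c(rhs, stage_cap(V1, query$stage_tol)), ub = ub, bin = iz)
  if (s2$status != "optimal") return(NULL)
  list(V1 = V1, V2 = s2$objval, v = s2$x[iv])
}

#' Stoichiometry-free shortest carbon path
#'
#' Classical path finding over the carbon-arc graph alone: no mass
#' balance, no activity model -- the comparison baseline that motivates
#' balanced path finding.
#'
#' @param net an \code{icfp_network}.
#' @param source,target metabolite ids.
#' @return list with \code{nodes} (metabolite sequence) and
#'   \code{reactions} (per arc, the reactions carrying it), or \code{NULL}
#'   if the target is unreachable.
#' @export
shortest_carbon_path <- function(net, source, target) {
  pairs <- unique(data.frame(i = net$arcs$substrate, j = net$arcs$product,
                             stringsAsFactors = FALSE))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  g <- igraph::graph_from_data_frame(pairs, directed = TRUE,
                                     vertices = net$metabolites$id)
  sp <- suppressWarnings(igraph::shortest_paths(g, from = source,
                                                to = target, mode = "out"))
  nodes <- igraph::as_ids(sp$vpath[[1]])
  if (length(nodes) < 2L) return(NULL)
  reactions <- lapply(seq_len(length(nodes) - 1L), function(k) {
    unique(net$arcs$reaction[net$arcs$substrate == nodes[k] &
                             net$arcs$product == nodes[k + 1]])
  })
  list(nodes = nodes, reactions = reactions)
}
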