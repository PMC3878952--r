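## The carbon flux path mixed-integer model.
##
## Variables: v_r >= 0 flux of (irreversible) reaction r; z_r in {0,1} its
## activity indicator; u_ij in {0,1} for every ordered metabolite pair (i,j)
## backed by at least one carbon-exchange arc.  Pairs without an arc never
## appear: the arc-support constraint would force their u to 0 anyway, so
## pruning them shrinks the model with no semantic change.
##
## Constraint families (tags used in row names and diagnostics):
##   eq1  one arc leaves the source, one enters the target
##   eq2  no arc enters the source, none leaves the target
##   eq3  arc conservation at intermediate metabolites
##   eq4  in-degree <= 1 (no metabolite revisited; applied to every
##        metabolite, including the source, where it is vacuous)
##   eq5  steady state for internal metabolites
##   eq6  nonnegative net production for external metabolites outside the
##        growth medium (medium metabolites are fully unconstrained)
##   eq7  flux_floor * z_r <= v_r <= N * z_r
##   eq8  a reaction and its reverse are never both active
##   eq9  an arc in the path is witnessed by an active reaction carrying it

#' Define a path query
#'
#' @param source,target metabolite ids (source != target).
#' @param k number of ranked paths to enumerate.
#' @param big_m flux upper bound N linking v and z; any optimal flux within
#'   1\% of it triggers a truncation warning downstream.
#' @param flux_floor minimum nonzero flux (1 in the underlying model).
#' @param stage_tol relative tolerance used when carrying a stage optimum
#'   into the next stage as a cap.
#' @return an object of class \code{path_query}.
#' @export
path_query <- function(source, target, k = 1L, big_m = 1000,
                       flux_floor = 1, stage_tol = 1e-12) {
  stopifnot(is.character(source), is.character(target),
            length(source) == 1L, length(target) == 1L)
  if (source == target) stop("source and target must differ")
  if (!(big_m > flux_floor && flux_floor > 0)) {
    stop("need big_m > flux_floor > 0")
  }
  if (k < 1) stop("k must be >= 1")
  structure(list(source = source, target = target, k = as.integer(k),
                 big_m = big_m, flux_floor = flux_floor,
                 stage_tol = stage_tol),
            class = "path_query")
}

## normalise a classification argument into a named character vector over
## all reactions of `net` ("H"/"M"/"L"); NULL -> all "M".  Unnamed reactions
## default to "M"; split partners inherit the base reaction's state.
normalize_states <- function(net, states) {
  rids <- reaction_ids(net)
  out <- stats::setNames(rep("M", length(rids)), rids)
  if (is.null(states)) return(out)
  if (is.data.frame(states)) {
    states <- stats::setNames(as.character(states$state), states$reaction_id)
  }
  if (is.null(names(states))) {
    stop("states must be named by reaction id")
  }
  bad <- setdiff(unique(states), c("H", "M", "L"))
  if (length(bad)) stop("unknown reaction states: ", paste(bad, collapse = ", "))
  hit <- intersect(names(states), rids)
  out[hit] <- states[hit]
  ## backward copies of split reversible reactions inherit the state
  for (rid in rids) {
    r <- net$reactions[[rid]]
    base <- sub("_rev$", "", rid)
    if (!(rid %in% names(states)) && base %in% names(states)) {
      out[rid] <- states[[base]]
    }
  }
  out
}

#' Build the CFP mixed-integer model
#'
#' @param net a solver-ready (irreversible) \code{icfp_network}.
#' @param query a [path_query()].
#' @param states reaction classification: named character vector (or
#'   data.frame with \code{reaction_id}, \code{state}) over \{"H","M","L"\};
#'   \code{NULL} classifies every reaction "M".
#' @return an object of class \code{cfp_model} holding the constraint
#'   matrix, variable index and the three objective vectors.
#' @export
build_cfp_model <- function(net, query, states = NULL) {
  if (any(vapply(net$reactions, `[[`, logical(1), "reversible"))) {
    stop("network must be split to irreversible form first; see split_reversible()")
  }
  mets <- net$metabolites
  if (!query$source %in% mets$id) stop("source metabolite not in network: ", query$source)
  if (!query$target %in% mets$id) stop("target metabolite not in network: ", query$target)
  states <- normalize_states(net, states)

  rids <- reaction_ids(net)
  nR <- length(rids)
  arcs <- net$arcs
  if (nrow(arcs) == 0L) stop("network has no carbon-exchange arcs")
  arcs <- arcs[arcs$substrate != arcs$product, , drop = FALSE]
  pair_key <- paste(arcs$substrate, arcs$product, sep = "\r")
  pairs <- unique(data.frame(i = arcs$substrate, j = arcs$product,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  nU <- nrow(pairs)
  pkey <- paste(pairs$i, pairs$j, sep = "\r")

  a <- query$source
  b <- query$target
  if (!any(pairs$i == a)) {
    stop_no_path("no carbon-exchange arc leaves the source '", a, "'")
  }
  if (!any(pairs$j == b)) {
    stop_no_path("no carbon-exchange arc enters the target '", b, "'")
  }
  ## fast reachability diagnostic over the carbon-arc graph
  g <- igraph::graph_from_data_frame(pairs, directed = TRUE,
                                     vertices = mets$id)
  dist <- igraph::distances(g, v = a, to = b, mode = "out")
  if (!is.finite(dist[1, 1])) {
    stop_no_path("target '", b, "' is not carbon-reachable from source '",
                 a, "'")
  }

  iv <- seq_len(nR)                 # v_r
  iz <- nR + seq_len(nR)            # z_r
  iu <- 2L * nR + seq_len(nU)       # u_ij
  nvar <- 2L * nR + nU

  rows <- list(); dirs <- character(0); rhs <- numeric(0); tags <- character(0)
  add_row <- function(idx, coef, dir, b, tag) {
    row <- numeric(nvar)
    row[idx] <- coef
    rows[[length(rows) + 1L]] <<- row
    dirs[length(dirs) + 1L] <<- dir
    rhs[length(rhs) + 1L] <<- b
    tags[length(tags) + 1L] <<- tag
  }

  out_of <- function(m) iu[pairs$i == m]
  into <- function(m) iu[pairs$j == m]

  ## eq1 / eq2: path endpoints
  add_row(out_of(a), rep(1, length(out_of(a))), "=", 1, "eq1_source_out")
  add_row(into(b), rep(1, length(into(b))), "=", 1, "eq1_target_in")
  if (length(into(a))) add_row(into(a), rep(1, length(into(a))), "=", 0, "eq2_source_in")
  if (length(out_of(b))) add_row(out_of(b), rep(1, length(out_of(b))), "=", 0, "eq2_target_out")

  ## eq3: degree balance at intermediates; eq4: in-degree <= 1 everywhere
  for (m in mets$id) {
    if (!(m %in% c(a, b))) {
      idx <- c(into(m), out_of(m))
      if (length(idx)) {
        add_row(idx, c(rep(1, length(into(m))), rep(-1, length(out_of(m)))),
                "=", 0, paste0("eq3_", m))
      }
    }
    if (length(into(m))) {
      add_row(into(m), rep(1, length(into(m))), "<=", 1, paste0("eq4_", m))
    }
  }

  ## eq5 / eq6: mass balance
  for (ci in seq_len(nrow(mets))) {
    m <- mets$id[ci]
    coefs <- vapply(net$reactions, function(r) {
      s <- r$stoich[m]; if (is.na(s)) 0 else s
    }, numeric(1))
    nz <- which(coefs != 0)
    if (!length(nz)) next
    if (mets$is_internal[ci]) {
      add_row(iv[nz], coefs[nz], "=", 0, paste0("eq5_", m))
    } else if (!mets$in_medium[ci]) {
      add_row(iv[nz], coefs[nz], ">=", 0, paste0("eq6_", m))
    }
  }

  ## eq7: flux/activity linking
  for (r in seq_len(nR)) {
    add_row(c(iz[r], iv[r]), c(query$flux_floor, -1), "<=", 0,
            paste0("eq7_floor_", rids[r]))
    add_row(c(iv[r], iz[r]), c(1, -query$big_m), "<=", 0,
            paste0("eq7_cap_", rids[r]))
  }

  ## eq8: reverse-pair exclusion
  seen <- character(0)
  for (r in net$reactions) {
    p <- r$reverse_partner
    if (!is.na(p) && p %in% rids && !(r$id %in% seen)) {
      add_row(c(iz[match(r$id, rids)], iz[match(p, rids)]), c(1, 1), "<=", 1,
              paste0("eq8_", r$id))
      seen <- c(seen, r$id, p)
    }
  }

  ## eq9: arc support
  arc_pair_idx <- match(pair_key, pkey)
  for (p in seq_len(nU)) {
    rs <- unique(arcs$reaction[arc_pair_idx == p])
    add_row(c(iu[p], iz[match(rs, rids)]), c(1, rep(-1, length(rs))),
            "<=", 0, paste0("eq9_", pairs$i[p], "_", pairs$j[p]))
  }

  A <- do.call(rbind, rows)
  rownames(A) <- tags
  ub <- c(rep(query$big_m, nR), rep(1, nR + nU))

  obj_stage1 <- numeric(nvar); obj_stage1[iv[states[rids] == "L"]] <- 1
  obj_stage2 <- numeric(nvar); obj_stage2[iv[states[rids] == "M"]] <- 1
  obj_stage3 <- numeric(nvar); obj_stage3[iu] <- 1

  structure(list(net = net, query = query, states = states,
                 rids = rids, pairs = pairs, iv = iv, iz = iz, iu = iu,
                 nvar = nvar, A = A, dir = dirs, rhs = rhs, ub = ub,
                 bin = c(iz, iu),
                 obj = list(stage1 = obj_stage1, stage2 = obj_stage2,
                            stage3 = obj_stage3)),
            class = "cfp_model")
}

stop_no_path <- function(...) {
  stop(structure(class = c("icfp_no_path", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @export
print.cfp_model <- function(x, ...) {
  cat("CFP model: ", length(x$rids), " reactions (v, z), ", nrow(x$pairs),
      " arc variables (u), ", nrow(x$A), " constraints; query ",
      x$query$source, " -> ", x$query$target, "\n", sep = "")
  invisible(x)
}

#' Export a CFP model as an LP-format file
#'
#' Constraint names carry their constraint-family tags (\code{eq1} ..
#' \code{eq9}), which makes solver logs and external debugging runs easy to
#' map back to the model.
#'
#' @param model a \code{cfp_model}.
#' @param path output file.
#' @param stage which staged objective to write (1, 2 or 3).
#' @export
write_lp <- function(model, path, stage = 1) {
  obj <- model$obj[[paste0("stage", stage)]]
  vn <- c(paste0("v_", model$rids), paste0("z_", model$rids),
          paste0("u_", model$pairs$i, "__", model$pairs$j))
  term <- function(coef, keep = coef != 0) {
    idx <- which(keep)
    if (!length(idx)) return("0")
    paste(sprintf("%+g %s", coef[idx], vn[idx]), collapse = " ")
  }
  con <- character(nrow(model$A))
  op <- c("<=" = "<=", ">=" = ">=", "=" = "=")
  for (i in seq_len(nrow(model$A))) {
    con[i] <- sprintf(" %s: %s %s %g", rownames(model$A)[i],
                      term(model$A[i, ]), op[[model$dir[i]]], model$rhs[i])
  }
  writeLines(c("Minimize", paste(" obj:", term(obj)),
               "Subject To", con,
               "Bounds",
               sprintf(" 0 <= %s <= %g", vn, model$ub),
               "Binary", paste("", vn[model$bin]), "End"),
             path)
  invisible(path)
}

#' Verify a path solution against every model constraint
#'
#' Re-evaluates constraint families eq1-eq9 and the staged objective
#' directly from the solution's fluxes and arc list, independently of the
#' solver: activity indicators are reconstructed from the fluxes and arcs
#' are checked as exact binaries.
#'
#' @param net the (irreversible) network the solution refers to.
#' @param query the [path_query()] used.
#' @param states reaction classification used (as in [build_cfp_model()]).
#' @param sol an \code{icfp_path} solution.
#' @param tol tolerance on continuous constraints.
#' @return character vector of violation messages; empty if valid.
#' @export
check_solution <- function(net, query, states, sol, tol = 1e-6) {
  states <- normalize_states(net, states)
  rids <- reaction_ids(net)
  v <- stats::setNames(rep(0, length(rids)), rids)
  v[names(sol$fluxes)] <- sol$fluxes
  z <- as.numeric(v > query$flux_floor / 2)
  names(z) <- rids
  bad <- character(0)
  note <- function(...) bad <<- c(bad, paste0(...))

  arcs <- sol$arcs
  a <- query$source; b <- query$target
  ## eq1/eq2
  if (sum(arcs$i == a) != 1) note("Eq1: ", sum(arcs$i == a), " arcs leave the source")
  if (sum(arcs$j == b) != 1) note("Eq1: ", sum(arcs$j == b), " arcs enter the target")
  if (any(arcs$j == a)) note("Eq2: an arc enters the source")
  if (any(arcs$i == b)) note("Eq2: an arc leaves the target")
  ## eq3/eq4
  for (m in setdiff(unique(c(arcs$i, arcs$j)), c(a, b))) {
    if (sum(arcs$j == m) != sum(arcs$i == m)) note("Eq3: degree imbalance at ", m)
  }
  indeg <- table(arcs$j)
  if (any(indeg > 1)) note("Eq4: metabolite revisited: ",
                           paste(names(indeg)[indeg > 1], collapse = ","))
  ## path connectivity: walking from the source must reach the target
  ## through every listed arc exactly once
  walk <- a; cur <- a; used <- rep(FALSE, nrow(arcs))
  repeat {
    nxt <- which(!used & arcs$i == cur)
    if (!length(nxt)) break
    used[nxt[1]] <- TRUE
    cur <- arcs$j[nxt[1]]
    walk <- c(walk, cur)
    if (cur == b) break
  }
  if (cur != b || any(!used)) note("path: arcs do not form one simple ",
                                   a, " -> ", b, " path")
  ## eq5/eq6
  mets <- net$metabolites
  for (ci in seq_len(nrow(mets))) {
    m <- mets$id[ci]
    bal <- sum(vapply(net$reactions, function(r) {
      s <- r$stoich[m]; if (is.na(s)) 0 else s * v[r$id]
    }, numeric(1)))
    if (mets$is_internal[ci] && abs(bal) > tol) {
      note("Eq5: steady-state violated at ", m, " (", signif(bal, 4), ")")
    }
    if (!mets$is_internal[ci] && !mets$in_medium[ci] && bal < -tol) {
      note("Eq6: net consumption of non-medium external ", m)
    }
  }
  ## eq7
  active <- rids[z > 0.5]
  if (any(v[z > 0.5] < query$flux_floor - tol)) {
    note("Eq7: active reaction below the flux floor")
  }
  if (any(v > query$big_m + tol)) note("Eq7: flux exceeds the N bound")
  if (!setequal(active, sol$active_reactions)) {
    note("Eq7: active set inconsistent with fluxes")
  }
  ## eq8
  for (r in net$reactions) {
    p <- r$reverse_partner
    if (!is.na(p) && p %in% rids && z[r$id] > 0.5 && z[p] > 0.5) {
      note("Eq8: reverse pair both active: ", r$id, "/", p)
    }
  }
  ## eq9
  net_arcs <- net$arcs
  for (k in seq_len(nrow(arcs))) {
    witness <- net_arcs$reaction[net_arcs$substrate == arcs$i[k] &
                                 net_arcs$product == arcs$j[k]]
    if (!any(z[witness] > 0.5)) {
      note("Eq9: arc (", arcs$i[k], ",", arcs$j[k], ") has no active ",
           "supporting reaction")
    }
  }
  ## staged objective recomputation.  When the solve ignored expression
  ## (plain CFP: no H and no L reactions), V1/V2 are reported as 0 by
  ## convention and only the length is checked.
  len <- nrow(arcs)
  so <- sol$staged_objective
  if (!identical(sol$expression_used, FALSE)) {
    V1 <- sum(v[states[rids] == "L"])
    V2 <- sum(v[states[rids] == "M"])
    ## stage caps admit drift of up to V*stage_tol + stage_tol above the
    ## reported optimum; widen the comparison band accordingly
    tol <- tol + 2 * query$stage_tol * (1 + abs(so[["V1"]]) + abs(so[["V2"]]))
    if (abs(V1 - so[["V1"]]) > tol) {
      note("objective: V1 mismatch (", signif(V1, 8), " vs ",
           signif(so[["V1"]], 8), ")")
    }
    if (abs(V2 - so[["V2"]]) > tol) {
      note("objective: V2 mismatch (", signif(V2, 8), " vs ",
           signif(so[["V2"]], 8), ")")
    }
  }
  if (len != so[["length"]]) note("objective: length mismatch")
  bad
}
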