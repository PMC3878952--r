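## Synthetic inputs: the worked 10-metabolite example, random networks with
## a planted balanceable path, and synthetic expression series.  These are
## first-class generators (seeded, validated), not ad-hoc test helpers.

#' The 10-metabolite, 12-reaction worked example
#'
#' A small network with two source-to-target routes whose comparison shows
#' why stoichiometric balancing must inform path ranking.  Reactions are
#' classified H = \{2,3,4,5,8\}, M = \{1,6,7,12\}, L = \{9,10,11\}.  The
#' length-minimal backbone A -> B -> C -> E (reactions 3, 5, 8, all H)
#' throws off the byproducts X and Y, whose removal forces flux through the
#' lowly expressed reactions 10 and 11; the alternative route
#' A -> F -> G -> P -> E runs through H reactions 2 and 4 and is balanced
#' entirely by the medium-expressed reactions 6 and 7, with zero L flux.
#' The figure this reconstructs does not print coefficients, so the
#' stoichiometry here is a constructed artifact; what is pinned down (and
#' verified at load against the brute-force reference) is the
#' classification and the two structural claims above.
#'
#' @param verify re-verify the structural claims with the brute-force
#'   reference implementation.
#' @return list with \code{network} (an \code{icfp_network}),
#'   \code{states} (reaction classification) and \code{query}
#'   (a [path_query()] A -> E with k = 2).
#' @export
figure1_fixture <- function(verify = TRUE) {
  mets <- data.frame(
    id = c("A", "B", "C", "E", "F", "G", "P", "W", "X", "Y"),
    name = c("A", "B", "C", "E", "F", "G", "P", "W", "X", "Y"),
    is_internal = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                    TRUE, TRUE),
    in_medium = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE),
    stringsAsFactors = FALSE)
  rx <- function(id, stoich, gene) {
    list(id = id, stoich = stoich, reversible = FALSE, gpr = gene)
  }
  reactions <- list(
    rx("r1", c(A = -1, X = 1), "g1"),
    rx("r2", c(A = -1, F = 1), "g2"),
    rx("r3", c(A = -1, B = 1, X = 1), "g3"),
    rx("r4", c(P = -1, E = 1), "g4"),
    rx("r5", c(B = -1, C = 1, Y = 1), "g5"),
    rx("r6", c(F = -1, G = 1), "g6"),
    rx("r7", c(G = -1, P = 1), "g7"),
    rx("r8", c(C = -1, E = 1), "g8"),
    rx("r9", c(X = -1, Y = 1), "g9"),
    rx("r10", c(X = -1, W = 1), "g10"),
    rx("r11", c(Y = -1, W = 1), "g11"),
    rx("r12", c(E = -1, W = 1), "g12"))
  arcs <- data.frame(
    reaction = c("r1", "r2", "r3", "r3", "r4", "r5", "r5", "r6", "r7",
                 "r8", "r9", "r10", "r11", "r12"),
    substrate = c("A", "A", "A", "A", "P", "B", "B", "F", "G",
                  "C", "X", "X", "Y", "E"),
    product = c("X", "F", "B", "X", "E", "C", "Y", "G", "P",
                "E", "Y", "W", "W", "W"),
    stringsAsFactors = FALSE)
  net <- metabolic_network(mets, reactions, arcs)
  states <- stats::setNames(rep("M", 12), paste0("r", 1:12))
  states[paste0("r", c(2, 3, 4, 5, 8))] <- "H"
  states[paste0("r", c(9, 10, 11))] <- "L"
  query <- path_query("A", "E", k = 2)
  if (verify) verify_figure1(net, states)
  list(network = net, states = states, query = query)
}

## Structural claims, checked against the brute-force reference:
## (a) the unique shortest carbon path is A->B->C->E and balancing it needs
##     nonzero L flux; (b) the top-ranked entry under the classification has
##     V1 = 0 through the A->F->G->P->E route.
verify_figure1 <- function(net, states) {
  sp <- shortest_carbon_path(net, "A", "E")
  stopifnot(identical(sp$nodes, c("A", "B", "C", "E")))
  stopifnot(setequal(unlist(sp$reactions), c("r3", "r5", "r8")))
  top <- brute_force_icfp(net, states, "A", "E", top_n = 2)
  stopifnot(length(top) == 2L,
            top[[1]]$V1 == 0,
            identical(top[[1]]$nodes, c("A", "F", "G", "P", "E")),
            top[[2]]$V1 > 0,
            identical(top[[2]]$nodes, c("A", "B", "C", "E")))
  invisible(TRUE)
}

#' Generate a random stoichiometric network with a planted balanced path
#'
#' Builds a chain of unit-coefficient conversions from a medium source to
#' an external target (the planted path, always balanceable at unit flux),
#' then adds random reactions with coefficients in \{-2,-1,1,2\}, carbon
#' arcs consistent with the stoichiometric signs, optional reversibility,
#' and random GPR rules over a synthetic gene pool.
#'
#' @param n_mets number of metabolites (>= 3).
#' @param n_rxns reaction budget (planted chain plus extras).
#' @param seed RNG seed; equal seeds give identical networks.
#' @param density fraction of the remaining reaction budget actually used
#'   for random extra reactions (0 = planted path only).
#' @param reversible_fraction probability that an extra reaction is
#'   reversible.
#' @return an \code{icfp_network}; attributes \code{source}, \code{target}
#'   and \code{planted_path} record the planted route.
#' @export
random_network <- function(n_mets, n_rxns, seed = 1, density = 1,
                           reversible_fraction = 0.2) {
  stopifnot(n_mets >= 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ids <- sprintf("m%02d", seq_len(n_mets))
  src <- ids[1]
  tgt <- ids[n_mets]
  ## up to one additional external sink metabolite
  extra_ext <- if (n_mets >= 5 && stats::runif(1) < 0.5) {
    sample(setdiff(ids, c(src, tgt)), 1)
  } else character(0)
  mets <- data.frame(
    id = ids, name = ids,
    is_internal = !(ids %in% c(src, tgt, extra_ext)),
    in_medium = ids == src,
    stringsAsFactors = FALSE)

  genes <- sprintf("g%02d", seq_len(max(4L, ceiling(1.5 * n_rxns))))
  rand_gpr <- function() {
    kind <- sample(4, 1)
    g <- sample(genes, 3)
    switch(kind, g[1], paste(g[1], "and", g[2]),
           paste0("(", g[1], " and ", g[2], ") or ", g[3]), "")
  }

  ## planted chain src -> ... -> tgt through internal intermediates
  k <- sample(2:min(4L, n_mets - 1L), 1)
  inter <- if (k > 1) sample(setdiff(ids, c(src, tgt, extra_ext)), k - 1) else character(0)
  chain <- c(src, inter, tgt)
  reactions <- list()
  arcs <- data.frame(reaction = character(0), substrate = character(0),
                     product = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    rid <- sprintf("p%02d", i)
    st <- stats::setNames(c(-1, 1), c(chain[i], chain[i + 1]))
    reactions[[rid]] <- list(id = rid, stoich = st, reversible = FALSE,
                             gpr = rand_gpr())
    arcs <- rbind(arcs, data.frame(reaction = rid, substrate = chain[i],
                                   product = chain[i + 1],
                                   stringsAsFactors = FALSE))
  }

  n_extra <- max(0L, round(density * (n_rxns - k)))
  for (i in seq_len(n_extra)) {
    rid <- sprintf("x%02d", i)
    ns <- sample(1:2, 1)
    np <- sample(1:2, 1)
    subs <- sample(ids, ns)
    prods <- sample(setdiff(ids, subs), np)
    st <- stats::setNames(c(-sample(1:2, ns, replace = TRUE),
                            sample(1:2, np, replace = TRUE)),
                          c(subs, prods))
    rev <- stats::runif(1) < reversible_fraction
    reactions[[rid]] <- list(id = rid, stoich = st, reversible = rev,
                             gpr = rand_gpr())
    ## carbon arcs: each substrate-product pair with prob 0.8, at least one
    grid <- expand.grid(substrate = subs, product = prods,
                        stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < 0.8
    if (!any(keep)) keep[sample(nrow(grid), 1)] <- TRUE
    arcs <- rbind(arcs, data.frame(reaction = rid,
                                   substrate = grid$substrate[keep],
                                   product = grid$product[keep],
                                   stringsAsFactors = FALSE))
  }

  net <- metabolic_network(mets, reactions, arcs)
  ## the planted chain is balanceable at unit flux by construction; verify
  split <- split_reversible(net)
  parcs <- data.frame(i = chain[-length(chain)], j = chain[-1],
                      stringsAsFactors = FALSE)
  st <- oracle_path_stages(split, normalize_states(split, NULL), parcs,
                           path_query(src, tgt))
  stopifnot(!is.null(st))
  attr(net, "source") <- src
  attr(net, "target") <- tgt
  attr(net, "planted_path") <- chain
  net
}

#' Generate synthetic expression series with planted truth
#'
#' Emulates per-feature log2 expression measured across a series of
#' conditions (e.g. specific growth rates): differential features follow a
#' linear log2 trend with total change +/- \code{effect_log2} across the
#' condition range, invariant features have slope zero, and Gaussian noise
#' is added everywhere.  A random subset of features additionally gets a
#' protein-level series (same truth, independent noise) to exercise the
#' gene/protein merging rule.
#'
#' @param n_features number of features (genes).
#' @param conditions numeric condition labels; default 8 growth rates.
#' @param frac_up,frac_down fractions of up/down features (sum <= 1).
#' @param effect_log2 total planted log2 change across the range.
#' @param noise_sd Gaussian noise standard deviation (log2 scale).
#' @param protein_fraction fraction of features that also get a protein
#'   series.
#' @param seed RNG seed.
#' @param feature_ids optional feature names (default \code{gene0001}...).
#' @return list with \code{series} (list of [expression_series()]) and
#'   \code{truth} (data.frame \code{feature_id}, \code{state}).
#' @export
synthetic_expression <- function(n_features, conditions = seq(0.11, 0.46,
                                                              length.out = 8),
                                 frac_up = 0.1, frac_down = 0.1,
                                 effect_log2 = 2 * log2(1.5),
                                 noise_sd = 0.25, protein_fraction = 0.3,
                                 seed = 1, feature_ids = NULL) {
  stopifnot(frac_up + frac_down <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(feature_ids)) feature_ids <- sprintf("gene%04d", seq_len(n_features))
  n_up <- round(frac_up * n_features)
  n_down <- round(frac_down * n_features)
  state <- rep("invariant", n_features)
  state[seq_len(n_up)] <- "up"
  if (n_down > 0) state[n_up + seq_len(n_down)] <- "down"
  state <- sample(state)
  rng <- max(conditions) - min(conditions)
  xr <- (conditions - min(conditions)) / rng
  series <- list()
  for (i in seq_len(n_features)) {
    eff <- switch(state[i], up = effect_log2, down = -effect_log2, 0)
    base <- stats::runif(1, 5, 10)
    y <- base + eff * xr + stats::rnorm(length(conditions), 0, noise_sd)
    series <- c(series, list(expression_series(feature_ids[i], y,
                                               conditions, "gene")))
    if (stats::runif(1) < protein_fraction) {
      yp <- base + eff * xr + stats::rnorm(length(conditions), 0, noise_sd)
      series <- c(series, list(expression_series(feature_ids[i], yp,
                                                 conditions, "protein")))
    }
  }
  list(series = series,
       truth = data.frame(feature_id = feature_ids, state = state,
                          stringsAsFactors = FALSE))
}
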