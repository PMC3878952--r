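## Metabolic network container and I/O.
##
## A network couples metabolites (internal set I vs external set E, with the
## growth-medium subset E_m of E), reactions (stoichiometry, reversibility,
## GPR rule), and the carbon-exchange arc table: ordered substrate->product
## pairs within a reaction between which carbon atoms are actually
## transferred.  Compartments are not modelled separately; a compartmentalised
## species is a distinct metabolite whose id carries the compartment suffix
## (e.g. "acald_c").

BALANCE_TOL <- 1e-9

#' Construct a metabolic network
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{is_internal} (logical), \code{in_medium} (logical).
#' @param reactions list of reaction records; each a list with \code{id},
#'   \code{stoich} (named numeric, negative = consumed), \code{reversible}
#'   (logical), \code{gpr} (string, may be \code{""}), and optionally
#'   \code{reverse_partner}.
#' @param arcs data.frame of carbon-exchange triples with columns
#'   \code{reaction}, \code{substrate}, \code{product}; may be empty.
#' @return an object of class \code{icfp_network}.
#' @export
metabolic_network <- function(metabolites, reactions, arcs = NULL) {
  if (is.null(arcs)) {
    arcs <- data.frame(reaction = character(0), substrate = character(0),
                       product = character(0), stringsAsFactors = FALSE)
  }
  metabolites$is_internal <- as.logical(metabolites$is_internal)
  metabolites$in_medium <- as.logical(metabolites$in_medium)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  reactions <- lapply(reactions, function(r) {
    r$reversible <- isTRUE(as.logical(r$reversible))
    if (is.null(r$gpr) || is.na(r$gpr)) r$gpr <- ""
    if (is.null(r$gpr_tree)) r$gpr_tree <- parse_gpr(r$gpr)
    if (is.null(r$reverse_partner)) r$reverse_partner <- NA_character_
    r
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        arcs = arcs),
                   class = "icfp_network")
  validate_network(net)
  net
}

reaction_ids <- function(net) names(net$reactions)

validate_network <- function(net) {
  mets <- net$metabolites
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (length(net$reactions) == 0L) stop("network has an empty reaction list")
  if (anyDuplicated(names(net$reactions))) {
    stop("duplicate reaction ids")
  }
  bad_medium <- mets$id[mets$in_medium & mets$is_internal]
  if (length(bad_medium)) {
    stop("medium metabolites must be external: ",
         paste(bad_medium, collapse = ", "))
  }
  dangling <- character(0)
  for (r in net$reactions) {
    if (length(r$stoich) == 0L) stop("reaction ", r$id, " has empty stoichiometry")
    dangling <- c(dangling, setdiff(names(r$stoich), mets$id))
  }
  if (length(dangling)) {
    stop("reactions reference unknown metabolites: ",
         paste(unique(dangling), collapse = ", "))
  }
  validate_arcs(net$arcs, net)
  invisible(net)
}

validate_arcs <- function(arcs, net) {
  if (nrow(arcs) == 0L) return(invisible(arcs))
  unknown_r <- setdiff(arcs$reaction, reaction_ids(net))
  if (length(unknown_r)) {
    stop("carbon arcs reference unknown reactions: ",
         paste(unique(unknown_r), collapse = ", "))
  }
  unknown_m <- setdiff(c(arcs$substrate, arcs$product), net$metabolites$id)
  if (length(unknown_m)) {
    stop("carbon arcs reference unknown metabolites: ",
         paste(unique(unknown_m), collapse = ", "))
  }
  for (k in seq_len(nrow(arcs))) {
    r <- net$reactions[[arcs$reaction[k]]]
    si <- r$stoich[arcs$substrate[k]]
    sj <- r$stoich[arcs$product[k]]
    if (arcs$substrate[k] == arcs$product[k] ||
        is.na(si) || is.na(sj) || si >= 0 || sj <= 0) {
      stop("carbon arc violates the substrate/product sign convention: (",
           arcs$reaction[k], ", ", arcs$substrate[k], ", ",
           arcs$product[k], ")")
    }
  }
  invisible(arcs)
}

#' @export
print.icfp_network <- function(x, ...) {
  mets <- x$metabolites
  cat("Metabolic network: ", nrow(mets), " metabolites (",
      sum(mets$is_internal), " internal, ", sum(!mets$is_internal),
      " external, ", sum(mets$in_medium), " in medium), ",
      length(x$reactions), " reactions (",
      sum(vapply(x$reactions, `[[`, logical(1), "reversible")),
      " reversible), ", nrow(x$arcs), " carbon arcs\n", sep = "")
  invisible(x)
}

#' Load a metabolic network from disk
#'
#' @param path for \code{format = "tabular"}, a directory holding
#'   \code{metabolites.tsv}, \code{reactions.tsv} and (optionally)
#'   \code{carbon_arcs.tsv}; for \code{format = "sbml"}, an SBML file
#'   (carbon arcs must then be supplied separately via
#'   [load_carbon_arcs()]).
#' @param format \code{"tabular"} or \code{"sbml"}.
#' @return an \code{icfp_network} in raw (possibly reversible) form.
#' @export
load_network <- function(path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "tabular") read_network_tsv(path) else read_network_sbml(path)
}

read_tsv_checked <- function(file, required) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = "")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("format error in ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  d
}

read_network_tsv <- function(dir) {
  mets <- read_tsv_checked(file.path(dir, "metabolites.tsv"),
                           c("id", "name", "internal", "in_medium"))
  rx <- read_tsv_checked(file.path(dir, "reactions.tsv"),
                         c("id", "reversible", "gpr", "stoichiometry"))
  mets_df <- data.frame(id = as.character(mets$id),
                        name = as.character(mets$name),
                        is_internal = mets$internal == 1,
                        in_medium = mets$in_medium == 1,
                        stringsAsFactors = FALSE)
  reactions <- lapply(seq_len(nrow(rx)), function(i) {
    list(id = as.character(rx$id[i]),
         stoich = parse_stoich(rx$stoichiometry[i], rx$id[i]),
         reversible = rx$reversible[i] == 1,
         gpr = if (is.na(rx$gpr[i])) "" else as.character(rx$gpr[i]))
  })
  arc_file <- file.path(dir, "carbon_arcs.tsv")
  net <- metabolic_network(mets_df, reactions)
  if (file.exists(arc_file)) {
    net$arcs <- load_carbon_arcs(arc_file, net)
  }
  net
}

parse_stoich <- function(s, rid) {
  if (is.na(s) || !nzchar(trimws(s))) {
    stop("format error: empty stoichiometry for reaction ", rid)
  }
  toks <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- strsplit(trimws(toks), ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L, logical(1))
  if (any(bad)) {
    stop("format error: malformed stoichiometry token '",
         toks[bad][1], "' in reaction ", rid)
  }
  coef <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(coef)) {
    stop("format error: non-numeric coefficient in reaction ", rid)
  }
  stats::setNames(coef, vapply(parts, `[[`, character(1), 1L))
}

#' Write a network in the tabular dialect
#'
#' Coefficients are written to 12 significant digits.
#' @param net an \code{icfp_network}.
#' @param dir output directory (created if needed).
#' @export
write_network_tsv <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mets <- net$metabolites
  utils::write.table(
    data.frame(id = mets$id, name = mets$name,
               internal = as.integer(mets$is_internal),
               in_medium = as.integer(mets$in_medium)),
    file.path(dir, "metabolites.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rx <- data.frame(
    id = reaction_ids(net),
    reversible = vapply(net$reactions, function(r) as.integer(r$reversible),
                        integer(1)),
    gpr = vapply(net$reactions, function(r) deparse_gpr(r$gpr_tree),
                 character(1)),
    stoichiometry = vapply(net$reactions, function(r) {
      paste(names(r$stoich), formatC(r$stoich, digits = 12, format = "g"),
            sep = ":", collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(rx, file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$arcs, file.path(dir, "carbon_arcs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a carbon-exchange arc table
#'
#' @param path TSV with header \code{reaction}, \code{substrate},
#'   \code{product}.
#' @param net network against which the triples are validated (the arc's
#'   reaction must consume the substrate and produce the product).
#' @return deduplicated, validated arc data.frame.
#' @export
load_carbon_arcs <- function(path, net) {
  d <- read_tsv_checked(path, c("reaction", "substrate", "product"))
  d <- data.frame(reaction = as.character(d$reaction),
                  substrate = as.character(d$substrate),
                  product = as.character(d$product),
                  stringsAsFactors = FALSE)
  d <- unique(d)
  rownames(d) <- NULL
  validate_arcs(d, net)
  d
}

#' Split reversible reactions into forward/backward pairs
#'
#' Every reversible reaction is replaced by an irreversible forward copy and
#' a backward copy (suffix \code{"_rev"}) with negated stoichiometry; the two
#' are linked through \code{reverse_partner} and their joint activity is
#' excluded by the path model.  Carbon arcs of the original reaction are
#' mirrored (substrate/product swapped) onto the backward copy.  All fluxes
#' of the returned network may be taken nonnegative.  Idempotent.
#'
#' @param net an \code{icfp_network}.
#' @return the solver-ready irreversible network.
#' @export
split_reversible <- function(net) {
  out <- list()
  arcs <- net$arcs
  for (r in net$reactions) {
    if (!r$reversible) {
      out[[r$id]] <- r
      next
    }
    rev_id <- paste0(r$id, "_rev")
    fwd <- r
    fwd$reversible <- FALSE
    fwd$reverse_partner <- rev_id
    bwd <- r
    bwd$id <- rev_id
    bwd$stoich <- -r$stoich
    bwd$reversible <- FALSE
    bwd$reverse_partner <- r$id
    out[[fwd$id]] <- fwd
    out[[rev_id]] <- bwd
    sel <- arcs$reaction == r$id
    if (any(sel)) {
      mirrored <- data.frame(reaction = rev_id,
                             substrate = arcs$product[sel],
                             product = arcs$substrate[sel],
                             stringsAsFactors = FALSE)
      arcs <- rbind(arcs, mirrored)
    }
  }
  net$reactions <- out
  net$arcs <- unique(arcs)
  rownames(net$arcs) <- NULL
  validate_network(net)
  net
}

#' Declare the growth medium
#'
#' Metabolites named in \code{medium_ids} form the set E_m: they are left
#' unconstrained by the path model (free uptake and excretion).  Every other
#' external metabolite will be constrained to nonnegative net production
#' (can be produced, but not consumed).
#'
#' @param net an \code{icfp_network}.
#' @param medium_ids character vector of external metabolite ids.
#' @return the network with \code{in_medium} flags set accordingly.
#' @export
apply_medium <- function(net, medium_ids) {
  mets <- net$metabolites
  unknown <- setdiff(medium_ids, mets$id)
  if (length(unknown)) {
    stop("medium names unknown metabolites: ", paste(unknown, collapse = ", "))
  }
  internal <- intersect(medium_ids, mets$id[mets$is_internal])
  if (length(internal)) {
    stop("medium metabolites must be external: ",
         paste(internal, collapse = ", "))
  }
  net$metabolites$in_medium <- mets$id %in% medium_ids
  net
}
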