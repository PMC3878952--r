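## SBML import (Level 3 with the fbc extension, plus the legacy
## GENE_ASSOCIATION notes convention).  The tabular dialect is the
## authoritative exchange format for this package -- carbon-exchange arcs
## have no SBML representation and always come from the TSV side table --
## so this reader is a convenience mapping for metabolites, reactions and
## GPR rules only.  Species with boundaryCondition="true" are treated as
## external; everything else as internal.  Medium membership is declared
## afterwards with apply_medium().

read_network_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error parsing SBML: ",
                                           conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0L) stop("format error: SBML file has no species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    is_internal = !(xml2::xml_attr(sp, "boundaryCondition") %in% "true"),
    in_medium = FALSE,
    stringsAsFactors = FALSE)

  ## fbc gene products: id -> label
  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp, "label")), xml2::xml_attr(gp, "id"),
           xml2::xml_attr(gp, "label")),
    xml2::xml_attr(gp, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0L) stop("format error: SBML file has no reactions")
  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    refs <- function(which, sign) {
      sr <- xml2::xml_find_all(
        node, paste0("./s:", which, "/s:speciesReference"), ns)
      if (length(sr) == 0L) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(sr, "species"))
    }
    stoich <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    if (length(stoich) == 0L) {
      stop("format error: reaction ", rid, " has no participants")
    }
    ## merge duplicate species references
    stoich <- tapply(stoich, names(stoich), sum)
    stoich <- stats::setNames(as.numeric(stoich), names(stoich))
    gpa <- xml2::xml_find_first(
      node, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (!inherits(gpa, "xml_missing")) {
      sbml_gpa_string(xml2::xml_children(gpa)[[1]], gp_label)
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(node, ".//s:notes", ns))
      m <- regmatches(notes,
                      regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
      if (length(m)) trimws(sub("GENE_ASSOCIATION:", "", m)) else ""
    }
    list(id = rid, stoich = stoich,
         reversible = xml2::xml_attr(node, "reversible") %in% "true",
         gpr = gpr)
  })
  metabolic_network(mets, reactions)
}

## fbc:and / fbc:or / fbc:geneProductRef subtree -> GPR string
sbml_gpa_string <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- gp_label[ref]
    return(if (is.na(lab)) ref else unname(lab))
  }
  kids <- vapply(xml2::xml_children(node), sbml_gpa_string, character(1),
                 gp_label = gp_label)
  paste0("(", paste(kids, collapse = paste0(" ", nm, " ")), ")")
}
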