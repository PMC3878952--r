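## Gene-protein-reaction (GPR) Boolean rules.
##
## A GPR relates gene states to the activity evidence for a reaction:
## AND for enzyme complexes (all subunits required), OR for isoenzymes
## (any one suffices).  Rules are parsed once into a tree and evaluated
## under ternary logic: gene states are coded up = +1, invariant = 0,
## down = -1; AND takes the minimum over children, OR the maximum.

#' Parse a GPR rule string
#'
#' Grammar: \code{expr := term ("or" term)*}, \code{term := factor ("and"
#' factor)*}, \code{factor := gene | "(" expr ")"}.  Operators are
#' case-insensitive; \code{&} and \code{|} are accepted as synonyms.
#'
#' @param rule GPR string, e.g. \code{"(b0001 and b0002) or b0003"}.
#'   Empty or \code{NA} gives \code{NULL} (no gene evidence).
#' @return a tree of nested lists: operator nodes
#'   \code{list(op = "and"|"or", args = list(...))} and leaves
#'   \code{list(gene = "<id>")}, or \code{NULL}.
#' @examples
#' tr <- parse_gpr("(g1 and g2) or g3")
#' tr$op            # "or"
#' length(tr$args)  # 2
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule)) return(NULL)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(NULL)
  toks <- gpr_tokens(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_expr(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule near '", st$toks[st$pos], "': ", rule)
  }
  tree
}

gpr_tokens <- function(rule) {
  rule <- gsub("&{1,2}", " and ", rule)
  rule <- gsub("\\|{1,2}", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  low <- tolower(toks)
  ifelse(low %in% c("and", "or"), low, toks)
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_expr <- function(st) {
  args <- list(gpr_term(st))
  while (identical(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_term(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_term <- function(st) {
  args <- list(gpr_factor(st))
  while (identical(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_factor(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_factor <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR rule: unexpected end of input")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_expr(st)
    if (!identical(gpr_peek(st), ")")) stop("malformed GPR rule: missing ')'")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok %in% c(")", "and", "or")) {
    stop("malformed GPR rule: unexpected '", tok, "'")
  }
  st$pos <- st$pos + 1L
  list(gene = tok)
}

#' Evaluate a GPR tree under ternary logic
#'
#' @param tree parsed GPR tree from [parse_gpr()] (or \code{NULL}).
#' @param states named numeric vector of gene states in \{-1, 0, +1\};
#'   genes absent from \code{states} count as 0 (no evidence).
#' @return a value in \{-1, 0, +1\}; \code{0} for an empty rule.
#' @examples
#' eval_gpr(parse_gpr("g1 or g2"), c(g1 = 1, g2 = -1))   # +1
#' eval_gpr(parse_gpr("g1 and g2"), c(g1 = 1, g2 = 0))   #  0
#' @export
eval_gpr <- function(tree, states) {
  if (is.null(tree)) return(0)
  if (!is.null(tree$gene)) {
    v <- unname(states[tree$gene])
    return(if (is.na(v) || length(v) == 0L) 0 else v)
  }
  vals <- vapply(tree$args, eval_gpr, numeric(1), states = states)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Genes referenced by a GPR tree
#' @param tree parsed GPR tree (or \code{NULL}).
#' @return character vector of gene identifiers (empty for \code{NULL}).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (!is.null(tree$gene)) return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

## Render a GPR tree back to its string form (tabular round trips).
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (!is.null(tree$gene)) return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (is.null(a$gene)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
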