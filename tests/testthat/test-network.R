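test_that("the worked 10-metabolite example has the advertised shape", {
  fx <- figure1_fixture()
  expect_s3_class(fx$network, "icfp_network")
  expect_equal(nrow(fx$network$metabolites), 10)
  expect_length(fx$network$reactions, 12)
  expect_setequal(names(which(fx$states == "L")), paste0("r", c(9, 10, 11)))
  expect_setequal(names(which(fx$states == "M")), paste0("r", c(1, 6, 7, 12)))
  expect_setequal(names(which(fx$states == "H")), paste0("r", c(2, 3, 4, 5, 8)))
})

test_that("network validation rejects malformed input", {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     is_internal = c(FALSE, TRUE), in_medium = c(TRUE, FALSE))
  expect_error(metabolic_network(mets, list()), "empty reaction list")
  expect_error(
    metabolic_network(mets, list(list(id = "r1", stoich = c(A = -1, Z = 1),
                                      reversible = FALSE, gpr = ""))),
    "unknown metabolites")
  mets_bad <- transform(mets, in_medium = c(TRUE, TRUE))
  expect_error(
    metabolic_network(mets_bad,
                      list(list(id = "r1", stoich = c(A = -1, B = 1),
                                reversible = FALSE, gpr = ""))),
    "must be external")
})

test_that("tabular round trip is stable", {
  net <- random_network(7, 10, seed = 11)
  d1 <- file.path(tempdir(), "net1")
  d2 <- file.path(tempdir(), "net2")
  write_network_tsv(net, d1)
  net2 <- load_network(d1, "tabular")
  write_network_tsv(net2, d2)
  net3 <- load_network(d2, "tabular")
  expect_equal(net2$metabolites, net3$metabolites)
  expect_equal(names(net2$reactions), names(net3$reactions))
  for (id in names(net2$reactions)) {
    expect_equal(net2$reactions[[id]]$stoich, net3$reactions[[id]]$stoich)
    expect_equal(net2$reactions[[id]]$reversible,
                 net3$reactions[[id]]$reversible)
    expect_equal(net2$reactions[[id]]$gpr_tree, net3$reactions[[id]]$gpr_tree)
  }
  a2 <- net2$arcs[order(net2$arcs$reaction, net2$arcs$substrate, net2$arcs$product), ]
  a3 <- net3$arcs[order(net3$arcs$reaction, net3$arcs$substrate, net3$arcs$product), ]
  rownames(a2) <- rownames(a3) <- NULL
  expect_equal(a2, a3)
  # and the loaded network matches the generated one
  expect_setequal(net2$metabolites$id, net$metabolites$id)
  expect_setequal(names(net2$reactions), names(net$reactions))
})

test_that("reversible splitting mirrors arcs and is an involution-idempotent", {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     is_internal = c(FALSE, TRUE, FALSE),
                     in_medium = c(TRUE, FALSE, FALSE))
  reactions <- list(
    list(id = "rev", stoich = c(A = -1, B = 1), reversible = TRUE, gpr = "g1"),
    list(id = "f1", stoich = c(B = -1, C = 1), reversible = FALSE, gpr = ""),
    list(id = "f2", stoich = c(A = -1, C = 1), reversible = FALSE, gpr = ""))
  arcs <- data.frame(reaction = c("rev", "f1", "f2"),
                     substrate = c("A", "B", "A"),
                     product = c("B", "C", "C"), stringsAsFactors = FALSE)
  net <- metabolic_network(mets, reactions, arcs)
  sp <- split_reversible(net)
  expect_length(sp$reactions, 4)
  expect_equal(sp$reactions[["rev"]]$reverse_partner, "rev_rev")
  expect_equal(sp$reactions[["rev_rev"]]$reverse_partner, "rev")
  expect_equal(sp$reactions[["rev_rev"]]$stoich, -sp$reactions[["rev"]]$stoich)
  expect_false(any(vapply(sp$reactions, `[[`, logical(1), "reversible")))
  # mirrored arc on the backward copy
  expect_true(any(sp$arcs$reaction == "rev_rev" & sp$arcs$substrate == "B" &
                    sp$arcs$product == "A"))
  # idempotent
  sp2 <- split_reversible(sp)
  expect_equal(names(sp2$reactions), names(sp$reactions))
  expect_equal(sp2$arcs, sp$arcs)
})

test_that("medium declaration constrains the right metabolites", {
  fx <- figure1_fixture(verify = FALSE)
  net <- apply_medium(fx$network, c("A", "W"))
  expect_setequal(net$metabolites$id[net$metabolites$in_medium], c("A", "W"))
  expect_error(apply_medium(fx$network, "B"), "must be external")
  expect_error(apply_medium(fx$network, "nope"), "unknown")
  # empty medium: every external metabolite producible-only
  net0 <- apply_medium(fx$network, character(0))
  expect_false(any(net0$metabolites$in_medium))
})

test_that("carbon arc tables are validated and deduplicated", {
  net <- chain_network(2)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("reaction\tsubstrate\tproduct",
               "c1\tsrc\tm1", "c1\tsrc\tm1", "c2\tm1\ttgt"), f)
  arcs <- load_carbon_arcs(f, net)
  expect_equal(nrow(arcs), 2)
  # substrate that is actually a product -> rejected, naming the triple
  writeLines(c("reaction\tsubstrate\tproduct", "c1\tm1\tsrc"), f)
  expect_error(load_carbon_arcs(f, net), "sign convention.*c1")
})

test_that("SBML import maps species, stoichiometry and both GPR encodings", {
  path <- system.file("extdata", "toy_chain.sbml.xml", package = "icfp")
  net <- load_network(path, "sbml")
  expect_equal(nrow(net$metabolites), 4)
  expect_length(net$reactions, 3)
  expect_setequal(net$metabolites$id[!net$metabolites$is_internal],
                  c("glc_e", "pyr_e"))
  expect_true(net$reactions[["PGI"]]$reversible)
  expect_equal(net$reactions[["LOWER"]]$stoich, c(f6p_c = -1, pyr_e = 2))
  # fbc association: b0002 or (b0003 and b0004)
  tr <- net$reactions[["PGI"]]$gpr_tree
  expect_equal(tr$op, "or")
  expect_setequal(gpr_genes(tr), c("b0002", "b0003", "b0004"))
  # notes fallback
  expect_setequal(gpr_genes(net$reactions[["LOWER"]]$gpr_tree),
                  c("b0002", "b0003"))
  expect_error(load_network(tempfile(), "sbml"), "not found")
})
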