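test_that("staged optimisation reproduces the worked example end to end", {
  fx <- figure1_fixture(verify = FALSE)
  net <- split_reversible(fx$network)
  q <- path_query("A", "E", k = 1)
  model <- build_cfp_model(net, q, fx$states)

  V1 <- solve_stage1(model)
  expect_equal(V1, 0)
  V2 <- solve_stage2(model, V1)
  expect_equal(V2, 2)           # unit flux through reactions 6 and 7
  sol <- solve_stage3(model, V1, V2)
  expect_equal(sol$nodes, c("A", "F", "G", "P", "E"))
  expect_setequal(sol$active_reactions, c("r2", "r4", "r6", "r7"))
  expect_equal(unname(sol$staged_objective), c(0, 2, 4))
})

test_that("mandatory lowly or medium reactions price into V1 and V2", {
  # src -> m1 -> m2 -> tgt with the middle step lowly expressed
  net <- chain_network(3)
  stL <- c(c1 = "H", c2 = "L", c3 = "H")
  fit <- icfp(net, "src", "tgt", states = stL)
  expect_equal(fit$paths[[1]]$staged_objective[["V1"]], 1)
  expect_equal(fit$paths[[1]]$staged_objective[["V2"]], 0)

  stM <- c(c1 = "H", c2 = "M", c3 = "H")
  fit2 <- icfp(net, "src", "tgt", states = stM)
  expect_equal(fit2$paths[[1]]$staged_objective[["V1"]], 0)
  expect_equal(fit2$paths[[1]]$staged_objective[["V2"]], 1)

  # all-H network balances with V2 = 0
  stH <- c(c1 = "H", c2 = "H", c3 = "H")
  fit3 <- icfp(net, "src", "tgt", states = stH)
  expect_equal(fit3$paths[[1]]$staged_objective[["V2"]], 0)
})

test_that("ranked enumeration is lexicographic, sound and exhaustive", {
  fx <- figure1_fixture(verify = FALSE)
  fit <- icfp(fx$network, "A", "E", k = 3, states = fx$states)
  expect_length(fit$paths, 2)
  expect_true(fit$exhausted)
  t1 <- tuple_of(fit$paths[[1]])
  t2 <- tuple_of(fit$paths[[2]])
  expect_equal(t1, c(0, 2, 4))
  expect_equal(t2, c(2, 0, 3))
  # lexicographic order
  expect_true(t1[1] < t2[1] ||
                (t1[1] == t2[1] && (t1[2] < t2[2] ||
                                      (t1[2] == t2[2] && t1[3] <= t2[3]))))
  # elimination soundness: no later solution contains an earlier arc set
  a1 <- paste(fit$paths[[1]]$arcs$i, fit$paths[[1]]$arcs$j)
  a2 <- paste(fit$paths[[2]]$arcs$i, fit$paths[[2]]$arcs$j)
  expect_false(all(a1 %in% a2))

  # two-path network: exactly two solutions, then exhaustion notice
  net2 <- two_path_network()
  expect_message(fit2 <- icfp(net2, "src", "tgt", k = 5),
                 "exhausted after 2")
  expect_length(fit2$paths, 2)
  expect_equal(fit2$paths[[1]]$staged_objective[["length"]], 2)
  expect_equal(fit2$paths[[2]]$staged_objective[["length"]], 3)
})

test_that("enumeration is deterministic run to run", {
  net <- random_network(8, 12, seed = 5)
  gs <- stats::setNames(rep(c("up", "down", "invariant"), length.out =
                              length(network_genes(net))),
                        network_genes(net))
  states <- map_to_reactions(net, gs)
  f1 <- icfp(net, attr(net, "source"), attr(net, "target"), k = 3,
             states = states)
  f2 <- icfp(net, attr(net, "source"), attr(net, "target"), k = 3,
             states = states)
  expect_equal(lapply(f1$paths, `[[`, "arcs"),
               lapply(f2$paths, `[[`, "arcs"))
  expect_equal(lapply(f1$paths, `[[`, "fluxes"),
               lapply(f2$paths, `[[`, "fluxes"))
})

test_that("without expression signal the solver reduces to shortest balanced paths", {
  fx <- figure1_fixture(verify = FALSE)
  plain <- icfp(fx$network, "A", "E", k = 1)
  expect_equal(plain$paths[[1]]$nodes, c("A", "B", "C", "E"))
  expect_equal(unname(plain$paths[[1]]$staged_objective), c(0, 0, 3))
  # an all-M classification is the same thing
  allM <- icfp(fx$network, "A", "E", k = 1,
               states = stats::setNames(rep("M", 12), paste0("r", 1:12)))
  expect_equal(allM$paths[[1]]$nodes, plain$paths[[1]]$nodes)
})

test_that("an unreachable target raises a typed no-path error", {
  net <- chain_network(2)
  expect_error(icfp(net, "tgt", "src"), class = "icfp_no_path")
})

test_that("fold-change input classifies and solves in one call", {
  fx <- figure1_fixture(verify = FALSE)
  # push the long route's genes up, the short route's balancers down
  fc <- stats::setNames(rep(0, 12), paste0("g", 1:12))
  fc[c("g2", "g4")] <- 1
  fc[c("g10", "g11")] <- -1
  fit <- icfp(fx$network, "A", "E", k = 1, log2fc = fc)
  expect_equal(fit$paths[[1]]$nodes, c("A", "F", "G", "P", "E"))
  expect_equal(fit$paths[[1]]$staged_objective[["V1"]], 0)
})

test_that("fitted objects print, summarise, tabulate and export", {
  fx <- figure1_fixture(verify = FALSE)
  fit <- icfp(fx$network, "A", "E", k = 2, states = fx$states)
  expect_output(print(fit), "A -> F -> G -> P -> E")
  expect_output(print(summary(fit)), "V1")
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$V1, c(0, 2))
  d <- file.path(tempdir(), "paths_out")
  write_paths(fit, d)
  expect_true(file.exists(file.path(d, "paths.tsv")))
  js <- jsonlite::read_json(file.path(d, "paths.json"))
  expect_length(js, 2)
  expect_equal(js[[1]]$V1, 0)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
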