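test_that("preprocessing filters to metabolic genes and routes short series", {
  conds <- seq(0.1, 0.45, length.out = 8)
  s_ok <- expression_series("gA", rnorm(8, 7), conds)
  s_short <- expression_series("gB", c(7, 7.2, NA, NA, NA, NA, NA, 7.1), conds)
  s_alien <- expression_series("not_metabolic", rnorm(8, 7), conds)
  pp <- preprocess(list(s_ok, s_short, s_alien), metabolic_genes = c("gA", "gB"))
  expect_equal(vapply(pp$kept, `[[`, character(1), "feature_id"), "gA")
  expect_equal(pp$dropped_to_invariant, "gB")

  # raw route log2-transforms once and rejects non-positive intensities
  s_raw <- expression_series("gA", 2^c(7, 7.5, 8, 8.5, 9, 9.5, 10, 10.5), conds)
  pp2 <- preprocess(list(s_raw), "gA", values_are_log2 = FALSE)
  expect_equal(pp2$kept[[1]]$values, c(7, 7.5, 8, 8.5, 9, 9.5, 10, 10.5))
  s_bad <- expression_series("gA", c(-1, 2, 3, 4, 5, 6, 7, 8), conds)
  expect_error(preprocess(list(s_bad), "gA", values_are_log2 = FALSE),
               "non-positive.*gA")
})

test_that("threshold regression test matches its closed form", {
  conds <- seq(0.1, 0.45, length.out = 8)
  # deterministic series, fixed by hand; expectation computed from the
  # two shifted t tails of the OLS fit
  y <- c(7.00, 7.15, 7.42, 7.55, 7.58, 7.90, 8.02, 8.13)
  r <- threshold_regression_test(expression_series("g", y, conds))
  x <- conds
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit <- mean(y) + b * (x - mean(x))
  s2 <- sum((y - fit)^2) / 6
  se <- sqrt(s2 / sum((x - mean(x))^2)) * (max(x) - min(x))
  eff <- b * (max(x) - min(x))
  tau <- log2(1.5)
  p_exp <- pt((abs(eff) - tau) / se, 6, lower.tail = FALSE) +
    pt((abs(eff) + tau) / se, 6, lower.tail = FALSE)
  expect_equal(r$p_value, min(1, p_exp), tolerance = 1e-12)
  expect_equal(r$sign, 1)
  expect_equal(r$effect, eff, tolerance = 1e-12)
})

test_that("threshold regression handles degenerate series per convention", {
  conds <- seq(0.1, 0.45, length.out = 8)
  # flat series: no change can exceed a positive threshold
  flat <- threshold_regression_test(expression_series("g", rep(7, 8), conds))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$sign, 0)
  # noiseless planted change of 2 log2 units: limiting step test
  y <- 7 + 2 * (conds - min(conds)) / diff(range(conds))
  sharp <- threshold_regression_test(expression_series("g", y, conds))
  expect_lt(sharp$p_value, 0.05)
  expect_equal(sharp$p_value, 0)
  expect_equal(sharp$sign, 1)
  # zero condition variance: no direction estimable
  same <- threshold_regression_test(
    expression_series("g", rnorm(8), rep(0.2, 8)))
  expect_equal(same$p_value, 1)
  expect_equal(same$sign, 0)
  # effect exactly at the threshold: p >= 0.5 whatever the noise level
  # (residual pattern orthogonal to the covariate leaves the slope exact)
  resid <- c(1, -1, -1, 1, 1, -1, -1, 1)
  for (amp in c(0.05, 0.2, 0.8)) {
    yb <- 7 + log2(1.5) * (conds - min(conds)) / diff(range(conds)) +
      amp * resid
    r <- threshold_regression_test(expression_series("g", yb, conds))
    expect_gte(r$p_value, 0.5)
  }
  expect_error(
    threshold_regression_test(expression_series("g", c(1, 2, 3, NA, NA, NA, NA, NA), conds)),
    ">= 4 measurements")
})

test_that("test p-values track limma's treat on a common batch", {
  conds <- seq(0.11, 0.46, length.out = 8)
  set.seed(7)
  n <- 150
  eff <- sample(c(0, 1.2, -1.2), n, TRUE)
  xr <- (conds - min(conds)) / diff(range(conds))
  Y <- matrix(rnorm(n * 8, 7, 0.3), n, 8) + outer(eff, xr)
  fit <- limma::lmFit(Y, cbind(1, conds))
  pl <- limma::treat(limma::eBayes(fit), lfc = log2(1.5))$p.value[, 2]
  mine <- vapply(seq_len(n), function(i) {
    threshold_regression_test(expression_series(paste0("g", i), Y[i, ], conds))$p_value
  }, numeric(1))
  # same test statistic family; limma moderates variances, so expect strong
  # rank agreement rather than equality
  expect_gt(cor(mine, pl, method = "spearman"), 0.95)
  # moderation with a large prior approaches limma under homoskedastic data
  mod <- threshold_regression_tests(
    lapply(seq_len(n), function(i) expression_series(paste0("g", i), Y[i, ], conds)),
    moderate = TRUE, prior_df = 1e6)
  expect_gt(cor(mod$p_value, pl, method = "spearman"), 0.98)
})

test_that("FDR estimation: Benjamini-Hochberg values and input checking", {
  expect_equal(estimate_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(estimate_fdr(0.5), 0.5)
  expect_equal(estimate_fdr(rep(1, 5)), rep(1, 5))
  expect_error(estimate_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # density route: q-values are in [0,1], monotone in p, and liberal at
  # most by the estimated null fraction
  set.seed(3)
  p <- c(rbeta(60, 0.2, 8), runif(240))
  q <- estimate_fdr(p, method = "grenander")
  expect_true(all(q >= 0 & q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("gene/protein merging takes the protein call wholesale", {
  gc <- data.frame(feature_id = c("a", "b"), p_value = c(0.01, 0.2),
                   q_value = NA_real_, sign = c(1, -1), source = "gene",
                   stringsAsFactors = FALSE)
  pc <- data.frame(feature_id = "a", p_value = 0.6, q_value = NA_real_,
                   sign = -1, source = "protein", stringsAsFactors = FALSE)
  m <- merge_gene_protein(gc, pc, all_features = c("a", "b", "c"))
  expect_equal(nrow(m), 3)
  a <- m[m$feature_id == "a", ]
  expect_equal(a$p_value, 0.6)
  expect_equal(a$sign, -1)
  expect_equal(a$source, "protein")
  expect_equal(m$source[m$feature_id == "b"], "gene")
  cc <- m[m$feature_id == "c", ]
  expect_equal(cc$source, "none")
  expect_equal(cc$sign, 0)
})

test_that("differential calling is strict at the FDR boundary", {
  calls <- data.frame(feature_id = c("a", "b", "c", "d"),
                      p_value = 0.01, q_value = c(0.1, 0.2, 0.05, 0.19),
                      sign = c(1, 1, 0, -1), source = "gene",
                      stringsAsFactors = FALSE)
  st <- call_differential(calls, fdr_cut = 0.2)
  expect_equal(unname(st), c("up", "invariant", "invariant", "down"))
  # monotonicity: raising the cut never reverts a call to invariant
  for (cut in c(0.05, 0.1, 0.25, 0.5)) {
    lo <- call_differential(calls, fdr_cut = cut)
    hi <- call_differential(calls, fdr_cut = cut + 0.1)
    called_lo <- lo != "invariant"
    expect_true(all(hi[called_lo] == lo[called_lo]))
  }
})

test_that("fold-change classification thresholds at 1.5-fold", {
  st <- classify_by_fold_change(c(a = 0.60, b = -0.60, c = 0, d = 0.5850,
                                  e = NA))
  expect_equal(unname(st), c("up", "down", "invariant", "invariant",
                             "invariant"))
})

test_that("gene states map onto reactions through GPRs as a partition", {
  net <- chain_network(3)
  net$reactions[["c1"]]$gpr_tree <- parse_gpr("g1 or g2")
  net$reactions[["c2"]]$gpr_tree <- parse_gpr("g1 and g2")
  net$reactions[["c3"]]$gpr_tree <- NULL
  st <- map_to_reactions(net, c(g1 = "up", g2 = "down"))
  expect_equal(unname(st), c("H", "L", "M"))
  st2 <- map_to_reactions(net, c(g1 = "up", g2 = "invariant"))
  expect_equal(unname(st2["c2"]), "M")
  # partition and purity
  expect_equal(sum(st == "H") + sum(st == "M") + sum(st == "L"), 3)
  expect_identical(st, map_to_reactions(net, c(g1 = "up", g2 = "down")))
  # split reversible pairs share the state
  fxnet <- split_reversible(chain_network(2))
  expect_error(map_to_reactions(net, c(g1 = "sideways")), "unknown gene state")
})

test_that("the full classification front end runs both routes", {
  net <- random_network(6, 8, seed = 3)
  genes <- network_genes(net)
  sim <- synthetic_expression(length(genes), frac_up = 0.3, frac_down = 0.3,
                              noise_sd = 0.05, seed = 4, feature_ids = genes)
  cl <- classify_reactions(net, series = sim$series)
  expect_s3_class(cl, "reaction_classification")
  expect_equal(nrow(cl), length(net$reactions))
  expect_true(all(cl$state %in% c("H", "M", "L")))
  cnt <- attr(cl, "counts")
  expect_equal(cnt$n_H + cnt$n_M + cnt$n_L, length(net$reactions))

  fc <- stats::setNames(c(2, -2, 0), genes[1:3])
  cl2 <- classify_reactions(net, log2fc = fc)
  expect_equal(nrow(cl2), length(net$reactions))
  expect_error(classify_reactions(net), "exactly one")
  expect_error(classify_reactions(net, series = sim$series, log2fc = fc),
               "exactly one")
  # writer produces a readable TSV
  f <- tempfile(fileext = ".tsv")
  write_classification(cl, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(cl))
})
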