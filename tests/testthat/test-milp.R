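# The optimisation kernel backing both the path model and the reference
# implementation.  LP results are cross-checked against boot::simplex and
# an independent mixed-integer check against scipy via the system python.

test_that("the LP layer solves, detects infeasibility and unboundedness", {
  r <- icfp:::solve_lp(c(-1, -2), rbind(c(1, 1), c(1, 0)), c("<=", "<="),
                       c(4, 2))
  expect_equal(r$status, "optimal")
  expect_equal(r$objval, -8)
  expect_equal(r$x, c(0, 4))

  r2 <- icfp:::solve_lp(c(1, 1), rbind(c(1, 1), c(1, 0)), c("=", ">="),
                        c(3, 1))
  expect_equal(r2$objval, 3)

  r3 <- icfp:::solve_lp(c(1, 0), rbind(c(1, 0), c(1, 0)), c("<=", ">="),
                        c(1, 2))
  expect_equal(r3$status, "infeasible")

  r4 <- icfp:::solve_lp(c(-1, 0), matrix(c(0, 1), 1, 2), "<=", 1)
  expect_equal(r4$status, "unbounded")

  # bounds are honoured (lb shifted, ub as rows)
  r5 <- icfp:::solve_lp(c(-1, -1), matrix(c(1, 1), 1, 2), "<=", 10,
                        lb = c(1, 0), ub = c(3, 2))
  expect_equal(r5$objval, -5)
})

test_that("LP optima agree with boot::simplex on random programs", {
  set.seed(11)
  checked <- 0
  for (i in 1:120) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    A <- matrix(sample(-3:3, m * n, TRUE), m, n)
    b <- runif(m, 0, 5); cc <- runif(n, -2, 2)
    dirs <- sample(c("<=", ">=", "="), m, TRUE, prob = c(.6, .2, .2))
    mine <- icfp:::solve_lp(cc, A, dirs, b)
    A1 <- A[dirs == "<=", , drop = FALSE]; b1 <- b[dirs == "<="]
    A2 <- A[dirs == ">=", , drop = FALSE]; b2 <- b[dirs == ">="]
    A3 <- A[dirs == "=", , drop = FALSE];  b3 <- b[dirs == "="]
    bs <- tryCatch(boot::simplex(cc, A1, b1,
                                 if (nrow(A2)) A2 else NULL,
                                 if (nrow(A2)) b2 else NULL,
                                 if (nrow(A3)) A3 else NULL,
                                 if (nrow(A3)) b3 else NULL, maxi = FALSE),
                   error = function(e) NULL, warning = function(w) NULL)
    # only compare where boot reaches a clean optimum itself
    if (is.null(bs) || bs$solved != 1) next
    checked <- checked + 1
    expect_equal(mine$status, "optimal", info = paste("case", i))
    expect_equal(mine$objval, unname(bs$value), tolerance = 1e-7,
                 info = paste("case", i))
  }
  expect_gt(checked, 15)
})

test_that("branch and bound proves optima on known mixed problems", {
  # 0/1 knapsack: max 10x1+13x2+7x3, 5x1+7x2+4x3 <= 10
  r <- icfp:::solve_milp(c(-10, -13, -7), matrix(c(5, 7, 4), 1, 3), "<=", 10,
                         bin = 1:3)
  expect_equal(r$objval, -17)
  expect_equal(r$x, c(1, 0, 1))
  # mixed binary/continuous
  r2 <- icfp:::solve_milp(c(-1, -0.5), matrix(c(1, 1), 1, 2), "<=", 3.5,
                          ub = c(1, 3), bin = 1)
  expect_equal(r2$objval, -2.25)
  expect_equal(r2$x, c(1, 2.5))
  # infeasible integer restriction of a feasible relaxation
  r3 <- icfp:::solve_milp(c(1), matrix(c(1, 1), 2, 1), c(">=", "<="),
                          c(0.25, 0.75), ub = 1, bin = 1)
  expect_equal(r3$status, "infeasible")
})

test_that("branch and bound agrees with an external solver", {
  set.seed(21)
  cases <- lapply(1:8, function(i) {
    n <- sample(3:7, 1); m <- sample(2:5, 1)
    list(A = matrix(sample(-3:3, m * n, TRUE), m, n),
         b = runif(m, 0, 6), cc = round(runif(n, -3, 3), 3),
         dirs = sample(c("<=", ">=", "="), m, TRUE, prob = c(.7, .2, .1)),
         bin = sort(sample(n, sample(n, 1))), ub = rep(10, n))
  })
  mine <- lapply(cases, function(d) {
    r <- icfp:::solve_milp(d$cc, d$A, d$dirs, d$b, ub = d$ub, bin = d$bin)
    list(status = r$status, obj = if (r$status == "optimal") r$objval else NA)
  })
  payload <- jsonlite::toJSON(list(cases = cases, mine = mine), digits = NA)
  f <- tempfile(fileext = ".json")
  writeLines(payload, f)
  script <- '
import json, sys, numpy as np
from scipy.optimize import milp, LinearConstraint, Bounds
d = json.load(open(sys.argv[1]))
bad = 0
for case, res in zip(d["cases"], d["mine"]):
    A = np.array(case["A"], float); b = np.array(case["b"], float).ravel()
    c = np.array(case["cc"], float).ravel(); dirs = case["dirs"]
    binidx = np.array(case["bin"], int).ravel() - 1
    n = len(c)
    lo = np.full(len(b), -np.inf); hi = np.array(b, float)
    for i, s in enumerate(dirs):
        if s == ">=": lo[i], hi[i] = b[i], np.inf
        elif s == "=": lo[i] = b[i]
    integ = np.zeros(n); integ[binidx] = 1
    ub = np.array(case["ub"], float).ravel(); ub[binidx] = 1
    r = milp(c, constraints=LinearConstraint(A, lo, hi), integrality=integ,
             bounds=Bounds(0, ub))
    st = "optimal" if r.status == 0 else ("infeasible" if r.status == 2 else str(r.status))
    mst = res["status"][0]
    mobj = res["obj"][0] if res["obj"] else None
    if st != mst or (st == "optimal" and abs(r.fun - mobj) > 1e-5):
        bad += 1
print(bad)
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- suppressWarnings(system2("python", c(sf, f), stdout = TRUE,
                                  stderr = TRUE))
  expect_equal(tail(out, 1), "0")
})
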