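test_that("simple LPs solve to their known optima", {
  p <- lp_problem(c(x = 1), "max",
                  matrix(1, 1, 1, dimnames = list(NULL, "x")),
                  "L", 3, lb = c(x = -Inf), ub = c(x = Inf), vars = "x")
  r <- solve_lp(p)
  expect_identical(r$status, "optimal")
  expect_equal(r$objective_value, 3)
  expect_equal(unname(r$fluxes["x"]), 3)
})

test_that("infeasible and unbounded systems are classified", {
  A <- matrix(c(1, 1), 2, 1, dimnames = list(NULL, "x"))
  infeas <- lp_problem(c(x = 1), "max", A, c("G", "L"), c(1, 0),
                       lb = c(x = -Inf), ub = c(x = Inf), vars = "x")
  expect_identical(solve_lp(infeas)$status, "infeasible")
  unb <- lp_problem(c(x = 1), "max",
                    matrix(1, 1, 1, dimnames = list(NULL, "x")),
                    "G", 0, lb = c(x = 0), ub = c(x = Inf), vars = "x")
  expect_identical(solve_lp(unb)$status, "unbounded")
})

test_that("problem validation rejects malformed systems", {
  A <- matrix(1, 1, 1, dimnames = list(NULL, "x"))
  expect_error(lp_problem(c(y = 1), "max", A, "L", 1, 0, 1, "x"),
               "unknown variables")
  expect_error(lp_problem(c(x = 1), "max", A, "L", 1, lb = 2, ub = 1, "x"),
               "lb > ub")
  expect_error(lp_problem(c(x = 1), "max", A, "L", 1, 0, 5, "x",
                          integers = "x"),
               "within \\[0, 1\\]")
  p <- lp_problem(c(x = 1), "max", A, "L", 1, 0, 1, "x")
  expect_error(solve_milp(p), "no integer variables")
})

test_that("set-cover MILP matches the enumeration optimum", {
  # min x1+x2+x3 with pairwise covering rows; brute-force optimum is 2
  vars <- paste0("x", 1:3)
  A <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  colnames(A) <- vars
  p <- lp_problem(stats::setNames(rep(1, 3), vars), "min", A,
                  rep("G", 3), rep(1, 3), rep(0, 3), rep(1, 3), vars,
                  integers = vars)
  r <- solve_milp(p)
  expect_identical(r$status, "optimal")
  brute <- min(vapply(1:7, function(m) {
    x <- as.integer(bitwAnd(m, c(1L, 2L, 4L)) > 0)
    if (all(A %*% x >= 1)) sum(x) else NA_integer_
  }, integer(1)), na.rm = TRUE)
  expect_equal(r$objective_value, brute)
  expect_equal(unname(round(r$objective_value)), 2)
  expect_lt(abs(round(r$objective_value) - r$objective_value), 1e-6)
})

test_that("fixing all binaries reduces the MILP to an LP feasibility check", {
  vars <- c("x", "b")
  A <- matrix(c(1, -1), 1, 2, dimnames = list(NULL, vars))
  p <- lp_problem(c(b = 1), "min", A, "L", 0, lb = c(0, 1), ub = c(2, 1),
                  vars = vars, integers = "b")
  r <- solve_milp(p)
  expect_identical(r$status, "optimal")
  expect_equal(r$objective_value, 1)
  expect_equal(unname(r$membership["b"]), 1)
})

test_that("LP optima agree with the scipy/HiGHS backend on community problems", {
  probs <- list()
  for (name in c("toy_3", "toy_5_redundant", "toy_9_demo")) {
    toy <- toy_fixture(name)
    bio <- toy$comm$biomass
    probs[[length(probs) + 1L]] <-
      minicom:::community_lp(toy$comm,
                             stats::setNames(rep(1, length(bio)), bio))
    w <- minicom:::scfa_objective(toy$comm, functionality_spec(3))
    probs[[length(probs) + 1L]] <-
      minicom:::community_lp(toy$comm, w)
  }
  own <- lapply(probs, solve_lp)
  ref <- minicom:::scipy_solve(probs)
  for (i in seq_along(probs)) {
    expect_identical(own[[i]]$status, ref[[i]]$status)
    expect_equal(own[[i]]$objective_value, ref[[i]]$objective_value,
                 tolerance = 1e-6)
  }
})

test_that("random bounded LPs agree with the scipy backend", {
  set.seed(42)
  mk <- function() {
    n <- sample(4:15, 1); m <- sample(2:10, 1)
    A <- matrix(rnorm(m * n), m, n)
    A[abs(A) < 0.5] <- 0
    vars <- paste0("x", seq_len(n)); colnames(A) <- vars
    lb <- sample(c(-5, 0), n, TRUE)
    ub <- lb + sample(c(1, 5, 10), n, TRUE)
    x0 <- (lb + ub) / 2
    rs <- sample(c("E", "L", "G"), m, TRUE)
    rhs <- as.numeric(A %*% x0) +
      ifelse(rs == "L", 0.5, ifelse(rs == "G", -0.5, 0))
    lp_problem(stats::setNames(rnorm(n), vars), sample(c("max", "min"), 1),
               A, rs, rhs, lb, ub, vars)
  }
  probs <- lapply(1:25, function(i) mk())
  own <- lapply(probs, solve_lp)
  ref <- minicom:::scipy_solve(probs)
  for (i in seq_along(probs)) {
    expect_identical(own[[i]]$status, ref[[i]]$status)
    if (own[[i]]$status == "optimal")
      expect_equal(own[[i]]$objective_value, ref[[i]]$objective_value,
                   tolerance = 1e-6)
  }
})

test_that("membership MILP objectives are integral", {
  toy <- toy_fixture("toy_9_demo")
  spec <- functionality_spec(3)
  tt <- toy_targets(toy, spec)
  p <- minicom:::build_membership_milp(toy$comm, spec, tt$targets)
  r <- solve_milp(p)
  expect_identical(r$status, "optimal")
  expect_lt(abs(round(r$objective_value) - r$objective_value), 1e-6)
  expect_true(all(abs(r$membership - round(r$membership)) < 1e-6))
})
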