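test_that("textbook LPs are solved to high accuracy", {
  # max 3x + 5y s.t. x <= 4, 2y <= 12, 3x + 2y <= 18 -> (2, 6), 36
  r <- solve_lp(c(3, 5), rbind(c(1, 0), c(0, 2), c(3, 2)),
                c("<=", "<=", "<="), c(4, 12, 18), maximize = TRUE)
  expect_equal(r$status, "optimal")
  expect_equal(r$x, c(2, 6), tolerance = 1e-7)
  expect_equal(r$objval, 36, tolerance = 1e-7)

  # equality + finite upper bound
  r2 <- solve_lp(c(1, 2), rbind(c(1, 1)), "=", 1,
                 lb = 0, ub = c(0.3, Inf))
  expect_equal(r2$x, c(0.3, 0.7), tolerance = 1e-6)

  # free variable
  r3 <- solve_lp(c(1, 0), rbind(c(1, 1), c(0, 1)), c(">=", "<="),
                 c(2, 1), lb = c(-Inf, 0))
  expect_equal(r3$x[1], 1, tolerance = 1e-6)
})

test_that("infeasibility and unboundedness are certified, not conflated", {
  r <- solve_lp(1, rbind(1, 1), c(">=", "<="), c(2, 1))
  expect_equal(r$status, "infeasible")
  r2 <- solve_lp(-1, rbind(1), ">=", 0)
  expect_equal(r2$status, "unbounded")
  e <- solve_lp_elastic(NULL, rbind(1, 1), c(">=", "<="), c(2, 1))
  expect_false(e$feasible)
  expect_gt(e$infeas, 0.1)
  e2 <- solve_lp_elastic(NULL, rbind(1, 1), c(">=", "<="), c(1, 2))
  expect_true(e2$feasible)
})

test_that("solutions agree with an epsilon-regularized QP oracle", {
  skip_if_not_installed("quadprog")
  set.seed(42)
  for (case in 1:5) {
    n <- 4
    A <- matrix(round(stats::rnorm(2 * n), 2), 2, n)
    x0 <- abs(round(stats::rnorm(n), 2)) + 0.5   # feasible by construction
    b <- as.numeric(A %*% x0)
    cc <- abs(round(stats::rnorm(n), 2)) + 0.1   # bounded objective
    r <- solve_lp(cc, A, c("=", "="), b, lb = 0, ub = Inf)
    expect_equal(r$status, "optimal")
    # oracle: min eps/2 x'x + c'x on the same constraints (quadprog needs
    # strict convexity; small eps barely perturbs the LP optimum)
    qp <- quadprog::solve.QP(Dmat = diag(1e-7, n), dvec = -cc,
                             Amat = cbind(t(A), diag(n)),
                             bvec = c(b, numeric(n)), meq = 2)
    expect_equal(r$objval, sum(cc * qp$solution), tolerance = 1e-4)
  }
})

test_that("the solver is deterministic across repeated calls", {
  A <- rbind(c(1, 2, 1), c(2, 0.5, 1))
  r1 <- solve_lp(c(1, 1, 1), A, c(">=", ">="), c(2, 1.5))
  r2 <- solve_lp(c(1, 1, 1), A, c(">=", ">="), c(2, 1.5))
  expect_identical(r1$x, r2$x)
  expect_identical(r1$objval, r2$objval)
})
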