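# closed-form oracle: with one self-catalyzing producer, amounts follow
# M^k = M^{k-1} (1 + kcat dt), so alpha* = (1 + kcat dt)^{n_t}
autocat_alpha <- function(kcat_per_h, T_hours, n_t) {
  (1 + kcat_per_h * T_hours / n_t)^n_t
}

test_that("feasibility flips exactly at the closed-form growth factor", {
  m <- single_autocatalyst_model(kcat_per_h = 0.1)
  g <- tiny_grid(n_t = 8)
  a_star <- autocat_alpha(0.1, 24, 8)
  expect_true(is_feasible(m, g, NULL, a_star * 0.999)$feasible)
  expect_false(is_feasible(m, g, NULL, a_star * 1.001)$feasible)
  expect_false(is_feasible(m, g, NULL, 1e6)$feasible)
})

test_that("bisection reproduces the Euler closed form to high accuracy", {
  m <- single_autocatalyst_model(kcat_per_h = 0.1)
  g <- make_grid(24, 48, 24)
  tr <- maximize_alpha(m, g, tol = 1e-7)
  expect_equal(tr$alpha, autocat_alpha(0.1, 24, 48), tolerance = 1e-6)
  # trajectory follows the geometric recursion
  expect_equal(tr$M[, "E"], (1 + 0.1 * 0.5)^(0:48), tolerance = 1e-4)
})

test_that("a model with nothing to grow maintains alpha = 1", {
  m <- cfba_model(
    compounds = data.frame(id = "C", kind = "dynamic", biomass_weight = 1),
    reactions = list(list(id = "drain", stoichiometry = c(C = -1))),
    biomass_start_cap = 1)
  g <- tiny_grid(n_t = 3)
  tr <- maximize_alpha(m, g, tol = 1e-6)
  expect_equal(tr$alpha, 1, tolerance = 1e-5)
})

test_that("infeasible self-maintenance raises a distinct error", {
  # maintenance demands flux but the only reaction cannot run (ub = 0)
  m <- cfba_model(
    compounds = data.frame(id = "C", kind = "dynamic", biomass_weight = 1),
    reactions = list(list(id = "work", stoichiometry = c(C = 1e-9),
                          upper_bound = 0)),
    maintenance_constraints = list(list(flux_terms = c(work = 1),
                                        biomass_coefficient = 1,
                                        biomass_per = "hour")),
    biomass_start_cap = 1)
  g <- tiny_grid(n_t = 2)
  expect_error(maximize_alpha(m, g), "no-growth-infeasible")
})

test_that("bisection agrees with a dense feasibility grid search", {
  for (seed in c(3, 11)) {
    m <- random_autocatalytic_model(seed, 3)
    g <- tiny_grid(n_t = 6)
    tr <- maximize_alpha(m, g, tol = 1e-5)
    # independent oracle: scan a fine alpha grid around the reported value
    grid_pts <- tr$alpha * seq(0.97, 1.03, length.out = 61)
    feas <- vapply(grid_pts, function(a)
      is_feasible(m, g, NULL, a, certificate = FALSE)$feasible, TRUE)
    sup_grid <- max(grid_pts[feas])
    expect_equal(tr$alpha, sup_grid, tolerance = 2e-3)
    # monotonicity: no feasible point above an infeasible one
    expect_true(all(diff(feas) <= 0))
  }
})

test_that("alpha* is invariant under a common rescaling of all amounts", {
  m <- random_autocatalytic_model(5, 2)
  g <- tiny_grid(n_t = 4)
  a1 <- maximize_alpha(m, g, tol = 1e-6)$alpha
  m2 <- m
  m2$biomass_start_cap <- 7 * m2$biomass_start_cap
  m2$reactions$uptake$upper_bound <- 7 * m2$reactions$uptake$upper_bound
  a2 <- maximize_alpha(m2, g, tol = 1e-6)$alpha
  expect_equal(a1, a2, tolerance = 1e-4)
})

test_that("identical runs return identical growth factors", {
  m <- random_autocatalytic_model(9, 2)
  g <- tiny_grid(n_t = 4)
  a1 <- maximize_alpha(m, g, tol = 1e-6)$alpha
  a2 <- maximize_alpha(m, g, tol = 1e-6)$alpha
  expect_identical(a1, a2)
})

test_that("variability envelopes contain the representative trajectory", {
  m <- single_autocatalyst_model(kcat_per_h = 0.2)
  g <- tiny_grid(n_t = 4)
  tr <- maximize_alpha(m, g, tol = 1e-8)
  env <- variability(m, g, NULL, tr$alpha)
  expect_true(all(env$min <= env$max + 1e-6 * pmax(1, abs(env$max)),
                  na.rm = TRUE))
  expect_true(envelope_contains(env, tr, tol = 1e-5))
  # one-path network: the solution is unique, the envelope has width 0
  expect_lt(max(env$max - env$min, na.rm = TRUE), 1e-5)
})
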