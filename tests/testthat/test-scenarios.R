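test_that("binary light is on during light intervals and off at night", {
  g <- make_grid(24, 48, 12)
  L <- binary_light(g)
  expect_equal(sum(L$gamma == 1, na.rm = TRUE), 24)
  expect_equal(sum(L$photon_ub == 0), 24)
  g_dark <- make_grid(24, 8, 0)
  expect_true(all(binary_light(g_dark)$photon_ub == 0))
  g_light <- make_grid(24, 8, 24)
  expect_true(all(binary_light(g_light)$gamma == 1))
})

test_that("the bell profile peaks at midday and integrates to peak*T_L/2", {
  g <- make_grid(24, 48, 12)
  L <- bell_light(g, peak = 2)
  light <- g$phase == "light"
  mid <- which.min(abs(g$boundaries_sec[-1] - 6 * 3600))
  expect_equal(L$gamma[mid], 1 / 2, tolerance = 0.01)
  # dawn-edge interval: weak light, large gamma
  expect_gt(L$gamma[1], L$gamma[mid] * 10)
  # closed-form integral of the sin^2 curve
  T_L <- 12 * 3600
  integral <- sum(L$intensity[light]) * g$dt_sec
  expect_equal(integral, 2 * T_L / 2, tolerance = 1e-3)
  expect_error(bell_light(g, peak = 0), "positive")
})

test_that("night activity thresholds behave at the extremes", {
  m <- two_enzyme_model()
  g <- make_grid(24, 4, 12)
  tr <- maximize_alpha(m, g, tol = 1e-5)
  # all-zero dark fluxes: empty set
  tr0 <- tr
  tr0$v[g$phase == "dark", ] <- 0
  expect_length(night_activity(tr0, m), 0)
  # threshold of 1 can never be exceeded
  expect_length(night_activity(tr, m, tol = 1), 0)
  expect_error(night_activity(tr, m, tol = 1) -> x, NA)
  g_all_light <- make_grid(24, 4, 24)
  tr_l <- tr
  tr_l$grid <- g_all_light
  expect_error(night_activity(tr_l, m), "no dark intervals")
})

test_that("composition shares are a proper partition of biomass", {
  m <- single_autocatalyst_model()
  g <- tiny_grid(4)
  tr <- maximize_alpha(m, g, tol = 1e-6)
  ct <- composition_timecourse(tr, m)
  expect_true(all(abs(rowSums(ct$composition) - 1) < 1e-9))
  expect_equal(ncol(ct$composition), 1)   # single compound: share == 1
  expect_equal(ct$biomass[1], 1, tolerance = 1e-5)
})

test_that("kcat scans respond monotonically on a small network", {
  m <- two_enzyme_model()
  g <- make_grid(24, 4, 12)
  sc <- kcat_scan(m, g, NULL, "E", fold_changes = c(0.5, 1, 2),
                  tol = 1e-5)
  expect_true(all(sc$status == "ok"))
  # identity fold change reproduces the unperturbed optimum
  tr <- maximize_alpha(m, g, tol = 1e-5)
  expect_equal(sc$alpha[2], tr$alpha, tolerance = 1e-4)
  # faster catalysts never hurt growth
  expect_true(all(diff(sc$alpha) >= -1e-6))
})

test_that("scaling a catalyst's kcat rescales its inverse coefficients", {
  m <- two_enzyme_model()
  m2 <- scale_kcat(m, "E", 4)
  expect_equal(m2$capacity_constraints[[1]]$terms$inverse_kcat,
               m$capacity_constraints[[1]]$terms$inverse_kcat / 4)
  expect_error(scale_kcat(m, "nope", 2), "no capacity constraint")
})

test_that("capacity usage reports tight rows as utilization one", {
  m <- single_autocatalyst_model(kcat_per_h = 0.1)
  g <- tiny_grid(4)
  tr <- maximize_alpha(m, g, tol = 1e-8)
  cu <- capacity_usage(m, tr)
  # the only reaction runs at maximal capacity in every interval
  expect_true(all(abs(cu$utilization - 1) < 1e-3))
})
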