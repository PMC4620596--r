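test_that("time grids discretize the period as requested", {
  g <- make_grid(24, 48, 12)
  expect_equal(g$n_t, 48)
  expect_equal(g$dt_sec, 1800)
  expect_equal(sum(g$phase == "light"), 24)
  expect_equal(g$phase[24:25], c("light", "dark"))
  expect_equal(diff(g$boundaries_sec), rep(1800, 48))

  g2 <- make_grid(24, 2, 12)
  expect_equal(g2$phase, c("light", "dark"))
  g3 <- make_grid(24, 48, 0)
  expect_true(all(g3$phase == "dark"))
  # non-divisible split errors unless rounding is allowed
  expect_error(make_grid(24, 10, 11), "boundary")
  g4 <- make_grid(24, 10, 11, allow_rounding = TRUE)
  expect_equal(sum(g4$phase == "light"), 5)
})

test_that("variable count follows the block structure", {
  toy <- build_toy_model()
  g <- tiny_grid(n_t = 2)
  lp <- assemble_lp(toy, g, alpha = 1)
  n_dyn <- 2   # Y, Z
  n_rxn <- 3
  expect_equal(ncol(lp$A), n_dyn * 3 + n_rxn * 2)
  expect_setequal(unique(lp$rows$block),
                  c("steady_state", "euler", "capacity", "quota",
                    "cyclic_growth", "start_biomass"))
})

test_that("zero flux satisfies the maintenance-free LP at alpha = 1", {
  m <- two_enzyme_model()
  g <- tiny_grid(n_t = 3)
  lp <- assemble_lp(m, g, alpha = 1)
  # explicit certificate: M constant with quota-compliant composition
  x <- numeric(ncol(lp$A))
  for (k in 0:3) {
    x[lp_var_index(lp, "M", k, "E")] <- 0.6
    x[lp_var_index(lp, "M", k, "P")] <- 0.4
  }
  expect_lt(cfba:::lp_max_violation(lp, x), 1e-12)
  r <- is_feasible(m, g, NULL, 1)
  expect_true(r$feasible)
})

test_that("assembled blocks encode the conditional-FBA constraints", {
  m <- two_enzyme_model()
  g <- tiny_grid(n_t = 2)
  lp <- assemble_lp(m, g, alpha = 1.5)
  A <- as.matrix(lp$A)

  # Euler: M^1_E - M^0_E - dt * v_make_E = 0
  r <- which(lp$rows$block == "euler" & lp$rows$k == 1 & lp$rows$id == "E")
  expect_equal(A[r, lp_var_index(lp, "M", 1, "E")], 1)
  expect_equal(A[r, lp_var_index(lp, "M", 0, "E")], -1)
  expect_equal(A[r, lp_var_index(lp, "v", 1, "make_E")], -g$dt_sec)

  # capacity references the amount at the interval START (k - 1)
  r <- which(lp$rows$block == "capacity" & lp$rows$k == 2)
  expect_equal(A[r, lp_var_index(lp, "M", 1, "E")], -1)
  expect_equal(A[r, lp_var_index(lp, "M", 2, "E")], 0)
  expect_equal(A[r, lp_var_index(lp, "v", 2, "make_E")], 7200)

  # cyclic growth: M^2 >= alpha * M^0
  r <- which(lp$rows$block == "cyclic_growth" & lp$rows$id == "E")
  expect_equal(A[r, lp_var_index(lp, "M", 2, "E")], 1)
  expect_equal(A[r, lp_var_index(lp, "M", 0, "E")], -1.5)
  expect_equal(lp$dir[r], ">=")

  # start biomass equality at B0
  r <- which(lp$rows$block == "start_biomass")
  expect_equal(lp$dir[r], "=")
  expect_equal(lp$rhs[r], 1)
})

test_that("dark intervals shut photon uptake and drop light-modulated rows", {
  syn <- build_synechocystis_model()
  g <- make_grid(24, 4, 12)
  L <- binary_light(g)
  lp <- assemble_lp(syn, g, 1, L)
  iup_dark <- lp_var_index(lp, "v", 3, "Photon_Uptake")
  expect_equal(lp$ub[iup_dark], 0)
  iup_light <- lp_var_index(lp, "v", 1, "Photon_Uptake")
  expect_equal(lp$ub[iup_light], Inf)
  caps <- lp$rows[lp$rows$block == "capacity", ]
  expect_true(all(caps$k[caps$id == "Pigment"] %in% 1:2))
})

test_that("hour-based capacity coefficients are converted at assembly", {
  m <- two_enzyme_model()
  m$capacity_constraints[[1]]$terms$inverse_kcat <- c(2, 2)  # hours
  m$flux_time_unit <- "hour"
  g <- tiny_grid(n_t = 1)
  lp <- assemble_lp(m, g, 1)
  r <- which(lp$rows$block == "capacity")
  expect_equal(as.matrix(lp$A)[r, lp_var_index(lp, "v", 1, "make_E")],
               2 * 3600)
})
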