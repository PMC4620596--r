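test_that("packaged models validate cleanly", {
  toy <- build_toy_model()
  expect_length(validate_model(toy)$errors, 0)
  syn <- build_synechocystis_model()
  expect_length(validate_model(syn)$errors, 0)
})

test_that("validation flags broken models with specific errors", {
  m <- two_enzyme_model()
  # quota on a compound no reaction produces
  m_bad <- m
  m_bad$reactions$make_P <- NULL
  m_bad$quota_constraints <- list(list(members = "P", fraction = 0.4,
                                       enforce = "start_only"))
  v <- validate_model(m_bad)
  expect_true(any(grepl("unproducible quota compound", v$errors)))

  # capacity catalyst that is a balanced compound
  m_bad2 <- m
  m_bad2$capacity_constraints[[1]]$catalyst <- "S"
  v2 <- validate_model(m_bad2)
  expect_true(any(grepl("not a dynamic compound", v2$errors)))

  # negative lower bound on an irreversible reaction
  m_bad3 <- m
  m_bad3$reactions$make_E$lower_bound <- -1
  v3 <- validate_model(m_bad3)
  expect_true(any(grepl("negative lower bound", v3$errors)))

  # quota fraction outside (0,1)
  m_bad4 <- m
  m_bad4$quota_constraints[[1]]$fraction <- 1.2
  v4 <- validate_model(m_bad4)
  expect_true(any(grepl("quota fraction", v4$errors)))
})

test_that("biomass is the weighted sum of dynamic amounts", {
  expect_equal(biomass(c(0, 0), c(1, 1)), 0)
  expect_equal(biomass(c(2, 3), c(1, 1)), 5)
  expect_equal(biomass(c(4, 9), c(0.5, 0)), 2)
  expect_error(biomass(c(1, 2, 3), c(1, 1)), "conformable")
})

test_that("stoichiometric matrix partitions into balanced and dynamic blocks", {
  m <- two_enzyme_model()
  sm <- stoich_matrix(m)
  expect_equal(sm$balanced, "S")
  expect_equal(sm$dynamic, c("E", "P"))
  expect_equal(as.numeric(sm$S_B["S", ]), c(1, -1, -1))
  expect_equal(as.numeric(sm$S_A["E", ]), c(0, 1, 0))
  # light species contributes an extra balanced row
  syn <- build_synechocystis_model()
  sms <- stoich_matrix(syn)
  expect_true("photon" %in% sms$balanced)
  expect_equal(sms$S_B["photon", "PSII"], -4)
  expect_equal(sms$S_B["photon", "Photon_Uptake"], 1)
})
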