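test_that("single-reaction self-consistency gives kcat = v/M", {
  ref <- reference_state(v_ref = c(r1 = 3), M_ref = c(E1 = 6),
                         catalysis_map = list(E1 = "r1"))
  kc <- estimate_kcats(ref)
  expect_equal(kc$kcat, 0.5)
})

test_that("equal-split estimation makes the capacity row exactly tight", {
  ref <- reference_state(v_ref = c(r1 = 3, r2 = 1), M_ref = c(E = 6),
                         catalysis_map = list(E = c("r1", "r2")))
  kc <- estimate_kcats(ref)
  expect_equal(stats::setNames(kc$kcat, kc$reaction),
               c(r1 = 1.0, r2 = 1 / 3))
  # independent tightness oracle: direct substitution into the row
  expect_equal(3 / 1.0 + 1 / (1 / 3), 6)
  rep <- check_self_consistency(kc, ref, rtol = 1e-12)
  expect_true(all(rep$tight))
})

test_that("common-kcat catalysts share one efficiency with a tight summed row", {
  ref <- reference_state(v_ref = c(s1 = 2, s2 = 4), M_ref = c(Rib = 3),
                         catalysis_map = list(Rib = c("s1", "s2")))
  kc <- estimate_kcats(ref, common_kcat = "Rib")
  expect_equal(unique(kc$kcat), 2)
  expect_equal(2 / 2 + 4 / 2, 3)   # direct substitution
  expect_true(all(check_self_consistency(kc, ref, 1e-12)$tight))
})

test_that("perturbing one kcat is flagged by the consistency check", {
  ref <- reference_state(v_ref = c(r1 = 3, r2 = 5),
                         M_ref = c(E1 = 6, E2 = 2),
                         catalysis_map = list(E1 = "r1", E2 = "r2"))
  kc <- estimate_kcats(ref)
  kc$kcat[kc$catalyst == "E2"] <- 2 * kc$kcat[kc$catalyst == "E2"]
  rep <- check_self_consistency(kc, ref, rtol = 1e-9)
  expect_equal(sum(!rep$tight), 1)
  expect_equal(rep$catalyst[!rep$tight], "E2")
})

test_that("degenerate inputs error explicitly instead of yielding infinities", {
  expect_error(reference_state(c(r1 = 1), c(E = 0), list(E = "r1")),
               "non-positive reference amount")
  ref <- reference_state(c(r1 = 0), c(E = 1), list(E = "r1"))
  expect_error(estimate_kcats(ref), "zero reference flux")
})

test_that("kcats are homogeneous of the right degree in the reference", {
  ref0 <- reference_state(v_ref = c(r1 = 3, r2 = 1), M_ref = c(E = 6),
                          catalysis_map = list(E = c("r1", "r2")))
  k0 <- estimate_kcats(ref0)$kcat
  # scaling fluxes and amounts together leaves kcats unchanged
  ref1 <- reference_state(v_ref = c(r1 = 9, r2 = 3), M_ref = c(E = 18),
                          catalysis_map = list(E = c("r1", "r2")))
  expect_equal(estimate_kcats(ref1)$kcat, k0)
  # scaling amounts alone divides kcats
  ref2 <- reference_state(v_ref = c(r1 = 3, r2 = 1), M_ref = c(E = 12),
                          catalysis_map = list(E = c("r1", "r2")))
  expect_equal(estimate_kcats(ref2)$kcat, k0 / 2)
})

test_that("kcat tables round-trip through TSV and install into models", {
  ref <- reference_state(v_ref = c(make_E = 2, make_P = 1),
                         M_ref = c(E = 4),
                         catalysis_map = list(E = c("make_E", "make_P")))
  kc <- estimate_kcats(ref)
  path <- tempfile(fileext = ".tsv")
  write_kcat_tsv(kc, path)
  kc2 <- read_kcat_tsv(path)
  expect_equal(kc2$kcat, kc$kcat)
  m <- set_kcats(two_enzyme_model(), kc2)
  expect_equal(m$capacity_constraints[[1]]$terms$inverse_kcat,
               1 / kc$kcat)
})
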