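syn <- build_synechocystis_model()

test_that("the diurnal model has the published dimensions", {
  expect_length(syn$reactions, 52)
  expect_equal(nrow(syn$compounds), 50)
  expect_equal(sum(syn$compounds$kind == "dynamic"), 35)
  # 25 enzyme-synthesis reactions, one per enzyme
  es <- grep("^E_.*_S$|^E_Others_S$", names(syn$reactions), value = TRUE)
  es <- names(syn$reactions)[vapply(syn$reactions, function(r) {
    any(names(r$stoichiometry) == "AA" & r$stoichiometry["AA"] == -1) &&
      !is.na(r$stoichiometry["ATP"]) && r$stoichiometry[["ATP"]] == -104.56
  }, TRUE)]
  expect_length(es, 25)
})

test_that("key stoichiometries match the printed table field by field", {
  aa <- syn$reactions$AA_S$stoichiometry
  expect_equal(aa[["NADPH"]], -66.41)
  expect_equal(aa[["C3"]], -15.48)
  expect_equal(aa[["ATP"]], -19.89)
  expect_equal(aa[["O2"]], 0.321)
  expect_equal(aa[["CO2"]], 1.483)
  psii <- syn$reactions$PSII$stoichiometry
  expect_equal(psii[["photon"]], -4)
  expect_equal(psii[["Q"]], -2)
  expect_equal(psii[["O2"]], 1)
  atpase <- syn$reactions$ATPase$stoichiometry
  expect_equal(atpase[["Hx"]], -14)
  expect_equal(atpase[["ATP"]], 3)
  rib <- syn$reactions$Ribosome_S$stoichiometry
  expect_equal(rib[["E_Ribosome_comp"]], -0.339)
  expect_equal(rib[["RNA"]], -0.661)
  expect_true(syn$reactions$O2_Export$reversible)
})

test_that("constraint constants match the printed table", {
  fr <- vapply(syn$quota_constraints, `[[`, 0, "fraction")
  expect_setequal(fr, c(0.059, 0.12, 0.029, 0.031))
  dna <- Filter(function(q) "DNA" %in% q$members, syn$quota_constraints)
  expect_length(dna, 1)
  expect_equal(dna[[1]]$enforce, "start_only")
  expect_equal(dna[[1]]$fraction, 0.031)
  mc <- syn$maintenance_constraints
  coupling <- Filter(function(m) "ATPase" %in% names(m$flux_terms), mc)
  expect_length(coupling, 1)
  expect_equal(unname(coupling[[1]]$flux_terms[c("Maintenance", "ATPase")]),
               c(1, -0.05))
  basal <- Filter(function(m) m$biomass_coefficient > 0, mc)
  expect_equal(basal[[1]]$biomass_coefficient, 0.00641)
})

test_that("capacity coverage: every metabolic reaction has a catalyzing row", {
  # enzyme rows (pigment light harvesting is a separate, additional limit)
  enzyme_rows <- Filter(function(cc) !cc$light_modulated,
                        syn$capacity_constraints)
  cap_rxns <- unlist(lapply(enzyme_rows, function(cc) cc$terms$reaction))
  exchanges <- c("CO2_Export", "O2_Export", "Photon_Uptake", "Uptake_Carbon")
  es <- names(syn$reactions)[vapply(syn$reactions, function(r) {
    !is.na(r$stoichiometry["ATP"]) && r$stoichiometry[["ATP"]] == -104.56
  }, TRUE)]
  metabolic <- setdiff(names(syn$reactions), c(exchanges, es))
  for (rx in metabolic) {
    expect_equal(sum(cap_rxns == rx), 1, label = rx)
  }
  # enzyme-synthesis reactions are jointly limited by the ribosome pool
  rib <- Filter(function(cc) cc$catalyst == "Ribosome",
                syn$capacity_constraints)
  expect_length(rib, 1)
  expect_setequal(rib[[1]]$terms$reaction, es)
  expect_equal(unique(rib[[1]]$terms$inverse_kcat), 17.49)
})

test_that("the light-modulated capacity group covers exactly the photosystems", {
  lm <- Filter(function(cc) cc$light_modulated, syn$capacity_constraints)
  expect_length(lm, 1)
  expect_equal(lm[[1]]$catalyst, "Pigment")
  expect_setequal(lm[[1]]$terms$reaction, c("PSII", "PSI"))
  expect_equal(lm[[1]]$terms$inverse_kcat[lm[[1]]$terms$reaction == "PSII"],
               0.002549)
  expect_equal(lm[[1]]$terms$inverse_kcat[lm[[1]]$terms$reaction == "PSI"],
               0.0006371)
})

test_that("all printed capacity coefficients are present", {
  vals <- unlist(lapply(syn$capacity_constraints,
                        function(cc) cc$terms$inverse_kcat))
  printed <- c(0.002549, 0.0006371, 4.36, 0.3814, 0.001171, 12.88,
               0.008816, 0.4419, 0.00009621, 0.000001396, 2.515,
               0.0008281, 0.001658, 0.0001272, 17.49, 0.00005342,
               0.00278, 0.001041, 0.02612, 3.423, 1.084, 0.2214,
               0.002621, 3.193, 0.0222, 0.0003567)
  for (p in printed) {
    expect_true(any(abs(vals - p) < 1e-12), label = paste("coefficient", p))
  }
})
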