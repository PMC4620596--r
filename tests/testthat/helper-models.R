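# small fixtures shared across tests; everything is built in code

tiny_grid <- function(n_t = 4, T_hours = 24, light_hours = T_hours) {
  make_grid(T_hours = T_hours, n_t = n_t, light_hours = light_hours)
}

# two-compound branched network with a quota, used for probing assembly
two_enzyme_model <- function() {
  cfba_model(
    id = "two_enzyme",
    compounds = data.frame(
      id = c("S", "E", "P"),
      kind = c("balanced", "dynamic", "dynamic"),
      biomass_weight = c(0, 1, 1)),
    reactions = list(
      list(id = "uptake", stoichiometry = c(S = 1),
           upper_bound = 5 / 3600),
      list(id = "make_E", stoichiometry = c(S = -1, E = 1)),
      list(id = "make_P", stoichiometry = c(S = -1, P = 1))),
    capacity_constraints = list(
      list(catalyst = "E",
           terms = data.frame(reaction = c("make_E", "make_P"),
                              inverse_kcat = c(7200, 7200)))),
    quota_constraints = list(
      list(members = "P", fraction = 0.4, enforce = "start_only")))
}
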