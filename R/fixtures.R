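#' Single-autocatalyst model
#'
#' The smallest growing network: one dynamic compound `E` produced by one
#' reaction (`make_E`) that is catalyzed by `E` itself. With capacity
#' `v <= kcat * M_E` and the Euler update, the amounts obey the closed
#' recursion `M^k = M^{k-1} * (1 + kcat * dt)`, so the maximal cyclic
#' growth factor is exactly `(1 + kcat * dt)^{n_t}`, approaching
#' `exp(kcat * T)` as the grid is refined. Useful as an analytic oracle.
#'
#' @param kcat_per_h catalytic efficiency in 1/h.
#' @param B0 starting biomass.
#' @return a [cfba_model()].
#' @export
single_autocatalyst_model <- function(kcat_per_h = 0.1, B0 = 1) {
  cfba_model(
    compounds = data.frame(id = "E", kind = "dynamic", biomass_weight = 1),
    reactions = list(list(id = "make_E", stoichiometry = c(E = 1))),
    capacity_constraints = list(list(
      catalyst = "E",
      terms = data.frame(reaction = "make_E",
                         inverse_kcat = 3600 / kcat_per_h))),
    biomass_start_cap = B0,
    id = "single_autocatalyst")
}

#' Random autocatalytic chain model
#'
#' Deterministic (per seed) generator of validated test networks. For
#' `n_enzymes = 1` this is the [single_autocatalyst_model()]. For larger
#' `n`, a balanced substrate `X` is taken up (bounded) and converted into
#' a chain of enzymes `E_1 ... E_n` — the synthesis of `E_1` is catalyzed
#' by `E_1` (the autocatalytic root), that of `E_i` by `E_{i-1}` — plus a
#' quota compound `P` produced under capacity control of `E_n`. All kcats
#' are randomized positive values.
#'
#' @param seed integer seed (RNG state is restored on exit).
#' @param n_enzymes number of enzymes (>= 1).
#' @return a [cfba_model()].
#' @export
random_autocatalytic_model <- function(seed, n_enzymes) {
  stopifnot(n_enzymes >= 1)
  if (n_enzymes == 1) return(single_autocatalyst_model())
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  kcats <- stats::runif(n_enzymes + 1, 0.05, 0.5)   # 1/h
  enz <- paste0("E_", seq_len(n_enzymes))
  comp <- data.frame(
    id = c("X", enz, "P"),
    kind = c("balanced", rep("dynamic", n_enzymes + 1)),
    biomass_weight = c(0, rep(1, n_enzymes + 1)),
    stringsAsFactors = FALSE)
  rx <- list(list(id = "uptake", stoichiometry = c(X = 1),
                  upper_bound = stats::runif(1, 0.5, 2) / 3600))
  for (i in seq_len(n_enzymes)) {
    rx[[length(rx) + 1L]] <- list(
      id = paste0("make_E_", i),
      stoichiometry = stats::setNames(c(-1, 1), c("X", enz[i])))
  }
  rx[[length(rx) + 1L]] <- list(id = "make_P",
                                stoichiometry = c(X = -1, P = 1))
  caps <- list()
  for (i in seq_len(n_enzymes)) {
    caps[[i]] <- list(
      catalyst = enz[max(i - 1, 1)],
      terms = data.frame(reaction = paste0("make_E_", i),
                         inverse_kcat = 3600 / kcats[i]))
  }
  caps[[n_enzymes + 1L]] <- list(
    catalyst = enz[n_enzymes],
    terms = data.frame(reaction = "make_P",
                       inverse_kcat = 3600 / kcats[n_enzymes + 1]))
  # merge capacity constraints sharing a catalyst (E_1 catalyzes two)
  by_cat <- split(caps, vapply(caps, `[[`, "", "catalyst"))
  caps <- lapply(by_cat, function(g) {
    list(catalyst = g[[1]]$catalyst,
         terms = do.call(rbind, lapply(g, `[[`, "terms")))
  })
  cfba_model(
    compounds = comp, reactions = rx,
    capacity_constraints = unname(caps),
    quota_constraints = list(list(members = "P", fraction = 0.3,
                                  enforce = "start_only")),
    biomass_start_cap = 1,
    id = sprintf("random_autocatalytic_seed%d_n%d", seed, n_enzymes))
}
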