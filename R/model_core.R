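#' Construct a conditional-FBA model
#'
#' A cFBA model couples a stoichiometric network to resource-allocation
#' constraints. Compounds are partitioned into a *balanced* set (instantaneous
#' mass balance, `S_B v = 0`, like internal metabolites in conventional FBA)
#' and a *dynamic* set (amounts `M` accumulate over time via an explicit Euler
#' update). Dynamic compounds carry biomass weights `w`; biomass at a time
#' point is `b = w'M`. Capacity constraints tie every flux to the amount of
#' its catalyzing compound at the start of the interval, quota constraints
#' force minimum shares of non-catalytic biomass components, and maintenance
#' constraints enforce basal ATP expenditure.
#'
#' @param compounds data.frame with columns `id`, `kind`
#'   (`"balanced"`/`"dynamic"`), `biomass_weight`.
#' @param reactions list; each element a list with `id`, `stoichiometry`
#'   (named numeric, negative = consumed), `reversible` (logical),
#'   `lower_bound`, `upper_bound` (defaults `0`/`Inf` for irreversible,
#'   `-Inf`/`Inf` for reversible).
#' @param capacity_constraints list; each element a list with `catalyst`
#'   (a dynamic compound id), `terms` (data.frame `reaction`,
#'   `inverse_kcat` in seconds), `light_modulated` (logical; such rows are
#'   scaled by the per-interval factor `gamma` of the light profile).
#' @param quota_constraints list; each element a list with `members`
#'   (character), `fraction` in (0,1), `enforce`
#'   (`"all_timepoints"` or `"start_only"`).
#' @param maintenance_constraints list; each element a list with
#'   `flux_terms` (named numeric over reaction ids), `biomass_coefficient`
#'   (>= `biomass_coefficient * b` after moving to the right-hand side) and
#'   `biomass_per`, the time base of that coefficient (`"hour"` or
#'   `"second"`). Row sense is `sum(flux_terms * v) >= biomass_coefficient * b`.
#' @param biomass_start_cap scalar `B0`: the biomass at the first grid
#'   point is fixed to `B0` (removes the scale degeneracy of cyclic growth).
#' @param flux_time_unit time unit of the fluxes that the capacity
#'   coefficients (inverse kcats) are expressed against: `"second"`
#'   (default) or `"hour"`. Amounts are unit-free; internally all fluxes
#'   are per second and hour-based capacity coefficients are converted at
#'   assembly time.
#' @param light_species optional id of an environmental light-carrier
#'   species (e.g. `"photon"`). It may appear in stoichiometries and is
#'   balanced like a `balanced` compound, but is not part of the cellular
#'   compound list: light is an environmental input, not a cellular
#'   constituent.
#' @param id,notes optional model name and free-text notes.
#' @return an object of class `cfba_model`.
#' @seealso [validate_model()], [build_toy_model()],
#'   [build_synechocystis_model()]
#' @export
cfba_model <- function(compounds, reactions,
                       capacity_constraints = list(),
                       quota_constraints = list(),
                       maintenance_constraints = list(),
                       biomass_start_cap = 1,
                       flux_time_unit = c("second", "hour"),
                       light_species = NULL,
                       id = "cfba_model", notes = NULL) {
  flux_time_unit <- match.arg(flux_time_unit)
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind", "biomass_weight") %in% names(compounds)))
  reactions <- lapply(reactions, normalize_reaction)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  capacity_constraints <- lapply(capacity_constraints, normalize_capacity)
  quota_constraints <- lapply(quota_constraints, normalize_quota)
  maintenance_constraints <- lapply(maintenance_constraints,
                                    normalize_maintenance)
  structure(list(
    schema = "cfba-model/1",
    id = id,
    compounds = compounds,
    reactions = reactions,
    capacity_constraints = capacity_constraints,
    quota_constraints = quota_constraints,
    maintenance_constraints = maintenance_constraints,
    biomass_start_cap = as.numeric(biomass_start_cap),
    flux_time_unit = flux_time_unit,
    light_species = light_species,
    notes = notes
  ), class = "cfba_model")
}

normalize_reaction <- function(r) {
  stopifnot(!is.null(r$id), !is.null(r$stoichiometry))
  r$stoichiometry <- unlist(r$stoichiometry)
  r$reversible <- isTRUE(r$reversible)
  if (is.null(r$lower_bound)) r$lower_bound <- if (r$reversible) -Inf else 0
  if (is.null(r$upper_bound)) r$upper_bound <- Inf
  r[c("id", "stoichiometry", "reversible", "lower_bound", "upper_bound")]
}

normalize_capacity <- function(cc) {
  stopifnot(!is.null(cc$catalyst), !is.null(cc$terms))
  cc$terms <- as.data.frame(cc$terms, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction", "inverse_kcat") %in% names(cc$terms)))
  cc$light_modulated <- isTRUE(cc$light_modulated)
  cc[c("catalyst", "terms", "light_modulated")]
}

normalize_quota <- function(q) {
  stopifnot(!is.null(q$members), !is.null(q$fraction))
  q$members <- as.character(unlist(q$members))
  q$enforce <- match.arg(q$enforce %||% "all_timepoints",
                         c("all_timepoints", "start_only"))
  q[c("members", "fraction", "enforce")]
}

normalize_maintenance <- function(mc) {
  stopifnot(!is.null(mc$flux_terms))
  mc$flux_terms <- unlist(mc$flux_terms)
  mc$biomass_coefficient <- as.numeric(mc$biomass_coefficient %||% 0)
  mc$biomass_per <- match.arg(mc$biomass_per %||% "second",
                              c("second", "hour"))
  mc[c("flux_terms", "biomass_coefficient", "biomass_per")]
}

#' @exportS3Method base::print
print.cfba_model <- function(x, ...) {
  nd <- sum(x$compounds$kind == "dynamic")
  cat(sprintf(
    "<cfba_model '%s'>: %d compounds (%d dynamic), %d reactions,\n",
    x$id, nrow(x$compounds), nd, length(x$reactions)))
  cat(sprintf("  %d capacity, %d quota, %d maintenance constraints; B0 = %g\n",
              length(x$capacity_constraints), length(x$quota_constraints),
              length(x$maintenance_constraints), x$biomass_start_cap))
  invisible(x)
}

#' Compound and reaction accessors
#'
#' @param model a [cfba_model()].
#' @return character vectors of ids.
#' @export
dynamic_compounds <- function(model) {
  model$compounds$id[model$compounds$kind == "dynamic"]
}

#' @rdname dynamic_compounds
#' @export
balanced_compounds <- function(model) {
  model$compounds$id[model$compounds$kind == "balanced"]
}

#' @rdname dynamic_compounds
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Biomass weights of the dynamic compounds
#'
#' @param model a [cfba_model()].
#' @return named numeric vector over dynamic compound ids.
#' @export
biomass_weights <- function(model) {
  d <- model$compounds[model$compounds$kind == "dynamic", ]
  stats::setNames(d$biomass_weight, d$id)
}

#' Weighted biomass of an amount vector
#'
#' Biomass is the weighted sum `b = sum_j w_j M_j` over dynamic compounds.
#'
#' @param M nonnegative amount vector over dynamic compounds.
#' @param w biomass weight vector of the same length (or a [cfba_model()],
#'   from which weights are taken).
#' @return scalar biomass.
#' @export
biomass <- function(M, w) {
  if (inherits(w, "cfba_model")) w <- biomass_weights(w)
  if (length(M) != length(w)) {
    stop("amount vector and weight vector are not conformable (",
         length(M), " vs ", length(w), ")")
  }
  sum(as.numeric(M) * as.numeric(w))
}

#' Stoichiometric matrices of a model
#'
#' Builds the full stoichiometric matrix and its partition into the
#' balanced-row block `S_B` and the dynamic-row block `S_A`. A declared
#' light species contributes an extra balanced row.
#'
#' @param model a [cfba_model()].
#' @return list with sparse matrices `S_B`, `S_A` and the id vectors
#'   `balanced` (incl. the light species, if any), `dynamic`, `reactions`.
#' @export
stoich_matrix <- function(model) {
  bal <- balanced_compounds(model)
  if (!is.null(model$light_species)) bal <- c(bal, model$light_species)
  dyn <- dynamic_compounds(model)
  rxn <- reaction_ids(model)
  all_ids <- c(bal, dyn)
  idx <- stats::setNames(seq_along(all_ids), all_ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    known <- names(st) %in% all_ids
    ii <- c(ii, idx[names(st)[known]])
    jj <- c(jj, rep.int(j, sum(known)))
    xx <- c(xx, st[known])
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(all_ids), length(rxn)),
                            dimnames = list(all_ids, rxn))
  list(S_B = S[seq_along(bal), , drop = FALSE],
       S_A = S[length(bal) + seq_along(dyn), , drop = FALSE],
       balanced = bal, dynamic = dyn, reactions = rxn)
}

#' Validate a cFBA model
#'
#' Checks the structural invariants: unique ids, resolvable references,
#' balanced compounds carrying zero biomass weight, positive inverse kcats,
#' capacity catalysts being dynamic compounds, quota members being dynamic
#' weight-positive compounds, quota fractions in (0,1), irreversible
#' reactions with nonnegative lower bounds, and producibility of quota
#' compounds. Warnings flag dynamic compounds that no reaction produces or
#' consumes.
#'
#' @param model a [cfba_model()].
#' @return object of class `cfba_validation`: list with character vectors
#'   `errors` and `warnings`.
#' @export
validate_model <- function(model) {
  errors <- character(0)
  warnings <- character(0)
  cps <- model$compounds
  if (anyDuplicated(cps$id)) {
    errors <- c(errors, "duplicate compound ids")
  }
  if (anyDuplicated(names(model$reactions))) {
    errors <- c(errors, "duplicate reaction ids")
  }
  if (!all(cps$kind %in% c("balanced", "dynamic"))) {
    errors <- c(errors, "compound kind must be 'balanced' or 'dynamic'")
  }
  bad_w <- cps$kind == "balanced" & cps$biomass_weight != 0
  if (any(bad_w)) {
    errors <- c(errors, paste0("balanced compound with nonzero biomass ",
                               "weight: ", paste(cps$id[bad_w], collapse = ", ")))
  }
  if (any(cps$biomass_weight < 0)) {
    errors <- c(errors, "negative biomass weight")
  }
  known <- c(cps$id, model$light_species)
  for (r in model$reactions) {
    miss <- setdiff(names(r$stoichiometry), known)
    if (length(miss)) {
      errors <- c(errors, paste0("reaction ", r$id,
                                 " references unknown compound(s): ",
                                 paste(miss, collapse = ", ")))
    }
    if (length(r$stoichiometry) == 0) {
      errors <- c(errors, paste0("reaction ", r$id, " has empty stoichiometry"))
    }
    if (!r$reversible && r$lower_bound < 0) {
      errors <- c(errors, paste0("irreversible reaction ", r$id,
                                 " has negative lower bound"))
    }
  }
  dyn <- dynamic_compounds(model)
  rids <- reaction_ids(model)
  for (cc in model$capacity_constraints) {
    if (!(cc$catalyst %in% dyn)) {
      errors <- c(errors, paste0("capacity catalyst '", cc$catalyst,
                                 "' is not a dynamic compound"))
    }
    if (any(!(cc$terms$reaction %in% rids))) {
      errors <- c(errors, paste0("capacity constraint of '", cc$catalyst,
                                 "' names unknown reaction(s)"))
    }
    if (any(cc$terms$inverse_kcat <= 0)) {
      errors <- c(errors, paste0("non-positive inverse kcat for catalyst '",
                                 cc$catalyst, "'"))
    }
    if (anyDuplicated(cc$terms$reaction)) {
      errors <- c(errors, paste0("reaction appears twice in capacity ",
                                 "constraint of '", cc$catalyst, "'"))
    }
  }
  w <- biomass_weights(model)
  producers <- compound_flux_sign(model, dyn, +1)
  consumers <- compound_flux_sign(model, dyn, -1)
  for (q in model$quota_constraints) {
    miss <- setdiff(q$members, dyn)
    if (length(miss)) {
      errors <- c(errors, paste0("quota member(s) not dynamic compounds: ",
                                 paste(miss, collapse = ", ")))
    }
    ok <- intersect(q$members, dyn)
    zero_w <- ok[w[ok] <= 0]
    if (length(zero_w)) {
      errors <- c(errors, paste0("quota member(s) with non-positive biomass ",
                                 "weight: ", paste(zero_w, collapse = ", ")))
    }
    if (!(q$fraction > 0 && q$fraction < 1)) {
      errors <- c(errors, "quota fraction must lie in (0,1)")
    }
    unprod <- ok[!producers[ok]]
    if (length(unprod) && q$fraction > 0) {
      errors <- c(errors, paste0("unproducible quota compound: ",
                                 paste(unprod, collapse = ", ")))
    }
  }
  for (mc in model$maintenance_constraints) {
    if (all(mc$flux_terms == 0) && mc$biomass_coefficient == 0) {
      errors <- c(errors, "maintenance constraint with no nonzero term")
    }
    miss <- setdiff(names(mc$flux_terms), rids)
    if (length(miss)) {
      errors <- c(errors, paste0("maintenance names unknown reaction(s): ",
                                 paste(miss, collapse = ", ")))
    }
  }
  if (!(model$biomass_start_cap > 0)) {
    errors <- c(errors, "biomass_start_cap must be positive")
  }
  idle <- dyn[!producers[dyn] & !consumers[dyn]]
  if (length(idle)) {
    warnings <- c(warnings, paste0("dynamic compound never produced or ",
                                   "consumed: ", paste(idle, collapse = ", ")))
  }
  structure(list(errors = errors, warnings = warnings),
            class = "cfba_validation")
}

compound_flux_sign <- function(model, ids, sign) {
  hit <- stats::setNames(rep(FALSE, length(ids)), ids)
  for (r in model$reactions) {
    st <- r$stoichiometry
    sel <- names(st) %in% ids & (sign * st > 0 | (r$reversible & st != 0))
    hit[names(st)[sel]] <- TRUE
  }
  hit
}

#' @exportS3Method base::print
print.cfba_validation <- function(x, ...) {
  cat(sprintf("<cfba_validation>: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
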