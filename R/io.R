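MODEL_SCHEMA <- "cfba-model/1"

model_fields <- c("schema", "id", "description", "flux_time_unit",
                  "biomass_start_cap", "light_species", "compounds",
                  "reactions", "capacity_constraints", "quota_constraints",
                  "maintenance_constraints", "notes")

#' Save a cFBA model to the package JSON format
#'
#' The on-disk format is a versioned JSON document (schema id
#' `cfba-model/1`). Infinite bounds are omitted; all times are seconds
#' except where a field carries an explicit `per` unit.
#'
#' @param model a [cfba_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  rx <- lapply(unname(model$reactions), function(r) {
    out <- list(id = r$id,
                stoichiometry = as.list(r$stoichiometry),
                reversible = r$reversible)
    if (is.finite(r$lower_bound) &&
        !(r$lower_bound == 0 && !r$reversible)) {
      out$lower_bound <- r$lower_bound
    }
    if (is.finite(r$upper_bound)) out$upper_bound <- r$upper_bound
    out
  })
  caps <- lapply(model$capacity_constraints, function(cc) {
    list(catalyst = cc$catalyst,
         light_modulated = cc$light_modulated,
         terms = unname(Map(function(r, k) list(reaction = r,
                                                inverse_kcat = k),
                            cc$terms$reaction, cc$terms$inverse_kcat)))
  })
  quotas <- lapply(model$quota_constraints, function(q) {
    list(members = q$members, fraction = q$fraction, enforce = q$enforce)
  })
  maints <- lapply(model$maintenance_constraints, function(mc) {
    list(flux_terms = as.list(mc$flux_terms),
         biomass_coefficient = mc$biomass_coefficient,
         biomass_per = mc$biomass_per)
  })
  doc <- list(schema = MODEL_SCHEMA, id = model$id,
              flux_time_unit = model$flux_time_unit %||% "second",
              biomass_start_cap = model$biomass_start_cap,
              compounds = model$compounds,
              reactions = rx,
              capacity_constraints = caps,
              quota_constraints = quotas,
              maintenance_constraints = maints)
  if (!is.null(model$light_species)) doc$light_species <- model$light_species
  if (!is.null(model$notes)) doc$notes <- model$notes
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a cFBA model from the package JSON format
#'
#' Rejects unknown schema versions and unknown fields with field-level
#' messages; `save_model()` followed by `load_model()` is the identity on
#' all packaged models.
#'
#' @param path path to a `cfba-model/1` JSON file, or one of the builtin
#'   names `"builtin:toy"`, `"builtin:synechocystis"`.
#' @return a [cfba_model()].
#' @export
load_model <- function(path) {
  if (grepl("^builtin:", path)) {
    name <- sub("^builtin:", "", path)
    path <- system.file("extdata", "models", paste0(name, ".json"),
                        package = "cfba")
    if (path == "") stop("unknown builtin model: ", name)
  }
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse model file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(doc$schema) || !identical(doc$schema, MODEL_SCHEMA)) {
    stop("unsupported model schema version: ",
         doc$schema %||% "<missing>", " (expected ", MODEL_SCHEMA, ")")
  }
  unknown <- setdiff(names(doc), model_fields)
  if (length(unknown)) {
    stop("unknown field(s) in model file: ", paste(unknown, collapse = ", "))
  }
  comp <- do.call(rbind, lapply(doc$compounds, function(cp) {
    check_fields(cp, c("id", "kind", "biomass_weight"), "compound")
    data.frame(id = cp$id, kind = cp$kind,
               biomass_weight = cp$biomass_weight %||% 0,
               stringsAsFactors = FALSE)
  }))
  rx <- lapply(doc$reactions, function(r) {
    check_fields(r, c("id", "stoichiometry", "reversible",
                      "lower_bound", "upper_bound"), "reaction")
    list(id = r$id, stoichiometry = unlist(r$stoichiometry),
         reversible = isTRUE(r$reversible),
         lower_bound = r$lower_bound %||% NULL,
         upper_bound = r$upper_bound %||% NULL)
  })
  caps <- lapply(doc$capacity_constraints, function(cc) {
    check_fields(cc, c("catalyst", "light_modulated", "terms"),
                 "capacity constraint")
    list(catalyst = cc$catalyst,
         light_modulated = isTRUE(cc$light_modulated),
         terms = data.frame(
           reaction = vapply(cc$terms, `[[`, "", "reaction"),
           inverse_kcat = vapply(cc$terms, `[[`, 0, "inverse_kcat"),
           stringsAsFactors = FALSE))
  })
  quotas <- lapply(doc$quota_constraints, function(q) {
    check_fields(q, c("members", "fraction", "enforce"), "quota constraint")
    list(members = unlist(q$members), fraction = q$fraction,
         enforce = q$enforce)
  })
  maints <- lapply(doc$maintenance_constraints, function(mc) {
    check_fields(mc, c("flux_terms", "biomass_coefficient", "biomass_per"),
                 "maintenance constraint")
    list(flux_terms = unlist(mc$flux_terms),
         biomass_coefficient = mc$biomass_coefficient,
         biomass_per = mc$biomass_per)
  })
  cfba_model(compounds = comp, reactions = rx,
             capacity_constraints = caps, quota_constraints = quotas,
             maintenance_constraints = maints,
             biomass_start_cap = doc$biomass_start_cap %||% 1,
             flux_time_unit = doc$flux_time_unit %||% "second",
             light_species = doc$light_species,
             id = doc$id %||% "model", notes = unlist(doc$notes))
}

check_fields <- function(x, allowed, what) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown field(s) in ", what,
         if (!is.null(x$id)) paste0(" '", x$id, "'"), ": ",
         paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' Packaged models
#'
#' `build_toy_model()` loads the three-reaction illustrative network:
#' a substrate X (balanced) is taken up (v1, bounded) and converted either
#' into the enzyme Y (v2) or the target compound Z (v3); both conversions
#' are catalyzed by Y, and Z must make up at least half of the biomass at
#' the start of the cycle. Its unprinted parameters (kcats, uptake bound,
#' B0) are package defaults documented in the model file.
#'
#' `build_synechocystis_model()` loads the minimal diurnal model of
#' *Synechocystis* sp. PCC 6803: 52 reactions, 50 compounds, photosynthetic
#' light reactions, Calvin-Benson carbon fixation, glycogen storage, TCA
#' cycle and respiration, lumped biosynthesis of all major biomass
#' components, 25 enzyme-synthesis reactions limited by a common ribosome
#' pool, pigment-limited photosystems, biomass quotas and maintenance.
#' Light enters through the environmental species `photon`, which is
#' balanced but not part of the cellular compound list.
#'
#' @return a validated [cfba_model()].
#' @export
build_toy_model <- function() load_model("builtin:toy")

#' @rdname build_toy_model
#' @export
build_synechocystis_model <- function() load_model("builtin:synechocystis")

#' Write a trajectory as tidy TSV
#'
#' Long format: one row per variable per interval/grid point, columns
#' `variable`, `kind` (`flux` or `amount`), `t_start_h`, `t_end_h`,
#' `value`. The achieved growth factor is written as a `# alpha` header
#' line.
#'
#' @param traj a `cfba_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  hrs <- traj$grid$boundaries_sec / 3600
  nt <- traj$grid$n_t
  rows <- rbind(
    data.frame(variable = rep(colnames(traj$v), each = nt),
               kind = "flux",
               t_start_h = rep(hrs[1:nt], ncol(traj$v)),
               t_end_h = rep(hrs[2:(nt + 1)], ncol(traj$v)),
               value = as.numeric(traj$v)),
    data.frame(variable = rep(colnames(traj$M), each = nt + 1),
               kind = "amount",
               t_start_h = rep(hrs, ncol(traj$M)),
               t_end_h = rep(hrs, ncol(traj$M)),
               value = as.numeric(traj$M)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha\t%.12g", traj$alpha), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @param env a `cfba_envelope` from [variability()].
#' @export
write_envelope_tsv <- function(env, path) {
  utils::write.table(as.data.frame(env), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
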