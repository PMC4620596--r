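#' Binary (on/off) light profile
#'
#' During the light phase, light harvesting is limited only by the amount
#' of pigments (`gamma = 1` on light-modulated capacity rows); in dark
#' intervals all photon-producing uptake is shut off.
#'
#' @param grid a [make_grid()] grid with phase labels.
#' @return object of class `cfba_light`: list with per-interval `gamma`
#'   (multiplier on the inverse kcats of light-modulated rows; `NA` in the
#'   dark) and `photon_ub` (upper bound on light-species uptake; 0 in the
#'   dark).
#' @export
binary_light <- function(grid) {
  light <- grid$phase == "light"
  structure(list(gamma = ifelse(light, 1, NA_real_),
                 photon_ub = ifelse(light, Inf, 0),
                 mode = "binary"),
            class = "cfba_light")
}

#' Bell-shaped light profile
#'
#' Natural sunlight intensity is approximately bell-shaped. The profile
#' used here is `I(t) = peak * sin^2(pi * (t - t_dawn) / T_L)` across the
#' light phase and 0 in the dark (the functional form is a package choice;
#' its integral over the light phase is `peak * T_L / 2`). Light-modulated
#' capacity rows are scaled by `gamma_k = 1 / I(midpoint of interval k)`:
#' light absorption is proportional to the pigment amount multiplied by
#' the momentary light intensity. Intervals with (numerically) zero
#' intensity are treated as dark.
#'
#' @param grid a [make_grid()] grid.
#' @param peak peak (midday) intensity relative to the binary-light level
#'   (`peak = 1` makes midday identical to binary light).
#' @return a `cfba_light` profile.
#' @export
bell_light <- function(grid, peak = 1) {
  if (peak <= 0) stop("peak must be positive")
  light <- grid$phase == "light"
  T_L <- sum(light) * grid$dt_sec
  mid <- (grid$boundaries_sec[-length(grid$boundaries_sec)] +
            grid$boundaries_sec[-1]) / 2
  I <- ifelse(light, peak * sin(pi * mid / T_L)^2, 0)
  dark_like <- I <= peak * 1e-12
  structure(list(gamma = ifelse(dark_like, NA_real_, 1 / I),
                 photon_ub = ifelse(dark_like, 0, Inf),
                 intensity = I, mode = "bell", peak = peak),
            class = "cfba_light")
}

#' Scale the catalytic efficiency of one catalyst
#'
#' Multiplies every kcat of the given catalyst by `fold` (i.e. divides the
#' inverse-kcat coefficients of its capacity constraint by `fold`).
#'
#' @param model a [cfba_model()].
#' @param catalyst_id catalyst compound id.
#' @param fold positive fold change.
#' @return the modified model.
#' @export
scale_kcat <- function(model, catalyst_id, fold) {
  stopifnot(fold > 0)
  hit <- FALSE
  for (i in seq_along(model$capacity_constraints)) {
    if (model$capacity_constraints[[i]]$catalyst == catalyst_id) {
      model$capacity_constraints[[i]]$terms$inverse_kcat <-
        model$capacity_constraints[[i]]$terms$inverse_kcat / fold
      hit <- TRUE
    }
  }
  if (!hit) stop("no capacity constraint with catalyst '", catalyst_id, "'")
  model
}

#' Robustness scan over the catalytic efficiency of one catalyst
#'
#' For each fold change `f`, all kcats of the catalyst are multiplied by
#' `f`, the maximal growth factor is recomputed, and the end-of-period
#' composition and the set of synthesis reactions active in darkness are
#' recorded. Growth infeasibility at extreme fold changes is recorded as a
#' status, not raised.
#'
#' @inheritParams maximize_alpha
#' @param catalyst_id catalyst compound id to perturb.
#' @param fold_changes positive numeric vector (sorted internally).
#' @param night_tol tolerance passed to [night_activity()].
#' @return object of class `cfba_scan`: list with `catalyst_id`,
#'   `fold_changes`, `alpha` (vector, `NA` where infeasible), `status`,
#'   `composition` (matrix: fold changes x weight-positive compounds,
#'   end-of-period relative composition), `night_active` (list of
#'   character vectors).
#' @export
kcat_scan <- function(model, grid, light = NULL, catalyst_id,
                      fold_changes, tol = 1e-5, feastol = 1e-7,
                      night_tol = 1e-6, options = list()) {
  stopifnot(all(fold_changes > 0))
  fold_changes <- sort(fold_changes)
  w <- biomass_weights(model)
  wpos <- names(w)[w > 0]
  alpha <- rep(NA_real_, length(fold_changes))
  status <- character(length(fold_changes))
  comp <- matrix(NA_real_, length(fold_changes), length(wpos),
                 dimnames = list(NULL, wpos))
  night <- vector("list", length(fold_changes))
  for (i in seq_along(fold_changes)) {
    m2 <- scale_kcat(model, catalyst_id, fold_changes[i])
    traj <- tryCatch(
      maximize_alpha(m2, grid, light, tol = tol, feastol = feastol,
                     options = options),
      error = function(e) e)
    if (inherits(traj, "error")) {
      status[i] <- conditionMessage(traj)
      next
    }
    alpha[i] <- traj$alpha
    status[i] <- "ok"
    Mend <- traj$M[nrow(traj$M), wpos]
    b <- sum(w[wpos] * Mend)
    comp[i, ] <- if (b > 0) w[wpos] * Mend / b else NA_real_
    night[[i]] <- night_activity(traj, model, tol = night_tol)
  }
  structure(list(catalyst_id = catalyst_id, fold_changes = fold_changes,
                 alpha = alpha, status = status, composition = comp,
                 night_active = night),
            class = "cfba_scan")
}

#' Synthesis reactions active in the dark phase
#'
#' A synthesis reaction (one producing a dynamic compound) is
#' night-active when its integrated dark-phase flux exceeds
#' `tol` times its integrated full-period flux.
#'
#' @param traj a `cfba_trajectory` whose grid has dark intervals.
#' @param model the model the trajectory was computed from (used to
#'   identify synthesis reactions).
#' @param tol relative activity threshold (default `1e-6`).
#' @return character vector of reaction ids.
#' @export
night_activity <- function(traj, model, tol = 1e-6) {
  dark <- traj$grid$phase == "dark"
  if (!any(dark)) stop("trajectory grid has no dark intervals")
  dyn <- dynamic_compounds(model)
  synth <- vapply(model$reactions, function(r) {
    any(names(r$stoichiometry) %in% dyn & r$stoichiometry > 0)
  }, TRUE)
  ids <- reaction_ids(model)[synth]
  dt <- traj$grid$dt_sec
  tot <- colSums(abs(traj$v[, ids, drop = FALSE])) * dt
  drk <- colSums(abs(traj$v[dark, ids, drop = FALSE])) * dt
  ids[tot > 0 & drk > tol * tot]
}

#' Relative biomass composition along a trajectory
#'
#' @param traj a `cfba_trajectory`.
#' @param w biomass weight vector over the trajectory's compounds, or a
#'   [cfba_model()].
#' @return list with `composition` (matrix `(n_t+1) x n_weighted`, rows
#'   summing to 1) and `biomass` (vector of `b^k = w'M^k`).
#' @export
composition_timecourse <- function(traj, w) {
  if (inherits(w, "cfba_model")) w <- biomass_weights(w)
  w <- w[colnames(traj$M)]
  b <- as.numeric(traj$M %*% w)
  wpos <- names(w)[w > 0]
  shares <- sweep(traj$M[, wpos, drop = FALSE] *
                    rep(w[wpos], each = nrow(traj$M)), 1, b, "/")
  list(composition = shares, biomass = b)
}

#' Capacity utilization along a trajectory
#'
#' For every capacity constraint and interval, the ratio of the
#' constrained flux combination to its bound (catalyst amount at the
#' interval start, times the light factor where applicable). A ratio of 1
#' means the constraint is tight (the catalyst works at maximal capacity).
#'
#' @param model a [cfba_model()].
#' @param traj a `cfba_trajectory`.
#' @param light the light profile used for the run (or `NULL`).
#' @return data.frame with columns `catalyst`, `k`, `phase`, `lhs`,
#'   `bound`, `utilization` (`NA` where the row is inactive, e.g.
#'   light-modulated rows in the dark).
#' @export
capacity_usage <- function(model, traj, light = NULL) {
  nt <- traj$grid$n_t
  dark <- traj$grid$phase == "dark"
  if (is.null(light)) light <- list(gamma = rep(1, nt))
  invk_scale <- if (identical(model$flux_time_unit, "hour")) 3600 else 1
  out <- list()
  for (cc in model$capacity_constraints) {
    for (k in seq_len(nt)) {
      g <- if (cc$light_modulated) light$gamma[k] else 1
      active <- !(cc$light_modulated && (dark[k] || !is.finite(g)))
      lhs <- if (active) {
        sum(cc$terms$inverse_kcat * invk_scale * g *
              traj$v[k, cc$terms$reaction])
      } else NA_real_
      bound <- traj$M[k, cc$catalyst]
      out[[length(out) + 1L]] <- data.frame(
        catalyst = cc$catalyst, k = k, phase = traj$grid$phase[k],
        lhs = lhs, bound = bound,
        utilization = if (active && bound > 0) lhs / bound else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
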