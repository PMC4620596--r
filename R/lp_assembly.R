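#' Discretize a diurnal period into a uniform time grid
#'
#' The period `T` is split into `n_t` uniform intervals; the first
#' `n_t * light_hours / T` intervals are labelled `"light"`, the rest
#' `"dark"`. The grid starts at dawn. Internally all times are seconds;
#' the user-facing arguments are hours.
#'
#' @param T_hours total period length in hours (default 24).
#' @param n_t number of intervals (default 48).
#' @param light_hours length of the light phase in hours (default 12).
#' @param allow_rounding if the light/dark split does not fall on an
#'   interval boundary, error unless this is `TRUE` (then the boundary is
#'   rounded up to the next interval).
#' @return object of class `cfba_grid`: list with `T_sec`, `n_t`, `dt_sec`,
#'   `boundaries_sec` (length `n_t + 1`), `phase` (character, per interval),
#'   `T_hours`, `light_hours`.
#' @export
make_grid <- function(T_hours = 24, n_t = 48, light_hours = 12,
                      allow_rounding = FALSE) {
  stopifnot(n_t >= 1, T_hours > 0, light_hours >= 0, light_hours <= T_hours)
  n_light_exact <- n_t * light_hours / T_hours
  n_light <- ceiling(n_light_exact - 1e-9)
  if (abs(n_light_exact - round(n_light_exact)) > 1e-9 && !allow_rounding) {
    stop("light/dark split does not fall on an interval boundary; ",
         "set allow_rounding = TRUE to round up")
  }
  T_sec <- T_hours * 3600
  dt <- T_sec / n_t
  phase <- rep("dark", n_t)
  if (n_light > 0) phase[seq_len(n_light)] <- "light"
  structure(list(T_sec = T_sec, n_t = n_t, dt_sec = dt,
                 boundaries_sec = seq(0, T_sec, length.out = n_t + 1),
                 phase = phase, T_hours = T_hours,
                 light_hours = light_hours),
            class = "cfba_grid")
}

#' @exportS3Method base::print
print.cfba_grid <- function(x, ...) {
  cat(sprintf("<cfba_grid>: T = %g h, %d intervals of %g h (%d light, %d dark)\n",
              x$T_hours, x$n_t, x$dt_sec / 3600,
              sum(x$phase == "light"), sum(x$phase == "dark")))
  invisible(x)
}

#' Assemble the global linear program for a fixed growth factor
#'
#' Builds the block-structured LP whose feasibility decides whether the
#' model can multiply its compound-amount vector by `alpha` over one
#' period. Variables are the amount vectors `M^0 ... M^{n_t}` (dynamic
#' compounds) followed by the flux vectors `v^1 ... v^{n_t}`. Constraint
#' blocks:
#'
#' * `steady_state`: `S_B v^k = 0` for every interval (balanced compounds,
#'   including a declared light species).
#' * `euler`: `M^k = M^{k-1} + dt * S_A v^k` (explicit Euler update).
#' * `capacity`: for every capacity constraint with catalyst `j`:
#'   `sum_i inverse_kcat[i] * gamma_k * v_i^k <= M_j^{k-1}` — capacities in
#'   an interval depend on the amounts at the interval's *start*.
#'   Light-modulated rows are dropped in dark intervals (their fluxes are
#'   forced to zero through the light-species balance and the photon
#'   uptake bound).
#' * `quota`: `sum_{j in members} M_j^k >= fraction * w'M^k` at every grid
#'   point (or only at `k = 0` for start-only quotas).
#' * `maintenance`: `sum_i a_i v_i^k >= bc * w'M^{k-1}` per interval.
#' * `cyclic_growth`: `M^{n_t} >= alpha * M^0` componentwise (equality with
#'   `options$cyclic = "equality"`).
#' * `start_biomass`: `w'M^0 = B0` (set `options$start_biomass = "cap"` for
#'   the inequality form `<= B0`).
#'
#' In dark intervals every reaction producing the light species has its
#' upper bound set to zero.
#'
#' @param model a validated [cfba_model()].
#' @param grid a [make_grid()] time grid.
#' @param alpha cyclic growth factor (> 0).
#' @param light a light profile from [binary_light()] or [bell_light()],
#'   or `NULL` for a model without light modulation.
#' @param options list: `cyclic` (`"inequality"` default or `"equality"`),
#'   `start_biomass` (`"equality"` default or `"cap"`).
#' @return object of class `cfba_lp`: the constraint system plus variable
#'   and row metadata (`vars`, `rows` data.frames) for indexing.
#' @export
assemble_lp <- function(model, grid, alpha, light = NULL, options = list()) {
  if (!inherits(model, "cfba_model")) stop("model must be a cfba_model")
  if (alpha <= 0) stop("alpha must be positive")
  val <- validate_model(model)
  if (length(val$errors)) {
    stop("model fails validation: ", paste(val$errors, collapse = "; "))
  }
  cyclic_mode <- options$cyclic %||% "inequality"
  start_mode <- options$start_biomass %||% "equality"

  sm <- stoich_matrix(model)
  dyn <- sm$dynamic
  bal <- sm$balanced
  rxn <- sm$reactions
  nd <- length(dyn); nb <- length(bal); nr <- length(rxn)
  nt <- grid$n_t
  dt <- grid$dt_sec
  w <- biomass_weights(model)[dyn]

  if (is.null(light)) {
    light <- list(gamma = rep(1, nt), photon_ub = rep(Inf, nt))
  }
  is_dark <- grid$phase == "dark"

  n_M <- (nt + 1) * nd
  n_v <- nt * nr
  Mi <- function(k, j) k * nd + j          # k = 0..nt, j = 1..nd
  Vi <- function(k, i) n_M + (k - 1) * nr + i  # k = 1..nt, i = 1..nr

  TB <- Matrix::mat2triplet(sm$S_B)
  TA <- Matrix::mat2triplet(sm$S_A)

  ii <- vector("list", 16); jj <- ii; xx <- ii
  dir <- vector("list", 16); rhs <- ii; rblock <- ii; rk <- ii; rid <- ii
  nblk <- 0L
  rowoff <- 0L
  add_block <- function(i, j, x, d, r, block, k_lab, id_lab) {
    nblk <<- nblk + 1L
    ii[[nblk]] <<- i + rowoff
    jj[[nblk]] <<- j
    xx[[nblk]] <<- x
    dir[[nblk]] <<- d
    rhs[[nblk]] <<- r
    rblock[[nblk]] <<- rep_len(block, length(r))
    rk[[nblk]] <<- k_lab
    rid[[nblk]] <<- id_lab
    rowoff <<- rowoff + length(r)
  }

  # steady state: per interval, rows over balanced compounds
  if (nb > 0 && length(TB$i)) {
    nn <- length(TB$i)
    k_rep <- rep(seq_len(nt), each = nn)
    add_block(i = rep(TB$i, nt) + (k_rep - 1L) * nb,
              j = Vi(k_rep, rep(TB$j, nt)),
              x = rep(TB$x, nt),
              d = rep("=", nt * nb), r = numeric(nt * nb),
              block = "steady_state",
              k_lab = rep(seq_len(nt), each = nb),
              id_lab = rep(bal, nt))
  } else if (nb > 0) {
    add_block(integer(0), integer(0), numeric(0),
              rep("=", nt * nb), numeric(nt * nb), "steady_state",
              rep(seq_len(nt), each = nb), rep(bal, nt))
  }

  # Euler update rows: M^k_j - M^{k-1}_j - dt * (S_A v^k)_j = 0
  nnA <- length(TA$i)
  k_rep <- rep(seq_len(nt), each = nnA)
  j_rep <- rep(seq_len(nt), each = nd)
  add_block(
    i = c(rep(seq_len(nd), nt) + (j_rep - 1L) * nd,        # M^k
          rep(seq_len(nd), nt) + (j_rep - 1L) * nd,        # M^{k-1}
          rep(TA$i, nt) + (k_rep - 1L) * nd),              # fluxes
    j = c(Mi(j_rep, rep(seq_len(nd), nt)),
          Mi(j_rep - 1L, rep(seq_len(nd), nt)),
          Vi(k_rep, rep(TA$j, nt))),
    x = c(rep(1, nt * nd), rep(-1, nt * nd), rep(-dt * TA$x, nt)),
    d = rep("=", nt * nd), r = numeric(nt * nd),
    block = "euler", k_lab = j_rep, id_lab = rep(dyn, nt))

  # capacity rows; hour-based coefficients are converted to the internal
  # per-second fluxes (inverse kcats scale with the flux unit)
  invk_scale <- if (identical(model$flux_time_unit, "hour")) 3600 else 1
  dyn_idx <- stats::setNames(seq_along(dyn), dyn)
  rxn_idx <- stats::setNames(seq_along(rxn), rxn)
  for (ci in seq_along(model$capacity_constraints)) {
    cc <- model$capacity_constraints[[ci]]
    term_i <- rxn_idx[cc$terms$reaction]
    invk <- cc$terms$inverse_kcat * invk_scale
    cat_j <- dyn_idx[[cc$catalyst]]
    for (k in seq_len(nt)) {
      if (cc$light_modulated && is_dark[k]) next
      g <- if (cc$light_modulated) light$gamma[k] else 1
      if (!is.finite(g)) next
      add_block(i = rep(1L, length(term_i) + 1L),
                j = c(Vi(k, term_i), Mi(k - 1L, cat_j)),
                x = c(invk * g, -1),
                d = "<=", r = 0,
                block = "capacity", k_lab = k, id_lab = cc$catalyst)
    }
  }

  # quota rows: sum_members M^k - f * w'M^k >= 0
  wnz <- which(w != 0)
  for (qi in seq_along(model$quota_constraints)) {
    q <- model$quota_constraints[[qi]]
    ks <- if (q$enforce == "start_only") 0L else 0L:nt
    mem <- dyn_idx[q$members]
    for (k in ks) {
      cvec <- -q$fraction * w[wnz]
      names(cvec) <- NULL
      jcols <- Mi(k, wnz)
      # members add +1 on top of the -f*w coefficient
      mm <- match(mem, wnz)
      cvec[mm[!is.na(mm)]] <- cvec[mm[!is.na(mm)]] + 1
      extra <- mem[is.na(mm)]      # members with zero weight (not expected)
      add_block(i = rep(1L, length(jcols) + length(extra)),
                j = c(jcols, Mi(k, extra)),
                x = c(cvec, rep(1, length(extra))),
                d = ">=", r = 0,
                block = "quota", k_lab = k,
                id_lab = paste(q$members, collapse = "+"))
    }
  }

  # maintenance rows: sum a_i v^k_i - bc * w'M^{k-1} >= 0
  for (mi in seq_along(model$maintenance_constraints)) {
    mc <- model$maintenance_constraints[[mi]]
    bc <- mc$biomass_coefficient /
      (if (mc$biomass_per == "hour") 3600 else 1)
    term_i <- rxn_idx[names(mc$flux_terms)]
    for (k in seq_len(nt)) {
      jcols <- Vi(k, term_i)
      xvals <- as.numeric(mc$flux_terms)
      if (bc != 0) {
        jcols <- c(jcols, Mi(k - 1L, wnz))
        xvals <- c(xvals, -bc * w[wnz])
      }
      add_block(i = rep(1L, length(jcols)), j = jcols, x = xvals,
                d = ">=", r = 0,
                block = "maintenance", k_lab = k, id_lab = paste0("m", mi))
    }
  }

  # cyclic growth: M^{nt}_j - alpha * M^0_j >= 0 (or =)
  add_block(i = rep(seq_len(nd), 2L),
            j = c(Mi(nt, seq_len(nd)), Mi(0L, seq_len(nd))),
            x = c(rep(1, nd), rep(-alpha, nd)),
            d = rep(if (cyclic_mode == "equality") "=" else ">=", nd),
            r = numeric(nd),
            block = "cyclic_growth", k_lab = rep(nt, nd), id_lab = dyn)

  # start biomass: w'M^0 = B0 (or <=)
  add_block(i = rep(1L, length(wnz)), j = Mi(0L, wnz), x = w[wnz],
            d = if (start_mode == "cap") "<=" else "=",
            r = model$biomass_start_cap,
            block = "start_biomass", k_lab = 0L, id_lab = "b0")

  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(rowoff, n_M + n_v))

  # bounds
  lb <- c(numeric(n_M), rep(NA_real_, n_v))
  ub <- c(rep(Inf, n_M), rep(NA_real_, n_v))
  r_lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  r_ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  lb[n_M + seq_len(n_v)] <- rep(r_lb, nt)
  ub[n_M + seq_len(n_v)] <- rep(r_ub, nt)
  # dark intervals: shut reactions that produce the light species
  if (!is.null(model$light_species)) {
    produces_light <- vapply(model$reactions, function(r) {
      s <- r$stoichiometry[model$light_species]
      !is.na(s) && s > 0
    }, TRUE)
    for (k in which(is_dark)) {
      cap <- light$photon_ub[k]
      idx <- n_M + (k - 1) * nr + which(produces_light)
      ub[idx] <- pmin(ub[idx], cap)
      lb[idx] <- pmax(pmin(lb[idx], cap), 0)
    }
  }

  vars <- data.frame(
    kind = c(rep("M", n_M), rep("v", n_v)),
    k = c(rep(0:nt, each = nd), rep(seq_len(nt), each = nr)),
    id = c(rep(dyn, nt + 1), rep(rxn, nt)),
    stringsAsFactors = FALSE)
  rows <- data.frame(
    block = unlist(rblock), k = unlist(rk), id = unlist(rid),
    stringsAsFactors = FALSE)

  lp <- structure(list(A = A, dir = unlist(dir), rhs = unlist(rhs),
                       lb = lb, ub = ub, vars = vars, rows = rows,
                       alpha = alpha, grid = grid,
                       dynamic = dyn, balanced = bal, reactions = rxn,
                       n_M = n_M, n_v = n_v, S_A = sm$S_A),
                  class = "cfba_lp")
  # positions of the -alpha entries (cyclic rows x M^0 columns) in A@x,
  # so bisection can re-target alpha without reassembling
  cycrows <- which(lp$rows$block == "cyclic_growth")
  idx <- integer(nd)
  for (j in seq_len(nd)) {
    col <- Mi(0L, j)
    span <- (A@p[col] + 1L):A@p[col + 1L]
    hit <- span[A@i[span] + 1L == cycrows[j]]
    idx[j] <- hit[1]
  }
  lp$alpha_idx <- idx
  lp
}

#' @exportS3Method base::print
print.cfba_lp <- function(x, ...) {
  cat(sprintf("<cfba_lp>: %d rows x %d variables (%d amounts, %d fluxes), alpha = %g\n",
              nrow(x$A), ncol(x$A), x$n_M, x$n_v, x$alpha))
  tab <- table(x$rows$block)
  cat("  blocks:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Index of a variable in an assembled LP
#'
#' @param lp a [assemble_lp()] result.
#' @param kind `"M"` (amount at grid point `k`) or `"v"` (flux in interval `k`).
#' @param k grid point (0..n_t) or interval (1..n_t).
#' @param id compound or reaction id.
#' @return integer column index.
#' @export
lp_var_index <- function(lp, kind, k, id) {
  which(lp$vars$kind == kind & lp$vars$k == k & lp$vars$id == id)
}

# re-target an assembled LP to a different growth factor by patching the
# -alpha entries of the cyclic-growth block
lp_set_alpha <- function(lp, alpha) {
  lp$A@x[lp$alpha_idx] <- -alpha
  lp$alpha <- alpha
  lp
}

#' Constraint violation of a trajectory, with exact Euler re-integration
#'
#' Evaluates how well a candidate `(M^0, v)` satisfies the cFBA semantics
#' of a model. The amount time course is first *re-integrated exactly*
#' from the fluxes (`M^k = M^{k-1} + dt S_A v^k`), so Euler-update slack
#' cannot accumulate multiplicatively across intervals; all remaining
#' constraint families (balanced-compound steady state, flux bounds,
#' capacity, quota, maintenance, nonnegativity, cyclic growth, start
#' biomass) are then checked on the re-integrated amounts. The returned
#' value is the largest relative violation; a genuinely feasible
#' trajectory returns ~0.
#'
#' @param model a [cfba_model()].
#' @param grid the [make_grid()] grid of the trajectory.
#' @param light the light profile used (or `NULL`).
#' @param traj a `cfba_trajectory` (only `M[1, ]` and `v` are used).
#' @param alpha growth factor to check against (default: the
#'   trajectory's).
#' @param options the [assemble_lp()] options used for the run.
#' @return largest relative constraint violation (scalar).
#' @export
trajectory_violation <- function(model, grid, light = NULL, traj,
                                 alpha = traj$alpha, options = list()) {
  sm <- stoich_matrix(model)
  nt <- grid$n_t
  dt <- grid$dt_sec
  dyn <- sm$dynamic
  v <- traj$v[, sm$reactions, drop = FALSE]
  if (is.null(light)) {
    light <- list(gamma = rep(1, nt), photon_ub = rep(Inf, nt))
  }
  is_dark <- grid$phase == "dark"
  # exact re-integration from the starting amounts
  M <- matrix(0, nt + 1, length(dyn), dimnames = list(NULL, dyn))
  M[1, ] <- traj$M[1, dyn]
  dM <- t(as.matrix(sm$S_A %*% t(v))) * dt      # nt x nd increments
  for (k in seq_len(nt)) M[k + 1, ] <- M[k, ] + dM[k, ]

  viol <- 0
  bump <- function(x) viol <<- max(viol, x)
  rel <- function(excess, scale) max(excess, 0) / (1 + abs(scale))

  # steady state of balanced compounds (incl. the light species row)
  if (nrow(sm$S_B) > 0) {
    sb <- as.matrix(sm$S_B %*% t(v))            # nbal x nt
    sb_scale <- as.matrix(abs(sm$S_B) %*% t(abs(v)))
    bump(max(abs(sb) / (1 + sb_scale)))
  }
  # flux bounds and dark photon shutdown
  r_lb <- vapply(model$reactions, `[[`, 0, "lower_bound")[sm$reactions]
  r_ub <- vapply(model$reactions, `[[`, 0, "upper_bound")[sm$reactions]
  for (k in seq_len(nt)) {
    lbk <- r_lb
    ubk <- r_ub
    if (!is.null(model$light_species) && is_dark[k]) {
      produces <- vapply(model$reactions[sm$reactions], function(r) {
        sl <- r$stoichiometry[model$light_species]
        !is.na(sl) && sl > 0
      }, TRUE)
      ubk[produces] <- pmin(ubk[produces], light$photon_ub[k])
      lbk[produces] <- pmax(pmin(lbk[produces], ubk[produces]), 0)
    }
    fin <- which(is.finite(lbk))
    if (length(fin)) bump(rel(max(lbk[fin] - v[k, fin]),
                              max(abs(lbk[fin]))))
    fin <- which(is.finite(ubk))
    if (length(fin)) bump(rel(max(v[k, fin] - ubk[fin]),
                              max(abs(ubk[fin]))))
  }
  # capacity (amounts at the interval start)
  invk_scale <- if (identical(model$flux_time_unit, "hour")) 3600 else 1
  for (cc in model$capacity_constraints) {
    for (k in seq_len(nt)) {
      g <- if (cc$light_modulated) light$gamma[k] else 1
      if (cc$light_modulated && (is_dark[k] || !is.finite(g))) next
      lhs <- sum(cc$terms$inverse_kcat * invk_scale * g *
                   v[k, cc$terms$reaction])
      bump(rel(lhs - M[k, cc$catalyst], lhs))
    }
  }
  # quota and maintenance against biomass
  w <- biomass_weights(model)[dyn]
  b <- as.numeric(M %*% w)
  for (q in model$quota_constraints) {
    ks <- if (q$enforce == "start_only") 1L else seq_len(nt + 1)
    for (k in ks) {
      need <- q$fraction * b[k]
      bump(rel(need - sum(M[k, q$members]), need))
    }
  }
  for (mc in model$maintenance_constraints) {
    bc <- mc$biomass_coefficient /
      (if (mc$biomass_per == "hour") 3600 else 1)
    for (k in seq_len(nt)) {
      lhs <- sum(mc$flux_terms * v[k, names(mc$flux_terms)])
      bump(rel(bc * b[k] - lhs, bc * b[k]))
    }
  }
  # nonnegativity, cyclic growth, start biomass
  bump(max(rel(max(-M), max(abs(M)))))
  cyc_mode <- options$cyclic %||% "inequality"
  short <- alpha * M[1, ] - M[nt + 1, ]
  if (cyc_mode == "equality") {
    bump(max(abs(short) / (1 + alpha * abs(M[1, ]))))
  } else {
    bump(max(short / (1 + alpha * abs(M[1, ]))))
  }
  start_mode <- options$start_biomass %||% "equality"
  B0 <- model$biomass_start_cap
  if (start_mode == "cap") {
    bump(rel(b[1] - B0, B0))
  } else {
    bump(abs(b[1] - B0) / (1 + B0))
  }
  viol
}
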