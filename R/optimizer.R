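#' Feasibility of the cyclic-growth LP at a fixed growth factor
#'
#' Assembles the LP for the given `alpha` and decides feasibility in
#' tiers: a parsimony-anchored solve whose homogeneous-embedding status
#' certifies infeasibility directly; a direct violation check of the
#' returned point (with projection polishing); on small models a
#' maximize-the-worst-cyclic-slack solve that decides by sign; and an
#' elastic relaxation as the last resort. Solver failures are surfaced
#' through `status`, never conflated with infeasibility.
#'
#' @inheritParams assemble_lp
#' @param feastol relative artificial-mass threshold below which the LP is
#'   declared feasible.
#' @param certificate if `TRUE` (default) and feasible, return the
#'   near-feasible point as a trajectory.
#' @return list with `feasible` (logical), `infeas` (relative residual),
#'   `status` (solver status), and `trajectory` (a `cfba_trajectory` or
#'   `NULL`).
#' @export
is_feasible <- function(model, grid, light = NULL, alpha,
                        feastol = 1e-7, options = list(),
                        certificate = TRUE) {
  lp <- assemble_lp(model, grid, alpha, light, options)
  is_feasible_lp(lp, model, alpha, feastol, certificate, light, options)
}

# feasibility verdict on an already-assembled LP (whose cyclic rows must
# carry this alpha; see lp_set_alpha). `light`/`options` are needed for
# the re-integration certificate on large problems.
is_feasible_lp <- function(lp, model, alpha, feastol = 1e-7,
                           certificate = TRUE, light = NULL,
                           options = list(), fast = FALSE) {
  # parsimony objective (minimize total irreversible flux): a pure
  # feasibility objective leaves the flux space hugely degenerate and
  # near-intractable, while an anchored LP is solved decisively by the
  # homogeneous embedding, whose status separates infeasibility from
  # numerical failure
  obj <- numeric(ncol(lp$A))
  irrev <- !vapply(model$reactions, `[[`, TRUE, "reversible")
  vsel <- lp$vars$kind == "v" & irrev[match(lp$vars$id, reaction_ids(model))]
  obj[vsel] <- 1
  big <- (nrow(lp$A) + ncol(lp$A)) > 4000
  ctrl <- if (big) list(tol = 1e-8, maxit = 60) else
    list(tol = max(1e-9, feastol / 3))
  res <- solve_lp(obj, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub, control = ctrl)
  if (res$status == "infeasible") {
    return(list(feasible = FALSE, infeas = 1, status = res$status,
                trajectory = NULL))
  }
  # on large discretizations the solver's accuracy floor (~1e-4 relative)
  # is the decision tolerance; small models are decided at feastol.
  # Certification on the loose path goes through exact Euler
  # re-integration of the candidate fluxes (trajectory_violation), so
  # per-row slack cannot compound into fictitious growth over many
  # intervals.
  cert_tol <- if (big) max(feastol, 1e-4) else feastol
  # the re-integration metric cannot compound across intervals, so the
  # reduced-accuracy decision tolerance on it can sit at the solver's
  # actual accuracy plateau; precision tiers run first, so well-behaved
  # problems never reach it
  cert_tol_reint <- max(feastol, 3e-3)
  viol <- lp_max_violation(lp, res$x)
  if (res$status != "optimal" && viol > cert_tol && viol < 1e-2) {
    # polish the best iterate onto the constraint set; a successful
    # projection is a feasibility certificate regardless of optimality
    res$x <- lp_project(lp, res$x)
    viol <- lp_max_violation(lp, res$x)
  }
  if (viol <= max(cert_tol, if (big) 1e-2 else 0)) {
    traj <- extract_trajectory(lp, res$x, alpha, status = res$status)
    tv <- if (big) {
      trajectory_violation(model, lp$grid, light, traj, alpha, options)
    } else viol
    if (tv <= cert_tol_reint) {
      return(list(feasible = TRUE, infeas = tv, status = res$status,
                  trajectory = if (certificate) traj else NULL))
    }
  }
  # still ambiguous: maximize the worst cyclic slack t in
  # M^{nt} - alpha M^0 >= t. This LP is feasible by construction and its
  # optimum t* decides feasibility by sign, which resolves alpha to high
  # precision when the solve converges.
  cyc <- which(lp$rows$block == "cyclic_growth")
  if (!big && all(lp$dir[cyc] == ">=")) {
    At <- cbind(lp$A, Matrix::sparseMatrix(i = cyc,
                                           j = rep(1L, length(cyc)),
                                           x = -1,
                                           dims = c(nrow(lp$A), 1L)))
    w <- biomass_weights(model)
    scale_t <- (1 + alpha) * model$biomass_start_cap / min(w[w > 0])
    objt <- c(-1e-8 * scale_t * obj, 1)   # vanishing parsimony anchor
    rest <- solve_lp(objt, At, lp$dir, lp$rhs,
                     c(lp$lb, -scale_t), c(lp$ub, 0.01 * scale_t),
                     maximize = TRUE,
                     control = list(tol = max(1e-9, feastol / 3)))
    if (rest$status == "optimal") {
      tstar <- rest$x[length(rest$x)]
      feas <- tstar >= -feastol * scale_t
      traj <- NULL
      if (feas && certificate) {
        traj <- extract_trajectory(lp, rest$x[seq_len(ncol(lp$A))],
                                   alpha, status = rest$status)
      }
      return(list(feasible = feas, infeas = max(-tstar, 0) / scale_t,
                  status = rest$status, trajectory = traj))
    }
  }
  # reduced-accuracy certificate for stalled solves of any size: exact
  # Euler re-integration of the candidate point
  if (res$status %in% c("stalled", "numerical") && viol < 1e-2) {
    traj <- extract_trajectory(lp, res$x, alpha, status = res$status)
    tv <- trajectory_violation(model, lp$grid, light, traj, alpha,
                               options)
    if (tv <= cert_tol_reint) {
      return(list(feasible = TRUE, infeas = tv, status = res$status,
                  trajectory = if (certificate) traj else NULL))
    }
  }
  # last resort: the elastic relaxation, whose artificial mass measures
  # the violation directly. When the elastic solve itself converges, its
  # verdict is trusted at feastol; when it stalls, the decision is made
  # at the solver's accuracy floor (~1e-4 relative on large
  # discretizations) -- documented as the decision tolerance.
  ers <- solve_lp_elastic(NULL, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub,
                          feastol = feastol, control = ctrl)
  floor_tol <- if (big) 1e-4 else 10 * feastol
  feas <- if (ers$status == "optimal") ers$feasible else
    (min(viol, ers$infeas) <= floor_tol)
  traj <- NULL
  infeas_out <- ers$infeas
  if (feas && big) {
    # the per-row artificial mass can also hide compounding slack;
    # re-verify through exact re-integration
    traj <- extract_trajectory(lp, ers$x, alpha, status = ers$status)
    tv <- trajectory_violation(model, lp$grid, light, traj, alpha,
                               options)
    feas <- tv <= cert_tol_reint
    infeas_out <- tv
    if (!feas) traj <- NULL
  } else if (feas && certificate) {
    traj <- extract_trajectory(lp, ers$x, alpha, status = ers$status)
  }
  if (!certificate) traj <- NULL
  list(feasible = feas, infeas = infeas_out,
       status = paste0(res$status, "+", ers$status), trajectory = traj)
}

#' Maximize the cyclic growth factor by bisection
#'
#' Finds the largest `alpha` for which the time-discretized LP is
#' feasible. The upper bracket is auto-expanded by doubling until
#' infeasible, then bisection runs until the relative bracket width drops
#' below `tol`. The returned representative trajectory is re-solved at the
#' final feasible `alpha` with a parsimony objective (minimize total
#' irreversible flux), which selects a deterministic point from the
#' optimal face; the solution of the growth LP is in general not unique.
#'
#' @inheritParams is_feasible
#' @param alpha_lo initial lower bound; must be feasible (default 1).
#' @param alpha_hi initial upper bracket (expanded by doubling as needed).
#' @param tol relative bisection tolerance on `alpha`.
#' @param verbose if `TRUE`, log one line per bisection iteration.
#' @return a `cfba_trajectory`: list with `alpha`, amount matrix `M`
#'   (`(n_t+1) x n_dynamic`), flux matrix `v` (`n_t x n_reactions`),
#'   `grid`, `status`, and the bisection `log` (data.frame).
#' @export
maximize_alpha <- function(model, grid, light = NULL,
                           alpha_lo = 1, alpha_hi = 2, tol = 1e-6,
                           feastol = 1e-7, options = list(),
                           verbose = FALSE) {
  stopifnot(alpha_lo > 0, alpha_hi > alpha_lo, tol > 0)
  log_rows <- list()
  probe <- function(a) {
    r <- is_feasible_lp(lp_set_alpha(lp0, a), model, a, feastol,
                        certificate = FALSE, light = light,
                        options = options)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      alpha = a, feasible = r$feasible, infeas = r$infeas,
      status = r$status)
    if (verbose) {
      message(sprintf("alpha = %.10g : %s (infeas %.3g, %s)",
                      a, if (r$feasible) "feasible" else "infeasible",
                      r$infeas, r$status))
    }
    r$feasible
  }
  lp0 <- assemble_lp(model, grid, alpha_lo, light, options)
  if (!probe(alpha_lo)) {
    stop("no-growth-infeasible: LP infeasible at alpha_lo = ", alpha_lo,
         " (the model cannot maintain itself over the period)")
  }
  lo <- alpha_lo
  hi <- alpha_hi
  expansions <- 0L
  while (probe(hi)) {
    lo <- hi
    hi <- hi * 2
    expansions <- expansions + 1L
    if (expansions > 60L) stop("growth factor appears unbounded")
  }
  while ((hi - lo) / lo > tol) {
    mid <- sqrt(lo * hi)
    if (probe(mid)) lo <- mid else hi <- mid
  }
  traj <- representative_trajectory(model, grid, light, lo, feastol, options)
  traj$log <- do.call(rbind, log_rows)
  traj$alpha_interval <- c(lo, hi)
  traj
}

# Parsimonious representative solution at a fixed (feasible) alpha:
# minimize the summed flux of irreversible reactions (for reversible
# reactions the net flux is not a flux magnitude; they get weight 0).
representative_trajectory <- function(model, grid, light, alpha,
                                      feastol = 1e-7, options = list()) {
  lp <- assemble_lp(model, grid, alpha, light, options)
  obj <- numeric(ncol(lp$A))
  irrev <- !vapply(model$reactions, `[[`, TRUE, "reversible")
  vsel <- lp$vars$kind == "v" & irrev[match(lp$vars$id, reaction_ids(model))]
  obj[vsel] <- 1
  cyc <- which(lp$rows$block == "cyclic_growth")
  if (all(lp$dir[cyc] == ">=")) {
    # parsimonious solve with a nonnegative cyclic slack column: keeps an
    # interior even when alpha sits at the feasibility boundary
    At <- cbind(lp$A, Matrix::sparseMatrix(i = cyc,
                                           j = rep(1L, length(cyc)),
                                           x = -1,
                                           dims = c(nrow(lp$A), 1L)))
    w <- biomass_weights(model)
    Mmax0 <- model$biomass_start_cap / min(w[w > 0])
    res <- solve_lp(c(obj, 0), At, lp$dir, lp$rhs,
                    c(lp$lb, 0), c(lp$ub, 10 * (1 + alpha) * Mmax0))
    xlp <- res$x[seq_len(ncol(lp$A))]
    if (res$status == "optimal" ||
        (res$status == "stalled" && lp_max_violation(lp, xlp) <= 1e-4)) {
      return(extract_trajectory(lp, xlp, alpha, status = res$status))
    }
  }
  res <- solve_lp_elastic(obj, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub,
                          feastol = feastol)
  if (!res$feasible) {
    # last resort: the max-slack certificate from the feasibility probe
    fz <- is_feasible(model, grid, light, alpha, feastol, options,
                      certificate = TRUE)
    if (!fz$feasible || is.null(fz$trajectory)) {
      stop("representative solve infeasible at alpha = ", alpha,
           " (status ", res$status, ")")
    }
    return(fz$trajectory)
  }
  extract_trajectory(lp, res$x, alpha, status = res$status)
}

extract_trajectory <- function(lp, x, alpha, status = "optimal") {
  nd <- length(lp$dynamic)
  nr <- length(lp$reactions)
  nt <- lp$grid$n_t
  M0 <- x[seq_len(nd)]
  v <- matrix(x[lp$n_M + seq_len(lp$n_v)], nrow = nt, ncol = nr,
              byrow = TRUE, dimnames = list(NULL, lp$reactions))
  # reported amounts are the exact Euler images of the reported fluxes,
  # so the trajectory is self-consistent to machine precision
  M <- matrix(0, nt + 1, nd, dimnames = list(NULL, lp$dynamic))
  M[1, ] <- pmax(M0, 0)
  dM <- t(as.matrix(lp$S_A %*% t(v))) * lp$grid$dt_sec
  for (k in seq_len(nt)) M[k + 1, ] <- M[k, ] + dM[k, ]
  structure(list(alpha = alpha, M = M, v = v,
                 grid = lp$grid, status = status),
            class = "cfba_trajectory")
}

#' @exportS3Method base::print
print.cfba_trajectory <- function(x, ...) {
  cat(sprintf("<cfba_trajectory>: alpha = %.6g over %g h (%d intervals), %d compounds, %d reactions\n",
              x$alpha, x$grid$T_hours, x$grid$n_t, ncol(x$M), ncol(x$v)))
  invisible(x)
}

#' Flux and compound variability at a fixed growth factor
#'
#' With `alpha` fixed, every requested flux (per interval) and compound
#' amount (per grid point) is minimized and maximized subject to the full
#' LP — two solves per variable. The width `max - min` quantifies the
#' non-uniqueness of the optimal solution.
#'
#' @inheritParams is_feasible
#' @param alpha the (maximal) growth factor at which to fix the LP.
#' @param reactions,compounds character vectors restricting the scan
#'   (default: all).
#' @param intervals integer vector of intervals/grid points to scan
#'   (default: all).
#' @return a `cfba_envelope`: data.frame with columns `kind` (`"v"`/`"M"`),
#'   `id`, `k`, `t_start_h`, `t_end_h`, `min`, `max`, `status`.
#' @export
variability <- function(model, grid, light = NULL, alpha,
                        reactions = NULL, compounds = NULL,
                        intervals = NULL, feastol = 1e-7,
                        options = list()) {
  lp <- assemble_lp(model, grid, alpha, light, options)
  nt <- grid$n_t
  if (is.null(reactions)) reactions <- lp$reactions
  if (is.null(compounds)) compounds <- lp$dynamic
  rows <- list()
  cyc <- which(lp$rows$block == "cyclic_growth")
  Aslack <- cbind(lp$A, Matrix::sparseMatrix(i = cyc,
                                             j = rep(1L, length(cyc)),
                                             x = -1,
                                             dims = c(nrow(lp$A), 1L)))
  wts <- biomass_weights(model)
  tcap <- 10 * (1 + alpha) * model$biomass_start_cap / min(wts[wts > 0])
  solve_dir <- function(obj, maximize) {
    res <- solve_lp(obj, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub,
                    maximize = maximize)
    if (res$status == "optimal") {
      return(list(ok = TRUE, val = res$objval, status = res$status))
    }
    if (all(lp$dir[cyc] == ">=")) {
      # equivalent reformulation with an explicit nonnegative cyclic
      # slack; often better conditioned at the feasibility boundary
      res <- solve_lp(c(obj, 0), Aslack, lp$dir, lp$rhs,
                      c(lp$lb, 0), c(lp$ub, tcap), maximize = maximize)
      if (res$status == "optimal") {
        return(list(ok = TRUE, val = res$objval, status = res$status))
      }
    }
    res <- solve_lp_elastic(obj, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub,
                            maximize = maximize, feastol = feastol)
    list(ok = res$feasible, val = res$objval, status = res$status)
  }
  bound_one <- function(kind, k, id) {
    jcol <- lp_var_index(lp, kind, k, id)
    obj <- numeric(ncol(lp$A))
    obj[jcol] <- 1
    lo <- solve_dir(obj, FALSE)
    hi <- solve_dir(obj, TRUE)
    status <- if (lo$ok && hi$ok) "ok" else
      paste0("min:", lo$status, "/max:", hi$status)
    hrs <- lp$grid$boundaries_sec / 3600
    data.frame(kind = kind, id = id, k = k,
               t_start_h = if (kind == "v") hrs[k] else hrs[k + 1],
               t_end_h = if (kind == "v") hrs[k + 1] else hrs[k + 1],
               min = if (lo$ok) lo$val else NA_real_,
               max = if (hi$ok) hi$val else NA_real_,
               status = status, stringsAsFactors = FALSE)
  }
  kv <- if (is.null(intervals)) seq_len(nt) else intervals
  kM <- if (is.null(intervals)) 0:nt else intervals
  for (id in reactions) for (k in kv) {
    rows[[length(rows) + 1L]] <- bound_one("v", k, id)
  }
  for (id in compounds) for (k in kM) {
    rows[[length(rows) + 1L]] <- bound_one("M", k, id)
  }
  env <- do.call(rbind, rows)
  class(env) <- c("cfba_envelope", class(env))
  env
}

#' Does a trajectory lie inside a variability envelope?
#'
#' @param env a [variability()] envelope.
#' @param traj a `cfba_trajectory` at the same `alpha`.
#' @param tol absolute slack allowed at the envelope boundary.
#' @return logical.
#' @export
envelope_contains <- function(env, traj, tol = 1e-6) {
  val <- numeric(nrow(env))
  for (r in seq_len(nrow(env))) {
    val[r] <- if (env$kind[r] == "v") {
      traj$v[env$k[r], env$id[r]]
    } else {
      traj$M[env$k[r] + 1, env$id[r]]
    }
  }
  scale <- pmax(1, abs(env$max), abs(env$min))
  all(val >= env$min - tol * scale & val <= env$max + tol * scale,
      na.rm = TRUE)
}

# Alternating projection of a near-feasible point onto the constraint
# rows and the variable box. One sparse Cholesky of A A' is reused across
# rounds; inequality rows are only corrected where violated.
lp_project <- function(lp, x, rounds = 25, tol = 1e-7) {
  A <- lp$A
  m <- nrow(A)
  AAt <- Matrix::tcrossprod(A) + Matrix::Diagonal(m, 1e-10)
  ch <- tryCatch(suppressWarnings(
    Matrix::Cholesky(Matrix::forceSymmetric(AAt), LDL = FALSE,
                     perm = TRUE)),
    error = function(e) NULL)
  if (is.null(ch)) return(x)
  best <- x
  best_v <- lp_max_violation(lp, x)
  for (r in seq_len(rounds)) {
    ax <- as.numeric(A %*% x)
    corr <- lp$rhs - ax
    corr[lp$dir == "<="] <- pmin(corr[lp$dir == "<="], 0)
    corr[lp$dir == ">="] <- pmax(corr[lp$dir == ">="], 0)
    x <- x + as.numeric(Matrix::crossprod(A, Matrix::solve(ch, corr)))
    x <- pmin(pmax(x, lp$lb), lp$ub)
    v <- lp_max_violation(lp, x)
    if (v < best_v) {
      best <- x
      best_v <- v
    }
    if (v <= tol) break
  }
  best
}

# largest scaled violation of an assembled LP at a candidate point
lp_max_violation <- function(lp, x) {
  ax <- as.numeric(lp$A %*% x)
  sc <- 1 + abs(lp$rhs) + abs(ax)
  r <- ax - lp$rhs
  row_viol <- ifelse(lp$dir == "<=", pmax(r, 0),
                     ifelse(lp$dir == ">=", pmax(-r, 0), abs(r))) / sc
  lbv <- pmax(lp$lb - x, 0) / (1 + abs(lp$lb))
  ubv <- pmax(x - lp$ub, 0) / (1 + abs(x))
  lbv[!is.finite(lp$lb)] <- 0
  ubv[!is.finite(lp$ub)] <- 0
  max(row_viol, lbv, ubv)
}
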