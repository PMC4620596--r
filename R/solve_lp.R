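#' Sparse interior-point linear programming
#'
#' Solves `min c'x` subject to `A x (dir) rhs` and `lb <= x <= ub` with a
#' Mehrotra-type predictor-corrector interior-point method on the
#' homogeneous self-dual embedding. The constraint matrix is held sparse
#' (`Matrix::dgCMatrix`) and the normal equations are factorized with
#' CHOLMOD. The homogeneous embedding yields clean certificates: an
#' infeasible program drives the homogenizing variable to zero and is
#' reported as `status = "infeasible"` (or `"unbounded"` for dual
#' infeasibility) rather than trapping the iteration at an infeasible
#' stationary point. The method is deterministic: two calls with
#' identical inputs return identical results.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), any base or Matrix class.
#' @param dir character vector of row senses: `"="`, `"<="`, `">="`.
#' @param rhs numeric right-hand sides (length m).
#' @param lb,lower lower variable bounds, `-Inf` allowed (default 0).
#' @param ub,upper upper variable bounds, `Inf` allowed (default `Inf`).
#' @param maximize if `TRUE` maximize `c'x` instead.
#' @param control list of solver options: `tol` (relative KKT tolerance,
#'   default `1e-8`), `maxit` (default `200`), `trace` (logical).
#' @return list with elements `x` (primal solution on the original
#'   variables), `objval`, `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"stalled"`, `"numerical"`), `iterations`, `gap`
#'   (final relative duality gap). For `"stalled"` the best (reduced
#'   accuracy) iterate is returned; for certificates `x` is meaningless.
#' @export
solve_lp <- function(obj, A, dir, rhs, lb = 0, ub = Inf,
                     maximize = FALSE, control = list(),
                     lower = NULL, upper = NULL) {
  if (!is.null(lower)) lb <- lower
  if (!is.null(upper)) ub <- upper
  std <- lp_standardize(obj, A, dir, rhs, lb, ub, maximize)
  res <- ip_solve(std$c, std$A, std$b, std$u, control)
  x <- lp_destandardize(std, res$x)
  objval <- sum(obj * x)
  list(x = x, objval = objval, status = res$status,
       iterations = res$iterations, gap = res$gap)
}

#' Elastic (always-feasible) linear programming
#'
#' Augments every constraint row with a pair of nonnegative artificial
#' variables so the program is feasible by construction, and minimizes
#' `penalty * sum(artificials) + c'x`. With `obj = NULL` this is a pure
#' phase-1 feasibility probe: the original program is feasible if and only
#' if the artificial mass is (numerically) zero. With an objective it acts
#' as an exact-penalty solve; the penalty is escalated automatically until
#' the artificials vanish or the program is declared infeasible.
#'
#' @inheritParams solve_lp
#' @param obj objective on the original variables, or `NULL` for a pure
#'   feasibility probe.
#' @param penalty initial artificial penalty weight.
#' @param feastol artificial mass (relative to `1 + ||rhs||`) below which
#'   the original program is considered feasible.
#' @return list with `x`, `objval` (on the original objective, `NA` for
#'   probes), `feasible` (logical), `infeas` (relative artificial mass),
#'   `status`.
#' @export
solve_lp_elastic <- function(obj, A, dir, rhs, lb = 0, ub = Inf,
                             maximize = FALSE, penalty = 1e3,
                             feastol = 1e-7, control = list()) {
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  m <- nrow(A)
  n <- ncol(A)
  probe <- is.null(obj)
  if (probe) obj <- numeric(n)
  if (maximize) { obj <- -obj; maximize <- FALSE }
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  # artificial pair (p, q) on every row: A x + p - q  (dir)  rhs
  Aaug <- cbind(A, Matrix::Diagonal(m), -Matrix::Diagonal(m))
  scale_rhs <- 1 + max(abs(rhs[is.finite(rhs)]), 0)
  obj_scale <- 1 + max(abs(obj), 0)
  lba <- c(lb, numeric(2 * m))
  uba <- c(ub, rep(Inf, 2 * m))
  rho <- penalty * obj_scale
  for (round in 1:4) {
    ca <- c(obj, rep(rho, 2 * m))
    res <- solve_lp(ca, Aaug, dir, rhs, lba, uba, control = control)
    art <- sum(res$x[(n + 1):(n + 2 * m)])
    infeas <- art / scale_rhs
    if (probe || infeas <= feastol || res$status != "optimal") break
    rho <- rho * 100
  }
  list(x = res$x[seq_len(n)],
       objval = if (probe) NA_real_ else sum(obj * res$x[seq_len(n)]),
       feasible = infeas <= feastol,
       infeas = infeas,
       status = res$status)
}

# --- standard-form conversion -------------------------------------------

# Convert a general LP to: min c'x  s.t.  A x = b,  0 <= x <= u.
# Inequality rows gain slack columns; variables are shifted/mirrored/split
# so every retained variable has lower bound 0. Fixed variables
# (lb == ub) are substituted out.
lp_standardize <- function(obj, A, dir, rhs, lb, ub, maximize) {
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(rhs) == m, length(dir) == m)
  obj <- rep_len(as.numeric(obj), n)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub)) stop("lower bound exceeds upper bound")
  if (maximize) obj <- -obj

  T <- Matrix::mat2triplet(A)
  ti <- T$i; tj <- T$j; tx <- T$x

  # variable transforms: type 1 shift (finite lb), 2 mirror (lb=-Inf,
  # finite ub), 3 split (free), 0 fixed.
  vtype <- integer(n)
  vtype[is.finite(lb)] <- 1L
  vtype[!is.finite(lb) & is.finite(ub)] <- 2L
  vtype[!is.finite(lb) & !is.finite(ub)] <- 3L
  fixed <- is.finite(lb) & is.finite(ub) & (ub - lb) <= 0
  vtype[fixed] <- 0L

  keep <- which(!fixed)
  # rhs adjustment from fixed variables and shifts
  shift <- ifelse(vtype == 1L, lb, 0)
  shift[fixed] <- lb[fixed]
  adj <- as.numeric(A %*% ifelse(vtype == 2L, 0, shift))
  b <- rhs - adj

  # column bookkeeping for retained variables
  ncol_new <- length(keep) + sum(vtype == 3L)
  colmap <- integer(n)            # first std column of each original var
  colmap[keep] <- seq_along(keep)
  split_extra <- integer(n)       # second column of split vars
  if (any(vtype == 3L)) {
    sv <- which(vtype == 3L)
    split_extra[sv] <- length(keep) + seq_along(sv)
  }

  sel <- !fixed[tj]
  ti2 <- ti[sel]; tj2 <- tj[sel]; tx2 <- tx[sel]
  sgn <- ifelse(vtype[tj2] == 2L, -1, 1)   # mirrored columns negate
  i_new <- ti2
  j_new <- colmap[tj2]
  x_new <- tx2 * sgn
  # extra negated copies for split variables
  spl <- vtype[tj2] == 3L
  if (any(spl)) {
    i_new <- c(i_new, ti2[spl])
    j_new <- c(j_new, split_extra[tj2[spl]])
    x_new <- c(x_new, -tx2[spl])
  }

  c_new <- numeric(ncol_new)
  u_new <- rep(Inf, ncol_new)
  ck <- keep
  c_new[colmap[ck]] <- obj[ck] * ifelse(vtype[ck] == 2L, -1, 1)
  fin <- ck[vtype[ck] == 1L & is.finite(ub[ck])]
  u_new[colmap[fin]] <- ub[fin] - lb[fin]
  if (any(vtype == 3L)) {
    sv <- which(vtype == 3L)
    c_new[split_extra[sv]] <- -obj[sv]
  }
  # mirrored: x = ub - x', objective constant ub*c ignored (recovered later)

  # slacks for inequality rows
  ns <- sum(dir != "=")
  if (ns > 0) {
    srows <- which(dir != "=")
    i_new <- c(i_new, srows)
    j_new <- c(j_new, ncol_new + seq_len(ns))
    x_new <- c(x_new, ifelse(dir[srows] == "<=", 1, -1))
    c_new <- c(c_new, numeric(ns))
    u_new <- c(u_new, rep(Inf, ns))
    ncol_new <- ncol_new + ns
  }

  Astd <- Matrix::sparseMatrix(i = i_new, j = j_new, x = x_new,
                               dims = c(m, ncol_new))
  list(c = c_new, A = Astd, b = b, u = u_new,
       n_orig = n, vtype = vtype, lb = lb, ub = ub,
       colmap = colmap, split_extra = split_extra, fixed = fixed)
}

lp_destandardize <- function(std, xstd) {
  x <- numeric(std$n_orig)
  for (j in seq_len(std$n_orig)) {
    if (std$fixed[j]) {
      x[j] <- std$lb[j]
    } else if (std$vtype[j] == 1L) {
      x[j] <- std$lb[j] + xstd[std$colmap[j]]
    } else if (std$vtype[j] == 2L) {
      x[j] <- std$ub[j] - xstd[std$colmap[j]]
    } else {
      x[j] <- xstd[std$colmap[j]] - xstd[std$split_extra[j]]
    }
  }
  x
}

# --- homogeneous self-dual interior point -------------------------------

# min c'x  s.t.  A x = b, 0 <= x <= u (u may be Inf). Finite upper bounds
# are folded into explicit rows x_j + s_j = u_j, giving the pure standard
# form the homogeneous embedding needs. In the embedding (x, tau) and
# (y, z, kappa) solve
#     A x = b tau,  A'y + z = c tau,  b'y - c'x = kappa,
# with x, z, tau, kappa >= 0; tau > 0 at convergence yields the solution
# x/tau, while tau -> 0 with kappa > 0 certifies primal or dual
# infeasibility (b'y > 0 resp. c'x < 0).
ip_solve <- function(cc, A, b, u, control = list()) {
  tol <- control$tol %||% 1e-8
  maxit <- control$maxit %||% 200
  trace <- isTRUE(control$trace)

  m <- nrow(A)
  n <- ncol(A)
  if (n == 0L) {
    ok <- length(b) == 0L || max(abs(b)) <= tol * (1 + max(abs(b), 0))
    return(list(x = numeric(0), status = if (ok) "optimal" else "infeasible",
                iterations = 0L, gap = 0))
  }
  # fold finite upper bounds into rows
  U <- which(is.finite(u))
  if (length(U)) {
    nu <- length(U)
    Aub <- Matrix::sparseMatrix(
      i = c(seq_len(nu), seq_len(nu)),
      j = c(U, n + seq_len(nu)),
      x = rep(1, 2 * nu), dims = c(nu, n + nu))
    A <- rbind(cbind(A, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0),
                                             dims = c(m, nu))),
               Aub)
    b <- c(b, u[U])
    cc <- c(cc, numeric(nu))
    m <- m + nu
    n <- n + nu
  }
  A <- methods::as(A, "CsparseMatrix")

  # row/column equilibration (geometric-mean sweeps)
  Rsc <- rep(1, m); Csc <- rep(1, n)
  Aw <- A
  for (sweep in 1:5) {
    r <- sqrt(rowmax_abs(Aw) * rowmin_abs(Aw))
    r[!is.finite(r) | r == 0] <- 1
    Aw <- Matrix::Diagonal(x = 1 / r) %*% Aw
    Rsc <- Rsc / r
    cs <- sqrt(colmax_abs(Aw) * colmin_abs(Aw))
    cs[!is.finite(cs) | cs == 0] <- 1
    Aw <- Aw %*% Matrix::Diagonal(x = 1 / cs)
    Csc <- Csc / cs
  }
  Aw <- methods::as(Aw, "CsparseMatrix")
  # x = Csc * x_w  =>  c_w = c * Csc,  b_w = b * Rsc
  bw <- b * Rsc
  cw <- cc * Csc
  bscale <- max(1, sqrt(sum(bw^2) / max(m, 1)))
  cscale <- max(1, sqrt(sum(cw^2) / n))
  bw <- bw / bscale
  cw <- cw / cscale
  At <- Matrix::t(Aw)
  bnorm <- 1 + sqrt(sum(bw^2))
  cnorm <- 1 + sqrt(sum(cw^2))

  x <- rep(1, n); z <- rep(1, n); y <- numeric(m)
  tau <- 1; kappa <- 1
  mu0 <- (sum(x * z) + tau * kappa) / (n + 1)

  status <- "numerical"
  gaprel <- Inf
  it <- 0L
  delta <- control$delta0 %||% 1e-12
  ch_sym <- NULL   # symbolic Cholesky analysis, reused across iterations
  best <- list(x = x / tau, merit = Inf, gap = Inf, pinf = Inf, dinf = Inf)
  best_it <- 0L

  for (it in seq_len(maxit)) {
    F1 <- as.numeric(Aw %*% x) - bw * tau
    F2 <- as.numeric(At %*% y) + z - cw * tau
    F3 <- sum(bw * y) - sum(cw * x) - kappa
    mu <- (sum(x * z) + tau * kappa) / (n + 1)

    # scaled-point measures
    xs <- x / tau
    pinf <- sqrt(sum((as.numeric(Aw %*% xs) - bw)^2)) / bnorm
    dinf <- sqrt(sum((as.numeric(At %*% (y / tau)) + z / tau - cw)^2)) / cnorm
    pobj <- sum(cw * xs)
    dobj <- sum(bw * y) / tau
    gaprel <- abs(pobj - dobj) / (1 + abs(pobj))
    merit <- max(pinf, dinf, gaprel)
    if (merit < best$merit) {
      # count only substantial gains toward the stall window
      if (merit < 0.8 * best$merit) best_it <- it
      best <- list(x = xs, merit = merit, gap = gaprel, pinf = pinf,
                   dinf = dinf)
    }
    if (trace) {
      message(sprintf(
        "it %3d mu %.3e tau %.3e kap %.3e pinf %.3e dinf %.3e gap %.3e",
        it, mu, tau, kappa, pinf, dinf, gaprel))
    }
    if (pinf < tol && dinf < 10 * tol && gaprel < 100 * tol) {
      status <- "optimal"
      best <- list(x = xs, merit = merit, gap = gaprel, pinf = pinf,
                   dinf = dinf)
      break
    }
    # infeasibility certificate: homogenizing variable collapses
    if (tau < 1e-10 * max(1, kappa) || (mu < 1e-12 * mu0 && tau < 1e-6)) {
      status <- if (sum(bw * y) > 1e-10) "infeasible"
        else if (-sum(cw * x) > 1e-10) "unbounded"
        else "numerical"
      break
    }
    if (it - best_it > 25L) {
      status <- if (best$pinf < 1e-4 && best$dinf < 1e-3 &&
                    best$gap < 3e-2) "stalled" else "numerical"
      break
    }

    dv <- z / x
    dv <- pmin(pmax(dv, 1e-12), 1e12)
    theta <- 1 / dv
    M0 <- Matrix::forceSymmetric(
      Matrix::tcrossprod(Aw %*% Matrix::Diagonal(x = theta), Aw))
    dM <- max(Matrix::diag(M0))
    ch <- NULL
    dl <- delta
    while (is.null(ch) && dl < 1e-2) {
      Mreg <- M0 + Matrix::Diagonal(m, dl * (1 + dM))
      ch <- tryCatch(
        suppressWarnings(
          if (is.null(ch_sym)) {
            Matrix::Cholesky(Mreg, LDL = FALSE, perm = TRUE)
          } else {
            # the sparsity pattern of A D A' is iteration-invariant:
            # reuse the symbolic analysis, refactor numerically
            Matrix::update(ch_sym, Mreg)
          }),
        error = function(e) NULL)
      if (is.null(ch)) dl <- dl * 100
    }
    if (is.null(ch)) break
    ch_sym <- ch
    solve_ref <- function(rhs_y) {
      dy <- as.numeric(Matrix::solve(ch, rhs_y))
      rnorm0 <- sqrt(sum(rhs_y^2)) + 1e-300
      for (ref in 1:2) {
        res <- rhs_y - as.numeric(M0 %*% dy)
        if (sqrt(sum(res^2)) < 1e-12 * rnorm0) break
        dy <- dy + as.numeric(Matrix::solve(ch, res))
      }
      dy
    }
    ADc <- as.numeric(Aw %*% (theta * cw))
    q1 <- solve_ref(ADc + bw)
    cDc <- sum(cw * theta * cw)
    cDAt_q1 <- sum((theta * cw) * as.numeric(At %*% q1))

    # one Newton solve of the embedding for given right-hand sides:
    #   Aw dx - bw dtau            = r1
    #   At dy + dz - cw dtau       = r2
    #   bw'dy - cw'dx - dkappa     = r3
    #   Z dx + X dz                = r4
    #   kappa dtau + tau dkappa    = r5
    newton_basic <- function(r1, r2, r3, r4, r5) {
      g <- r2 - r4 / x                      # = At dy - D dx - cw dtau
      rhs <- r1 + as.numeric(Aw %*% (theta * g))
      q2 <- solve_ref(rhs)
      cDAt_q2 <- sum((theta * cw) * as.numeric(At %*% q2))
      cDg <- sum(cw * theta * g)
      denom <- sum(bw * q1) - cDAt_q1 + cDc + kappa / tau
      numer <- r3 - sum(bw * q2) + cDAt_q2 - cDg + r5 / tau
      dtau <- numer / denom
      dy <- q2 + q1 * dtau
      dx <- theta * (as.numeric(At %*% dy) - cw * dtau - g)
      dz <- (r4 - z * dx) / x
      dkappa <- (r5 - kappa * dtau) / tau
      list(dx = dx, dy = dy, dz = dz, dtau = dtau, dkappa = dkappa)
    }
    solve_newton <- function(r1, r2, r3, r4, r5) {
      d <- newton_basic(r1, r2, r3, r4, r5)
      err <- Inf
      for (ref in 1:2) {
        e1 <- r1 - (as.numeric(Aw %*% d$dx) - bw * d$dtau)
        e2 <- r2 - (as.numeric(At %*% d$dy) + d$dz - cw * d$dtau)
        e3 <- r3 - (sum(bw * d$dy) - sum(cw * d$dx) - d$dkappa)
        e4 <- r4 - (z * d$dx + x * d$dz)
        e5 <- r5 - (kappa * d$dtau + tau * d$dkappa)
        err <- max(sqrt(sum(e1^2)) / bnorm, sqrt(sum(e2^2)) / cnorm)
        if (err < 1e-13) break
        dd <- newton_basic(e1, e2, e3, e4, e5)
        d2 <- list(dx = d$dx + dd$dx, dy = d$dy + dd$dy,
                   dz = d$dz + dd$dz, dtau = d$dtau + dd$dtau,
                   dkappa = d$dkappa + dd$dkappa)
        e1b <- r1 - (as.numeric(Aw %*% d2$dx) - bw * d2$dtau)
        e2b <- r2 - (as.numeric(At %*% d2$dy) + d2$dz - cw * d2$dtau)
        err2 <- max(sqrt(sum(e1b^2)) / bnorm, sqrt(sum(e2b^2)) / cnorm)
        if (err2 >= err) break
        d <- d2
        err <- err2
      }
      d$err <- err
      d
    }
    step_len <- function(v, dv) {
      idx <- dv < 0
      if (!any(idx)) return(1)
      min(1, min(-v[idx] / dv[idx]))
    }

    # predictor (affine)
    aff <- solve_newton(-F1, -F2, -F3, -x * z, -tau * kappa)
    if (aff$err > 1e-3 * (1 + merit)) {
      # hopeless direction: escalate regularization, give up only when
      # that is exhausted
      if (delta > 1e-4) break
      delta <- max(delta * 100, 1e-10)
      next
    }
    a_aff <- min(step_len(x, aff$dx), step_len(z, aff$dz),
                 if (aff$dtau < 0) -tau / aff$dtau else 1,
                 if (aff$dkappa < 0) -kappa / aff$dkappa else 1, 1)
    mu_aff <- (sum((x + a_aff * aff$dx) * (z + a_aff * aff$dz)) +
               (tau + a_aff * aff$dtau) * (kappa + a_aff * aff$dkappa)) /
      (n + 1)
    sigma <- min(1, max(0, mu_aff / mu))^3
    if (mu < 1e-3 * max(pinf, dinf)) sigma <- max(sigma, 0.5)

    eta <- 1 - sigma
    d <- solve_newton(-eta * F1, -eta * F2, -eta * F3,
                      sigma * mu - x * z - aff$dx * aff$dz,
                      sigma * mu - tau * kappa - aff$dtau * aff$dkappa)
    a <- 0.9995 * min(step_len(x, d$dx), step_len(z, d$dz),
                      if (d$dtau < 0) -tau / d$dtau else 1,
                      if (d$dkappa < 0) -kappa / d$dkappa else 1, 1)
    x_new <- pmax(x + a * d$dx, 1e-300)
    y_new <- y + a * d$dy
    z_new <- pmax(z + a * d$dz, 1e-300)
    tau_new <- max(tau + a * d$dtau, 1e-300)
    kappa_new <- max(kappa + a * d$dkappa, 1e-300)
    # vet the step: if the scaled-point merit explodes, the direction
    # was corrupted by roundoff -- revert and re-regularize instead
    xs_n <- x_new / tau_new
    pinf_n <- sqrt(sum((as.numeric(Aw %*% xs_n) - bw)^2)) / bnorm
    dinf_n <- sqrt(sum((as.numeric(At %*% (y_new / tau_new)) +
                          z_new / tau_new - cw)^2)) / cnorm
    if (max(pinf_n, dinf_n) > 10 * max(merit, 1e-9)) {
      if (delta > 1e-4) break
      delta <- max(delta * 100, 1e-10)
      next
    }
    x <- x_new; y <- y_new; z <- z_new
    tau <- tau_new; kappa <- kappa_new
  }
  if (status %in% c("numerical", "stalled") && is.finite(best$merit)) {
    if (status == "numerical" && best$pinf < 1e-4 && best$dinf < 1e-3 &&
        best$gap < 3e-2) {
      status <- "stalled"
    }
    xs <- best$x
    gaprel <- best$gap
  } else {
    xs <- x / tau
  }
  # undo b/c normalization and equilibration; drop upper-bound slacks
  xout <- xs * Csc * bscale
  list(x = xout[seq_len(n - length(U))],
       status = status, iterations = it, gap = gaprel)
}

rowmax_abs <- function(A) {
  T <- Matrix::mat2triplet(A)
  out <- numeric(nrow(A))
  if (length(T$i)) {
    agg <- tapply(abs(T$x), T$i, max)
    out[as.integer(names(agg))] <- agg
  }
  out[out == 0] <- 1
  out
}
rowmin_abs <- function(A) {
  T <- Matrix::mat2triplet(A)
  out <- rep(1, nrow(A))
  if (length(T$i)) {
    agg <- tapply(abs(T$x), T$i, min)
    out[as.integer(names(agg))] <- agg
  }
  out
}
colmax_abs <- function(A) rowmax_abs(Matrix::t(A))
colmin_abs <- function(A) rowmin_abs(Matrix::t(A))

`%||%` <- function(a, b) if (is.null(a)) b else a
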