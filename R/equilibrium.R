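# Ecological equilibria of the coarse-grained relative-abundance dynamics
#
#   df_mu/dt = f_mu [ sum_i r_mu,i h_i(f) - 1 ],   h_i = kappa_i / sum_mu r_mu,i f_mu
#
# The uninvadable equilibrium is the maximizer of the strictly concave
# potential Phi(f) = sum_i kappa_i log(sum_mu r_mu,i f_mu) - sum_mu f_mu over
# f >= 0, whose gradient is exactly the vector of per-capita growth rates.
# Phi is a Lyapunov function of the dynamics, so the maximizer is the
# uninvadable state and self-normalizes (sum f = 1 at the optimum).  We find
# it by a multiplicative (replicator/EM-like) ascent with trust-region
# over-relaxation to prune the bulk of the excluded strains, then an
# active-set Newton polish that drives the KKT residuals to machine
# precision, with re-admission of any excluded strain that still violates
# the non-invasibility certificate.

# Canonical form: uptake matrix restricted to consumed resources.
# Resources consumed by no pool member have undefined availability and are
# dropped from the bookkeeping, with kappa renormalized over the remainder
# (equivalent to removing those resources from the environment).
cr_canonical <- function(pool, env, warn = TRUE) {
  stopifnot(pool$R == env$R)
  r <- pool_uptake(pool)
  consumed <- colSums(r) > 0
  if (!all(consumed)) {
    if (warn) warning(sprintf("%d resource(s) consumed by no strain; dropped",
                              sum(!consumed)))
    r <- r[, consumed, drop = FALSE]
  }
  kappa <- env$kappa[consumed]
  list(r = r, kappa = kappa / sum(kappa), consumed = consumed)
}

#' Per-capita growth rates of the coarse-grained dynamics
#'
#' Evaluates `sum_i r_mu,i h_i(f) - 1` for every strain in the pool
#' (including zero-abundance strains, which is how invasibility is checked).
#' Resource availabilities are `h_i = kappa_i / c_i` with
#' `c_i = sum_mu r_mu,i f_mu`.
#'
#' @param f Abundance vector over the pool (non-negative).
#' @param pool A `cr_pool`.
#' @param env A `cr_env` with matching `R`.
#' @return Numeric vector of growth rates, one per strain.
#' @export
growth_rates <- function(f, pool, env) {
  can <- cr_canonical(pool, env, warn = FALSE)
  cc <- drop(crossprod(can$r, f))
  if (any(cc <= 0)) stop("resource with zero total consumption at this f")
  drop(can$r %*% (can$kappa / cc)) - 1
}

# Multiplicative ascent with trust-region over-relaxation.
# f' = f * exp(beta * log W), W_mu = growth + 1; beta = 1 is the monotone
# replicator/EM step.  beta grows while Phi keeps increasing and shrinks on
# failure.  Strains are pruned to hard zero once negligible (protecting the
# last consumer of every resource); pruned strains are re-checked later
# against the KKT certificate, so aggressive pruning cannot corrupt the
# final state.  Stops on a growth-residual criterion over non-negligible
# strains, on a stall of Phi, or at max_iter; classification is finished by
# the Newton phase either way.
ascent_phase <- function(r, kappa, f0, max_iter = 3000L, beta_max = 500,
                         rtol = 1e-8) {
  S <- nrow(r)
  active <- seq_len(S)
  ra <- r; fa <- f0
  cc <- drop(crossprod(ra, fa))
  phi <- sum(kappa * log(cc)) - sum(fa)
  beta <- 1
  win <- 60L
  phi_hist <- rep(-Inf, win)
  for (it in seq_len(max_iter)) {
    lw <- log(drop(ra %*% (kappa / cc)))
    live <- fa > 1e-9 * sum(fa)
    if ((if (any(live)) max(abs(lw[live])) else 0) < rtol) break
    f_new <- fa * exp(pmin(pmax(beta * lw, -50), 50))
    c_new <- drop(crossprod(ra, f_new))
    phi_new <- sum(kappa * log(c_new)) - sum(f_new)
    if (phi_new >= phi - 1e-11 * max(1, abs(phi))) {
      fa <- f_new; cc <- c_new; phi <- phi_new
      beta <- min(beta_max, beta * 1.4)
    } else {
      beta <- max(1, beta / 4)
    }
    k <- it %% win + 1L
    if (it > 2L * win && phi - phi_hist[k] < 3e-11 * max(1, abs(phi))) break
    phi_hist[k] <- phi
    if (it %% 10L == 0L && length(active) > 1L) {
      thr <- if (it > 150L) 1e-10 * sum(fa) else 1e-14
      tiny <- fa < thr
      if (any(tiny)) {
        keep <- !tiny
        cons <- drop(crossprod((ra > 0) + 0, keep + 0))
        if (any(cons == 0)) { # never prune the sole consumer of a resource
          for (i in which(cons == 0)) {
            cand <- which(ra[, i] > 0)
            keep[cand[which.max(fa[cand])]] <- TRUE
          }
        }
        if (!all(keep)) {
          active <- active[keep]
          ra <- ra[keep, , drop = FALSE]
          fa <- fa[keep]
          cc <- drop(crossprod(ra, fa))
        }
      }
    }
  }
  f <- numeric(S)
  f[active] <- fa
  list(f = f, iters = it)
}

# Active-set Newton on the survivor stationarity system
# G_mu(f) = sum_i kappa_i r_mu,i / c_i - 1 = 0.  The Newton direction is an
# ascent direction of the (strictly concave) potential, so each step is an
# Armijo line search on Phi, truncated at the first boundary hit; a strain
# pinned at the boundary is removed (one event at a time) and the solve
# continues on the reduced set.
newton_polish <- function(r, kappa, active, f_active,
                          gtol = 1e-12, max_it = 1500L) {
  B <- r[active, , drop = FALSE]
  fA <- pmax(f_active, 1e-14)
  cc <- drop(crossprod(B, fA))
  phi <- sum(kappa * log(cc)) - sum(fA)
  gmax <- Inf
  for (it in seq_len(max_it)) {
    G <- drop(B %*% (kappa / cc)) - 1
    gmax <- max(abs(G))
    if (gmax < gtol) break
    w <- kappa / cc^2
    Bs <- B * rep(sqrt(w), each = nrow(B))
    Jp <- tcrossprod(Bs) # negative of the Hessian, positive semidefinite
    dJ <- pmax(diag(Jp), 1e-300)
    lam <- 0
    accepted <- FALSE
    for (attempt in seq_len(10L)) {
      delta <- tryCatch(
        drop(solve(Jp + if (lam > 0) diag(lam * dJ, nrow(Jp)) else 0, G)),
        error = function(e) NULL)
      if (is.null(delta) || (slope <- sum(G * delta)) <= 0) {
        lam <- max(lam * 100, 1e-10)
        next
      }
      neg <- delta < 0 & fA + delta < 0
      tmax <- if (any(neg)) min(fA[neg] / (-delta[neg])) else Inf
      if (tmax < 1e-12) {
        # a strain is pinned at the boundary with an outward direction:
        # remove it from the active set and restart the iteration
        jn <- which(neg)[which.min(fA[neg] / (-delta[neg]))]
        keep <- seq_along(fA) != jn
        if (!any(keep)) stop("Newton polish lost all strains")
        active <- active[keep]
        fA <- fA[keep]
        B <- B[keep, , drop = FALSE]
        cc <- drop(crossprod(B, fA))
        phi <- sum(kappa * log(cc)) - sum(fA)
        f_try <- fA
        at_bound <- logical(length(fA))
        accepted <- TRUE # treat as a (zero-length) boundary step
        break
      }
      tstep <- min(1, tmax)
      while (tstep > 1e-13) {
        f_try <- fA + tstep * delta
        at_bound <- f_try <= 0
        f_try[at_bound] <- 0
        c_try <- drop(crossprod(B, f_try))
        if (all(c_try > 0)) {
          phi_try <- sum(kappa * log(c_try)) - sum(f_try)
          if (phi_try >= phi + 1e-4 * tstep * slope ||
              phi_try >= phi - 1e-15 * abs(phi)) {
            accepted <- TRUE
            break
          }
        }
        tstep <- tstep / 2
      }
      if (accepted) break
      lam <- max(lam * 100, 1e-10) # damp toward (scaled) gradient ascent
    }
    if (!accepted) break # cannot make progress; report current residual
    fA <- f_try
    if (any(at_bound)) {
      keep <- !at_bound
      if (!any(keep)) stop("Newton polish lost all strains")
      active <- active[keep]
      fA <- fA[keep]
      B <- B[keep, , drop = FALSE]
    }
    cc <- drop(crossprod(B, fA))
    phi <- sum(kappa * log(cc)) - sum(fA)
  }
  f <- numeric(nrow(r))
  f[active] <- fA
  list(f = f, active = active, gmax = gmax)
}

# Basic-solution reduction for degenerate optima: given the optimal
# consumption vector cstar, find f >= 0 with t(r) f = cstar supported on at
# most length(cstar) strains (Lawson-Hanson NNLS, which terminates at a
# basic feasible point since the residual is zero at the optimum).
nnls_basic <- function(r, cstar) {
  A <- t(r) # R x S
  S <- ncol(A)
  f <- numeric(S)
  P <- logical(S)
  resid <- cstar
  tol <- 1e-10 * max(abs(cstar))
  for (iter in seq_len(10L * nrow(A))) {
    w <- drop(crossprod(A, resid))
    w[P] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol) break
    P[j] <- TRUE
    repeat {
      idx <- which(P)
      z <- qr.coef(qr(A[, idx, drop = FALSE]), cstar)
      z[is.na(z)] <- 0
      if (all(z > 0)) { f[] <- 0; f[idx] <- z; break }
      fP <- f[idx]
      bad <- z <= 0
      alpha <- min(fP[bad] / (fP[bad] - z[bad]))
      f[idx] <- fP + alpha * (z - fP)
      P[f < 1e-14] <- FALSE
      f[!P] <- 0
    }
    resid <- cstar - drop(A %*% f)
    if (max(abs(resid)) < tol) break
  }
  f
}

#' Uninvadable ecological equilibrium of a species pool
#'
#' Computes a maximizer of the concave potential
#' `Phi(f) = sum_i kappa_i log(sum_mu r_mu,i f_mu) - sum_mu f_mu` over
#' `f >= 0`.  The stationarity conditions are exactly the survivor /
#' exclusion conditions of the dynamics: survivors have zero growth rate,
#' excluded strains have non-positive growth rate (non-invasibility), and
#' the abundances self-normalize to `sum f = 1`.  After the multiplicative
#' ascent converges, the survivor set is polished by an active-set Newton
#' solve, excluded strains whose growth rate exceeds the tolerance are
#' re-admitted, and the final KKT residuals are certified over the full
#' pool.  If the optimum is degenerate in the strong sense that more strains
#' than resources are marginal (e.g. all budgets identical under uniform
#' supply), the reported abundances are reduced to a basic optimal solution
#' with at most `R` survivors and the state is flagged degenerate.
#'
#' @param pool A `cr_pool`.
#' @param env A `cr_env` with the same number of resources.  Resources
#'   consumed by no pool member are dropped from the availability
#'   bookkeeping with a warning.
#' @param tol Tolerance on the KKT residuals (default `1e-10`).
#' @param f0 Optional warm-start abundance vector (length `S`); warm starts
#'   from a nearby equilibrium speed up sequential invasions considerably.
#' @param max_iter Iteration cap for the ascent phase.
#' @return An object of class `cr_state`: list with fields `pool`, `env`,
#'   `f` (abundances over the pool, zeros for excluded strains),
#'   `survivors` (integer indices), `h`, `g`, `h_bar` (availabilities,
#'   excess availabilities `g_i = h_i/h_bar - 1` and the mean availability,
#'   `NA` for dropped resources), `consumed` (logical mask over resources),
#'   `residuals` (max survivor |growth| and max excluded growth),
#'   `degenerate` flag, and `tol`.
#' @export
#' @examples
#' env <- make_environment(4, "uniform")
#' pool <- sample_pool(4, 2, 6, 0.1, seed = 1)
#' st <- compute_equilibrium(pool, env)
#' sum(st$f)
compute_equilibrium <- function(pool, env, tol = 1e-10, f0 = NULL,
                                max_iter = 3000L) {
  can <- cr_canonical(pool, env)
  r <- can$r; kappa <- can$kappa
  S <- pool$S
  if (S < 1) stop("pool is empty")
  if (is.null(f0)) f0 <- rep(1 / S, S)
  f0 <- pmax(f0, 1e-12)

  asc <- ascent_phase(r, kappa, f0, max_iter = max_iter)
  f <- asc$f
  active <- which(f / sum(f) > 1e-10)
  if (length(active) == 0L) active <- which.max(f)

  kkt_tol <- max(tol, 1e-12)
  growth <- NULL
  for (round in seq_len(25L)) {
    np <- newton_polish(r, kappa, active, f[active])
    if (np$gmax > max(kkt_tol, 1e-9) && round < 25L) {
      # polish stalled (near-degenerate bulk): push the whole pool through
      # the monotone ascent again from the polished point and retry
      f_all <- pmax(np$f, 1e-12)
      asc2 <- ascent_phase(r, kappa, f_all, max_iter = 1500L)
      f <- asc2$f
      active <- which(f / sum(f) > 1e-10)
      if (length(active) == 0L) active <- which.max(f)
      next
    }
    f <- np$f; active <- np$active
    cc <- drop(crossprod(r, f))
    growth <- drop(r %*% (kappa / cc)) - 1
    excl <- setdiff(seq_len(S), active)
    viol <- excl[growth[excl] > kkt_tol]
    if (length(viol) == 0L) break
    # re-admit all violators at small abundance and let the monotone
    # ascent sort out who establishes before polishing again (polishing
    # directly from such a warm start can drop newcomers prematurely)
    sub <- sort(c(active, viol))
    f_sub <- pmax(f[sub], 1e-8)
    asc2 <- ascent_phase(r[sub, , drop = FALSE], kappa, f_sub,
                         max_iter = 800L)
    f <- numeric(S)
    f[sub] <- asc2$f
    active <- which(f / sum(f) > 1e-10)
    if (length(active) == 0L) active <- which.max(f)
  }
  excl <- setdiff(seq_len(S), active)
  if (length(excl) > 0 && any(growth[excl] > kkt_tol)) {
    stop("equilibrium solver failed the non-invasibility certificate; ",
         "max excluded growth = ", max(growth[excl]))
  }
  if (max(abs(growth[active])) > max(kkt_tol, 1e-9)) {
    stop("equilibrium solver did not reach the requested KKT tolerance; ",
         "max survivor |growth| = ", max(abs(growth[active])))
  }

  degenerate <- length(excl) > 0 && any(growth[excl] > -kkt_tol)
  if (length(active) > ncol(r)) {
    # strongly degenerate optimum: reduce to a basic solution over c*
    f <- nnls_basic(r, cc)
    f <- f / sum(f) * sum(np$f)
    active <- which(f > 0)
    cc <- drop(crossprod(r, f))
    degenerate <- TRUE
  }

  h <- rep(NA_real_, env$R)
  h[can$consumed] <- kappa / cc
  h_bar <- mean(h[can$consumed])
  g <- h / h_bar - 1
  structure(list(
    pool = pool, env = env, f = f, survivors = active,
    h = h, g = g, h_bar = h_bar, consumed = can$consumed,
    residuals = c(survivor = max(abs(growth[active])),
                  excluded = if (length(excl)) max(growth[excl]) else -Inf),
    degenerate = degenerate, tol = tol
  ), class = "cr_state")
}

#' @export
print.cr_state <- function(x, ...) {
  cat(sprintf(
    "<cr_state> %d / %d survivors on %d resources (S*/R = %.3f)%s\n",
    length(x$survivors), x$pool$S, sum(x$consumed),
    length(x$survivors) / sum(x$consumed),
    if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  KKT residuals: survivor %.2e, excluded %.2e\n",
              x$residuals[["survivor"]], x$residuals[["excluded"]]))
  invisible(x)
}

#' Integrate the relative-abundance dynamics (validation oracle)
#'
#' Numerically integrates `df_mu/dt = f_mu [sum_i r_mu,i h_i(f) - 1]` with
#' [deSolve::ode()] (`lsoda`).  This is the independent dynamical oracle
#' used to cross-validate [compute_equilibrium()]: from any strictly
#' positive start the trajectory converges to the uninvadable state.
#'
#' @param pool A `cr_pool`.
#' @param env A `cr_env`.
#' @param f0 Strictly positive initial abundances (length `S`).  Need not be
#'   normalized; the dynamics self-normalize.
#' @param t_max Final time (generations).
#' @param tol Integrator relative tolerance (absolute tolerance is
#'   `max(tol^1.5, 1e-300)`).
#' @param n_out Number of output times (log-spaced).
#' @return A matrix with columns `time` and one abundance column per strain.
#' @export
integrate_dynamics <- function(pool, env, f0, t_max = 1e4, tol = 1e-10,
                               n_out = 60L) {
  if (length(f0) != pool$S || any(f0 <= 0)) {
    stop("f0 must be strictly positive on all pool members")
  }
  can <- cr_canonical(pool, env)
  r <- can$r; kappa <- can$kappa
  deriv <- function(t, f, parms) {
    f <- pmax(f, 0)
    cc <- drop(crossprod(r, f))
    if (any(cc <= 0)) stop("resource availability diverged during integration")
    list(f * (drop(r %*% (kappa / cc)) - 1))
  }
  times <- unique(c(0, exp(seq(log(1e-2), log(t_max), length.out = n_out))))
  out <- deSolve::ode(y = f0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = tol,
                      atol = max(tol^1.5, 1e-300))
  if (any(is.na(out))) stop("integration failed (NA in trajectory)")
  colnames(out) <- c("time", pool$id)
  out
}

#' Concave potential of the dynamics
#'
#' `Phi(f) = sum_i kappa_i log(sum_mu r_mu,i f_mu) - sum_mu f_mu`, the
#' Lyapunov function maximized at the uninvadable equilibrium.
#'
#' @inheritParams growth_rates
#' @return Scalar potential value.
#' @export
community_potential <- function(f, pool, env) {
  can <- cr_canonical(pool, env, warn = FALSE)
  cc <- drop(crossprod(can$r, f))
  sum(can$kappa * log(cc)) - sum(f)
}

#' Restrict a state to its survivors
#'
#' Returns the same equilibrium with the pool sliced down to the surviving
#' strains.  Excluded strains have zero abundance and contribute nothing to
#' the resource balance, so all availabilities carry over unchanged.
#'
#' @param state A `cr_state`.
#' @return A `cr_state` whose pool contains only the survivors.
#' @export
subset_state <- function(state) {
  surv <- state$survivors
  out <- state
  out$pool <- state$pool[surv]
  out$f <- state$f[surv]
  out$survivors <- seq_along(surv)
  out
}

#' Assemble a community from scratch
#'
#' Convenience wrapper: sample a pool, then compute its uninvadable
#' equilibrium.
#'
#' @inheritParams sample_pool
#' @param env A `cr_env`.
#' @param tol KKT tolerance passed to [compute_equilibrium()].
#' @return A `cr_state`.
#' @export
assemble_community <- function(R, R0, S, std_X, env, scheme = "binary",
                               seed = NULL, tol = 1e-10) {
  pool <- sample_pool(R, R0, S, std_X, scheme = scheme, seed = seed)
  compute_equilibrium(pool, env, tol = tol)
}
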