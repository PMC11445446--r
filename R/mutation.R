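# Mutant phenotypes and invasion fitness.
#
# A mutation changes a parent strain's phenotype (X, alpha) to
# (X + dX, alpha + d_alpha) with d_alpha summing to zero.  Knock-outs zero
# one used resource and renormalize; knock-ins grant an unused resource a
# share equal to the mean share of currently used resources (so a
# binary-equal-share parent stays equal-share on the enlarged support, and
# ||d_alpha|| ~ 1/R0 for both kinds).  Invasion fitness is the initial
# per-capita growth rate of the rare mutant at the unperturbed resident
# equilibrium; the mean-field approximation s ~ dX + sum_i d_alpha_i g_i is
# reported alongside the exact value.

new_mutation <- function(parent_id, parent_index, kind, target, dX,
                         alpha_new, X_new, d_alpha) {
  structure(list(
    parent_id = parent_id, parent_index = parent_index, kind = kind,
    target = target, dX = dX, alpha_new = alpha_new, X_new = X_new,
    d_alpha = d_alpha, norm_d_alpha = sqrt(sum(d_alpha^2))
  ), class = "cr_mutation")
}

#' @export
print.cr_mutation <- function(x, ...) {
  cat(sprintf("<cr_mutation> %s of parent %s%s, dX = %g, ||d_alpha|| = %.4g\n",
              x$kind, x$parent_id,
              if (!is.null(x$target) && !is.na(x$target))
                sprintf(" (resource %d)", x$target) else "",
              x$dX, x$norm_d_alpha))
  invisible(x)
}

resolve_parent <- function(pool, parent) {
  if (is.character(parent)) {
    idx <- match(parent, pool$id)
    if (is.na(idx)) stop("parent strain '", parent, "' not in pool")
  } else {
    idx <- as.integer(parent)
    if (idx < 1 || idx > pool$S) stop("parent index out of range")
  }
  idx
}

#' Construct a knock-out mutation
#'
#' The mutant loses the ability to consume resource `target` (its strategy
#' share is zeroed and the remaining shares are renormalized to sum to one),
#' optionally with a direct budget change `dX`.
#'
#' @param pool A `cr_pool`.
#' @param parent Strain index or id.
#' @param target Resource index; must be used by the parent.
#' @param dX Budget change (log uptake, default 0 = perfect trade-off).
#' @return A `cr_mutation`.
#' @export
#' @examples
#' pool <- sample_pool(10, 4, 3, 0, seed = 1)
#' mut <- knockout(pool, 1, which(pool$alpha[1, ] > 0)[1])
#' sum(mut$alpha_new)
knockout <- function(pool, parent, target, dX = 0) {
  idx <- resolve_parent(pool, parent)
  a <- pool$alpha[idx, ]
  if (a[target] <= 0) stop("knock-out target is not used by the parent")
  if (sum(a > 0) < 2) stop("cannot knock out the parent's last used resource")
  a_new <- a
  a_new[target] <- 0
  a_new <- a_new / sum(a_new)
  new_mutation(pool$id[idx], idx, "knockout", as.integer(target), dX,
               a_new, pool$X[idx] + dX, a_new - a)
}

#' Construct a knock-in mutation
#'
#' The mutant gains the ability to consume resource `target` (currently
#' unused by the parent).  The new resource receives a strategy share equal
#' to the mean share of the currently used resources, and all shares are
#' renormalized; for a parent with `k` used resources the new strategy is
#' `(k * alpha + e_target) / (k + 1)`.
#'
#' @inheritParams knockout
#' @return A `cr_mutation`.
#' @export
knockin <- function(pool, parent, target, dX = 0) {
  idx <- resolve_parent(pool, parent)
  a <- pool$alpha[idx, ]
  if (a[target] > 0) stop("knock-in target is already used by the parent")
  k <- sum(a > 0)
  if (k >= pool$R) stop("parent already uses all resources")
  a_new <- k * a
  a_new[target] <- 1
  a_new <- a_new / (k + 1)
  new_mutation(pool$id[idx], idx, "knockin", as.integer(target), dX,
               a_new, pool$X[idx] + dX, a_new - a)
}

#' Construct a general multi-resource (or budget-only) mutation
#'
#' Takes a user-supplied strategy change `d_alpha` (summing to zero) and a
#' budget change `dX`.  A zero `d_alpha` gives a pure budget mutation.
#'
#' @inheritParams knockout
#' @param d_alpha Length-`R` strategy change, `sum(d_alpha) = 0` and
#'   `alpha + d_alpha >= 0`.
#' @param dX Budget change.
#' @param tol Feasibility tolerance.
#' @return A `cr_mutation` with kind `"multi"` (or `"budget_only"` if
#'   `d_alpha` is identically zero).
#' @export
multi_mutation <- function(pool, parent, d_alpha, dX = 0, tol = 1e-9) {
  idx <- resolve_parent(pool, parent)
  if (length(d_alpha) != pool$R) stop("d_alpha must have length R")
  if (abs(sum(d_alpha)) > tol) stop("d_alpha must sum to zero")
  a_new <- pool$alpha[idx, ] + d_alpha
  if (any(a_new < -tol)) stop("d_alpha drives some strategy share negative")
  a_new <- pmax(a_new, 0)
  a_new <- a_new / sum(a_new)
  kind <- if (all(d_alpha == 0)) "budget_only" else "multi"
  new_mutation(pool$id[idx], idx, kind, NA_integer_, dX, a_new,
               pool$X[idx] + dX, a_new - pool$alpha[idx, ])
}

#' Random multi-resource mutation of prescribed magnitude
#'
#' Draws a random strategy perturbation supported on the parent's used
#' resources, projected to the sum-zero hyperplane and scaled to
#' `||d_alpha|| = norm`; directions that would make a share negative are
#' resampled.  Used to compare multi-resource mutations against knock-outs
#' with matched phenotypic effect size.
#'
#' @inheritParams knockout
#' @param norm Target Euclidean norm of `d_alpha`.
#' @param max_tries Resampling cap.
#' @return A `cr_mutation` of kind `"multi"`.
#' @export
random_multi_mutation <- function(pool, parent, norm, dX = 0,
                                  max_tries = 200L) {
  idx <- resolve_parent(pool, parent)
  a <- pool$alpha[idx, ]
  supp <- which(a > 0)
  if (length(supp) < 2) stop("parent must use at least 2 resources")
  for (i in seq_len(max_tries)) {
    z <- stats::rnorm(length(supp))
    z <- z - mean(z)
    nz <- sqrt(sum(z^2))
    if (nz == 0) next
    d <- numeric(pool$R)
    d[supp] <- z / nz * norm
    if (all(a + d >= 0)) return(multi_mutation(pool, idx, d, dX))
  }
  stop("could not sample a feasible d_alpha of the requested norm")
}

#' Invasion fitness of a mutation in a resident community
#'
#' The exact invasion fitness is the initial per-capita growth rate of the
#' rare mutant at the unperturbed resident equilibrium,
#' `s_exact = exp(X + dX) * sum_i (alpha + d_alpha)_i h_i - 1`.  The
#' mean-field approximation `s_approx = dX + sum_i d_alpha_i g_i` is
#' returned alongside.  The parent must be a survivor, and every resource
#' in the mutant's support must have at least one current consumer
#' (otherwise its availability is undefined in the coarse-grained model).
#'
#' @param state A `cr_state`.
#' @param mut A `cr_mutation` built from the state's pool.
#' @return List with `s_exact` and `s_approx`.
#' @export
invasion_fitness <- function(state, mut) {
  if (!(mut$parent_index %in% state$survivors)) {
    stop("mutation parent is not a survivor in this state")
  }
  supp_new <- mut$alpha_new > 0
  if (any(supp_new & !state$consumed)) {
    stop("mutant uses a resource with no current consumer; ",
         "availability undefined")
  }
  h <- state$h
  s_exact <- exp(mut$X_new) * sum(mut$alpha_new[supp_new] * h[supp_new]) - 1
  s_approx <- mut$dX + sum(mut$d_alpha[state$consumed] * state$g[state$consumed])
  list(s_exact = s_exact, s_approx = s_approx)
}

#' Fitness effect of a mutation in monoculture
#'
#' Equilibrates the parent alone (its monoculture availabilities are
#' `h_i = kappa_i / r_i` on its support), and evaluates the mean-field
#' fitness `dX + sum_i d_alpha_i g_i` with the monoculture excess
#' availabilities.  Only mutations supported within the parent's support
#' (knock-outs, budget shifts, within-support multi mutations) have a
#' defined monoculture fitness; knock-ins do not, because the availability
#' of a resource the monoculture does not consume is undefined.
#'
#' @param pool A `cr_pool` containing the parent.
#' @param env A `cr_env`.
#' @param mut A `cr_mutation`.
#' @return Scalar `s_mono`.
#' @export
monoculture_fitness <- function(pool, env, mut) {
  if (mut$kind == "knockin") stop("monoculture fitness undefined for knock-ins")
  idx <- mut$parent_index
  a <- pool$alpha[idx, ]
  supp <- a > 0
  if (any(mut$d_alpha != 0 & !supp)) {
    stop("mutation changes a resource outside the parent's support")
  }
  h <- env$kappa[supp] / (exp(pool$X[idx]) * a[supp])
  g <- h / mean(h) - 1
  mut$dX + sum(mut$d_alpha[supp] * g)
}

#' Enumerate the local distribution of fitness effects
#'
#' Enumerates every single-resource mutation of every survivor, unweighted:
#' all knock-outs of used resources (skipping single-resource parents), and,
#' when requested, all knock-ins of unused resources that currently have at
#' least one consumer.  Both the exact and approximate invasion fitness are
#' computed, along with the monoculture fitness where defined.
#'
#' @param state A `cr_state`.
#' @param kinds Character subset of `c("knockout", "knockin")`.
#' @param dX Budget change applied to every mutation.
#' @param monoculture Also compute the monoculture fitness column
#'   (knock-outs only; `NA` for knock-ins).
#' @return A data frame with columns `parent_id`, `parent_index`, `f_parent`,
#'   `kind`, `target`, `dX`, `s_exact`, `s_approx`, `s_mono`,
#'   `norm_d_alpha`, and `support_size`.
#' @export
enumerate_dfe <- function(state, kinds = "knockout", dX = 0,
                          monoculture = FALSE) {
  kinds <- match.arg(kinds, c("knockout", "knockin"), several.ok = TRUE)
  pool <- state$pool
  surv <- state$survivors
  h <- state$h
  g <- state$g
  A <- pool$alpha[surv, , drop = FALSE]
  eX <- exp(pool$X[surv])
  # E_mu = exp(X) sum_j alpha_j h_j = 1 + growth (exactly 1 for survivors up
  # to the KKT residual); keep the computed value for exactness.
  hh <- ifelse(is.na(h), 0, h)
  E <- eX * drop(A %*% hh)
  Ag <- drop(A %*% ifelse(is.na(g), 0, g)) # sum_j alpha_j g_j
  Q <- rowSums(A^2)
  ksupp <- rowSums(A > 0)
  fsurv <- state$f[surv]

  if (monoculture) {
    gm_target <- matrix(NA_real_, length(surv), pool$R)
    Agm <- numeric(length(surv))
    for (m in seq_along(surv)) {
      a <- A[m, ]
      sp <- a > 0
      hm <- state$env$kappa[sp] / (eX[m] * a[sp])
      gm <- hm / mean(hm) - 1
      gm_target[m, sp] <- gm
      Agm[m] <- sum(a[sp] * gm)
    }
  }

  blocks <- list()
  if ("knockout" %in% kinds) {
    idx <- which(A > 0 & ksupp >= 2, arr.ind = TRUE) # (survivor row, resource)
    if (nrow(idx) > 0) {
      m <- idx[, 1]; i <- idx[, 2]
      am <- A[idx]
      u <- eX[m] * am * hh[i]
      s_exact <- exp(dX) * (E[m] - u) / (1 - am) - 1
      s_approx <- dX + am / (1 - am) * (Ag[m] - g[i])
      nrm <- am * sqrt(pmax(Q[m] - am^2, 0) / (1 - am)^2 + 1)
      s_mono <- if (monoculture) {
        dX + am / (1 - am) * (Agm[m] - gm_target[cbind(m, i)])
      } else NA_real_
      blocks$knockout <- data.frame(
        parent_id = pool$id[surv][m], parent_index = surv[m],
        f_parent = fsurv[m], kind = "knockout", target = i, dX = dX,
        s_exact = s_exact, s_approx = s_approx, s_mono = s_mono,
        norm_d_alpha = nrm, support_size = ksupp[m],
        stringsAsFactors = FALSE)
    }
  }
  if ("knockin" %in% kinds) {
    eligible <- (A == 0) & matrix(state$consumed, length(surv), pool$R,
                                  byrow = TRUE)
    idx <- which(eligible, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      m <- idx[, 1]; i <- idx[, 2]
      k <- ksupp[m]
      s_exact <- exp(dX) * (k * E[m] + eX[m] * hh[i]) / (k + 1) - 1
      s_approx <- dX + (g[i] - Ag[m]) / (k + 1)
      nrm <- sqrt(1 + Q[m]) / (k + 1)
      blocks$knockin <- data.frame(
        parent_id = pool$id[surv][m], parent_index = surv[m],
        f_parent = fsurv[m], kind = "knockin", target = i, dX = dX,
        s_exact = s_exact, s_approx = s_approx, s_mono = NA_real_,
        norm_d_alpha = nrm, support_size = k,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  if (is.null(out)) {
    out <- data.frame(parent_id = character(), parent_index = integer(),
                      f_parent = numeric(), kind = character(),
                      target = integer(), dX = numeric(),
                      s_exact = numeric(), s_approx = numeric(),
                      s_mono = numeric(), norm_d_alpha = numeric(),
                      support_size = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarize a distribution of fitness effects
#'
#' @param dfe A data frame from [enumerate_dfe()] (or several, row-bound).
#' @param column Which fitness column to summarize (default `s_exact`).
#' @return List with `n`, `mean_hat`, `sigma_hat` (sample SD),
#'   `beneficial_fraction`, and `excess_kurtosis`.
#' @export
dfe_summary <- function(dfe, column = "s_exact") {
  s <- dfe[[column]]
  s <- s[is.finite(s)]
  n <- length(s)
  mu <- mean(s)
  sd_ <- stats::sd(s)
  kurt <- if (n > 3 && sd_ > 0) mean((s - mu)^4) / mean((s - mu)^2)^2 - 3
          else NA_real_
  list(n = n, mean_hat = mu, sigma_hat = sd_,
       beneficial_fraction = mean(s > 0), excess_kurtosis = kurt)
}

#' Correlation between community and monoculture fitness effects
#'
#' Pools all enumerated knock-out mutations across replicate states and
#' returns the Pearson correlation between the invasion fitness in the
#' community and the fitness effect of the same mutation in monoculture.
#' Under uniform resource supply the monoculture fitness of every knock-out
#' is identically `dX` (zero variance), in which case the correlation is
#' reported as 0 with a degeneracy flag rather than `NaN`.
#'
#' @param states A `cr_state` or list of them.
#' @param kinds Mutation kinds (knock-outs only have monoculture fitness).
#' @param dX Budget change.
#' @return List with `r`, `n`, and `degenerate`.
#' @export
dfe_correlation <- function(states, kinds = "knockout", dX = 0) {
  if (inherits(states, "cr_state")) states <- list(states)
  tabs <- lapply(states, enumerate_dfe, kinds = kinds, dX = dX,
                 monoculture = TRUE)
  tab <- do.call(rbind, tabs)
  tab <- tab[is.finite(tab$s_mono), ]
  if (nrow(tab) < 2) stop("fewer than 2 mutations with defined s_mono")
  v_mono <- stats::var(tab$s_mono)
  v_comm <- stats::var(tab$s_exact)
  if (v_mono < 1e-24 || v_comm < 1e-24) {
    return(list(r = 0, n = nrow(tab), degenerate = TRUE))
  }
  list(r = stats::cor(tab$s_exact, tab$s_mono), n = nrow(tab),
       degenerate = FALSE)
}
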