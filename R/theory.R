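# Mean-field predictions for assembled communities and first-step mutations.
#
# In the regime R >~ R0 >> 1 with comparable supply rates, the excess
# resource availabilities of an assembled community behave like Gaussian
# random variables,
#
#   g_i ~ (1 - S*/R) [ K_i/Kbar - 1 + Z_i C (S*/R)^{-1/2} sqrt((1-R0/R)/R0) ],
#
# with C an order-one factor depending on the sampling depth S/S*.  All
# closed forms below follow from this: the DFE width sigma_inv, the
# coexistence threshold s_coex and probability P_coex, and the correlation
# between community and monoculture fitness effects.  The "~" relations are
# promoted to "=" by carrying C through every formula; C itself is
# calibrated once against simulated Std(g) (see calibrate_C) and recorded.

#' Bundle of mean-field community parameters
#'
#' @param R,R0 Resource count and per-strain usage.
#' @param S Pool size.
#' @param S_star Expected number of survivors.
#' @param C Order-one mean-field factor (from [calibrate_C()]; default 1).
#' @param env Optional `cr_env` (supplies `Var(K)/Kbar^2`).
#' @return A `cr_theory_params` list with `R`, `R0`, `S`, `S_star`,
#'   `niche_saturation`, `permissivity`, `C`, `cv2`, and `validity` flags
#'   (`comparable_supply`: supply variation is small; `dense_consumption`:
#'   each resource is used by many survivors, `R0 S* >> R`).
#' @export
theory_params <- function(R, R0, S, S_star, C = 1, env = NULL) {
  sat <- S_star / R
  if (sat <= 0 || sat > 1 + 1e-9) stop("S_star must be in (0, R]")
  if (C <= 0) stop("C must be positive")
  cv2 <- if (is.null(env)) 0 else env$cv2
  structure(list(
    R = R, R0 = R0, S = S, S_star = S_star,
    niche_saturation = min(sat, 1), permissivity = S_star / S, C = C,
    cv2 = cv2,
    validity = c(comparable_supply = cv2 < 0.25,
                 dense_consumption = R0 * S_star > 5 * R)
  ), class = "cr_theory_params")
}

#' Predicted number of surviving species (simulation surrogate)
#'
#' Expected survivor count `S*` for a pool of `S` strains with budget
#' spread `std_X`.  The self-consistent mean-field solution for the
#' assembled state is replaced here by a direct Monte-Carlo surrogate:
#' `n_rep` pilot assemblies are run and their mean survivor count returned
#' with a standard error; the output records that the surrogate path was
#' used.  The competitive-exclusion bound `S* <= R` always holds.
#'
#' @param S Pool size.
#' @param std_X Budget spread.
#' @param R,R0 Pool dimensions.
#' @param env A `cr_env`.
#' @param n_rep Pilot replicates.
#' @param seed Seed.
#' @param scheme Sampling scheme.
#' @return List with `S_star`, `se`, `n_rep`, `path`, and `validity` flag
#'   (regime `R >= R0 >> 1`).
#' @export
predict_survivors <- function(S, std_X, R, R0, env, n_rep = 20L, seed = 1L,
                              scheme = "binary") {
  vals <- vapply(seq_len(n_rep), function(k) {
    st <- assemble_community(R, R0, S, std_X, env, scheme = scheme,
                             seed = derive_seed(seed, k))
    length(st$survivors)
  }, numeric(1))
  list(S_star = mean(vals), se = stats::sd(vals) / sqrt(n_rep),
       n_rep = n_rep, path = "monte-carlo-surrogate",
       validity = c(regime = R >= R0 && R0 >= 10))
}

#' Calibrate the order-one mean-field factor C
#'
#' Measures the spread of the excess availabilities `Std(g)` over pilot
#' assemblies at a single reference condition and returns the factor `C`
#' that makes the mean-field expression exact there:
#' `C = Std(g) / [(1 - S*/R) (S*/R)^{-1/2} sqrt((1 - R0/R)/R0)]`,
#' using the realized saturation.  `C` depends on the sampling depth
#' `S/S*`, so it should be calibrated at the permissivity of interest and
#' then held fixed; the returned object records the calibration condition.
#'
#' @param R,R0 Pool dimensions.
#' @param niche_saturation,permissivity Reference condition.
#' @param env A `cr_env` (uniform supply recommended for calibration).
#' @param n_rep Assemblies to average over.
#' @param seed Seed.
#' @return List with `C`, `std_g_sim`, `achieved_saturation`, `n_rep`, and
#'   `condition` metadata.
#' @export
calibrate_C <- function(R, R0, niche_saturation = 0.5, permissivity = 0.1,
                        env = NULL, n_rep = 30L, seed = 1L) {
  if (is.null(env)) env <- make_environment(R, "uniform")
  key <- paste("C", R, R0, niche_saturation, permissivity, signif(env$cv2, 8),
               n_rep, seed, sep = "|")
  if (!is.null(.crevo_cache[[key]])) return(.crevo_cache[[key]])
  cal <- calibrate_pool(niche_saturation, permissivity, R, R0, env,
                        n_rep = max(10L, n_rep %/% 2L), seed = seed)
  gs <- numeric(0)
  sats <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    st <- assemble_community(R, R0, cal$S, cal$std_X, env,
                             seed = derive_seed(seed, 5000L + k))
    gs <- c(gs, st$g[st$consumed])
    sats[k] <- length(st$survivors) / sum(st$consumed)
  }
  sat <- mean(sats)
  pred1 <- (1 - sat) * sat^(-0.5) * sqrt((1 - R0 / R) / R0) # C = 1 value
  res <- list(C = stats::sd(gs) / pred1, std_g_sim = stats::sd(gs),
              achieved_saturation = sat, n_rep = n_rep,
              condition = list(R = R, R0 = R0,
                               niche_saturation = niche_saturation,
                               permissivity = permissivity, seed = seed))
  .crevo_cache[[key]] <- res
  res
}

#' Mean-field statistics of the excess availabilities
#'
#' Per-resource mean and common standard deviation of `g_i`:
#' `mean_i = (1 - S*/R)(K_i/Kbar - 1)` and
#' `SD = (1 - S*/R) C (S*/R)^{-1/2} sqrt((1 - R0/R)/R0)`.
#'
#' @param params A `cr_theory_params`.
#' @param env A `cr_env`.
#' @return List with `mean` (length-R vector), `sd` (scalar), and
#'   `validity` flags (copied from `params`, with warnings raised outside
#'   the validity regime).
#' @export
g_statistics <- function(params, env) {
  sat <- params$niche_saturation
  if (!all(params$validity)) {
    warning("g statistics requested outside the mean-field validity regime")
  }
  list(mean = (1 - sat) * (env$K / mean(env$K) - 1),
       sd = (1 - sat) * params$C * sat^(-0.5) *
         sqrt((1 - params$R0 / params$R) / params$R0),
       validity = params$validity)
}

#' Predicted width of the distribution of fitness effects
#'
#' `sigma_inv = ||d_alpha|| (1 - S*/R) (S*/R)^{-1/2} sqrt((1-R0/R)/R0) C`:
#' under uniform supply and perfect trade-offs the DFE is Gaussian with
#' mean `dX` and this standard deviation.
#'
#' @param params A `cr_theory_params`.
#' @param norm_d_alpha Phenotypic effect size `||d_alpha||` (a single
#'   knock-out or knock-in has `||d_alpha|| ~ 1/R0`).
#' @param dX Mean of the DFE (budget change common to all mutations).
#' @return List with `sigma_inv`, `dfe` (a list with `mean`, `sd`, and
#'   density/quantile functions), and `validity`.
#' @export
predict_sigma_inv <- function(params, norm_d_alpha, dX = 0) {
  sat <- params$niche_saturation
  sigma <- norm_d_alpha * (1 - sat) * sat^(-0.5) *
    sqrt((1 - params$R0 / params$R) / params$R0) * params$C
  list(sigma_inv = sigma,
       dfe = list(mean = dX, sd = sigma,
                  density = function(s) stats::dnorm(s, dX, sigma),
                  quantile = function(p) stats::qnorm(p, dX, sigma)),
       validity = params$validity)
}

#' Community-wide strategy spread between random strain pairs
#'
#' `||d_alpha_comm||^2 ~ 2 (1 - R0/R) / R0`, the squared strategy distance
#' between random pairs of community members, against which the phenotypic
#' effect of a mutation is measured in the coexistence threshold.
#'
#' @param R,R0 Pool dimensions.
#' @return Scalar `||d_alpha_comm||^2`.
#' @export
norm_d_alpha_comm2 <- function(R, R0) 2 * (1 - R0 / R) / R0

#' Mean-field mutant-parent coexistence prediction
#'
#' Computes the coexistence threshold
#' `s_coex(f_P) = sigma_inv (f_P S*) (S*/R)^{-1/2} sqrt(2) ||d_alpha|| / ||d_alpha_comm||`,
#' the typical-background threshold `s_bar_coex` (`f_P = 1/S*`), and the
#' coexistence probability
#' `P_coex = Int_0^inf s rho(s) exp(-s/s_bar_coex) ds / Int_0^inf s rho(s) ds`
#' by numerical quadrature over the Gaussian DFE `rho` with mean `dX` and
#' SD `sigma_inv`.  For perfect trade-offs (`dX = 0`, and `s_bar_coex`
#' small against `sigma_inv`) the integral reduces to the closed form
#' `P_coex = (R/S*) 2 ||d_alpha||^2 / ||d_alpha_comm||^2`, which is also
#' returned, together with the budget-shift factor
#' `P_coex(dX) / P_coex(0)` in its three asymptotic regimes
#' (strongly beneficial: `(sigma/(sqrt(2 pi) dX)) exp(-dX^2/(2 sigma^2))`;
#' negligible: 1; strongly costly: `dX^2/sigma^2`).
#'
#' @param params A `cr_theory_params`.
#' @param norm_d_alpha Phenotypic effect size of the mutation.
#' @param dX Budget change.
#' @param rho Optional DFE density function (defaults to the Gaussian from
#'   [predict_sigma_inv()]).
#' @return A `cr_coex_prediction` list with `s_coex` (function of `f_P`),
#'   `s_bar_coex`, `P_coex` (quadrature), `P_coex_closed` (perfect
#'   trade-off closed form), `delta_X_factor`, `regime`, and `validity`.
#' @export
predict_coexistence <- function(params, norm_d_alpha, dX = 0, rho = NULL) {
  sat <- params$niche_saturation
  sig <- predict_sigma_inv(params, norm_d_alpha, dX)
  sigma <- sig$sigma_inv
  dac <- sqrt(norm_d_alpha_comm2(params$R, params$R0))
  s_coex <- function(f_P) {
    sigma * (f_P * params$S_star) * sat^(-0.5) * sqrt(2) * norm_d_alpha / dac
  }
  s_bar <- s_coex(1 / params$S_star)
  closed0 <- (1 / sat) * 2 * norm_d_alpha^2 / norm_d_alpha_comm2(params$R,
                                                                 params$R0)
  if (sigma == 0) {
    # fully saturated community: the DFE collapses and the quadrature is
    # taken in the limit, where it coincides with the closed form
    num <- closed0; den <- 1
  } else {
    if (is.null(rho)) rho <- function(s) stats::dnorm(s, dX, sigma)
    # integrate in units of the natural fitness scale so the quadrature
    # resolves arbitrarily narrow DFEs
    sc <- max(sigma, abs(dX), s_bar)
    num <- sc^2 * stats::integrate(
      function(u) u * rho(u * sc) * exp(-u * sc / s_bar), 0, Inf,
      rel.tol = 1e-10)$value
    den <- sc^2 * stats::integrate(function(u) u * rho(u * sc), 0, Inf,
                                   rel.tol = 1e-10)$value
    if (den <= 0) stop("DFE has no beneficial mass; P_coex undefined")
  }
  closed <- closed0
  ratio_dx <- abs(dX) / sigma
  if (dX > 0 && ratio_dx >= 1) {
    regime <- "strongly_beneficial"
    factor <- sigma / (sqrt(2 * pi) * dX) * exp(-dX^2 / (2 * sigma^2))
  } else if (dX < 0 && ratio_dx >= 1) {
    regime <- "strongly_costly"
    factor <- dX^2 / sigma^2
  } else {
    regime <- "negligible_budget_shift"
    factor <- 1
  }
  structure(list(
    s_coex = s_coex, s_bar_coex = s_bar, P_coex = num / den,
    P_coex_closed = closed, delta_X_factor = factor, regime = regime,
    sigma_inv = sigma, validity = sig$validity
  ), class = "cr_coex_prediction")
}

#' Predicted correlation between community and monoculture DFEs
#'
#' Decomposing the excess availabilities into their supply-driven and
#' community-noise components gives a Pearson correlation
#' `r = sqrt(y / (1 + y))` with
#' `y = (Var_env / Var_comm) (S*/R) / C^2`, where
#' `Var_env / Var_comm = (Var(K)/Kbar^2) R0 / (1 - R0/R)` is the scaled
#' variation in resource supply rates.  Uniform supply gives `r = 0`
#' (complete environmental shielding of the fitness landscape); `r -> 1`
#' when the supply variation dominates the community-generated variation.
#'
#' @param params A `cr_theory_params`.
#' @param env A `cr_env`.
#' @return List with `r`, `var_ratio` (`Var_env/Var_comm`), and
#'   `validity`.
#' @export
predict_dfe_correlation <- function(params, env) {
  var_ratio <- env$cv2 * params$R0 / (1 - params$R0 / params$R)
  y <- var_ratio * params$niche_saturation / params$C^2
  list(r = sqrt(y / (1 + y)), var_ratio = var_ratio,
       validity = params$validity)
}
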