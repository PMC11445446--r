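# Calibration of pool parameters to target community statistics.
#
# The community is classified by its niche saturation S*/R (fraction of
# resources "used up" by survivors) and sampling permissivity S*/S
# (fraction of the pool that survives assembly).  Pool size follows from
# the definitions, S = S*_target / permissivity; the budget spread std_X is
# the remaining knob and is found by a monotone search on pilot assemblies
# (S* decreases with std_X at fixed S).

.crevo_cache <- new.env(parent = emptyenv())

pilot_saturation <- function(R, R0, S, std_X, env, scheme, n_rep, seed,
                             probe_id = 0L) {
  sats <- vapply(seq_len(n_rep), function(k) {
    st <- assemble_community(R, R0, S, std_X, env, scheme = scheme,
                             seed = derive_seed(seed, probe_id * 10000L + k))
    length(st$survivors) / sum(st$consumed)
  }, numeric(1))
  mean(sats)
}

#' Calibrate pool size and budget spread to target community statistics
#'
#' Returns the pool size `S` and budget spread `std_X` such that randomly
#' assembled communities have the requested niche saturation `S*/R` and
#' sampling permissivity `S*/S` on average.  `S` follows from the
#' definitions (`S = round(S*_target / permissivity)`); `std_X` is found by
#' a bracketed secant search on pilot assemblies (`n_rep` replicates per
#' probe), exploiting that the surviving fraction decreases monotonically
#' with the budget spread.  If even a negligible spread cannot reach the
#' target saturation (the pool is not permissive enough), the result is
#' flagged infeasible and carries the achieved saturation, which is how
#' near-saturated conditions ("as close to S*/R = 1 as the pool permits")
#' are produced.
#'
#' Results are memoized per session, keyed by all arguments.
#'
#' @param target_niche_saturation Target `S*/R` in (0, 1].
#' @param target_permissivity Target `S*/S` in (0, 1].
#' @param R,R0 Resource count and per-strain usage of the pool.
#' @param env A `cr_env`.
#' @param scheme Sampling scheme.
#' @param n_rep Pilot replicates per probe (at least 20 recommended).
#' @param seed Seed for the pilot assemblies.
#' @param rel_tol Relative tolerance on the achieved mean saturation.
#' @param max_probes Probe budget for the search.
#' @return List with `S`, `std_X`, `achieved_saturation`,
#'   `achieved_permissivity`, `feasible`, `probes` (data frame of the probe
#'   history), `n_rep`, and `path` (calibration route; pilot simulation).
#' @export
calibrate_pool <- function(target_niche_saturation, target_permissivity,
                           R, R0, env, scheme = "binary", n_rep = 20L,
                           seed = 1L, rel_tol = 0.03, max_probes = 12L) {
  if (target_niche_saturation <= 0 || target_niche_saturation > 1) {
    stop("target niche saturation must be in (0, 1]")
  }
  if (target_permissivity <= 0 || target_permissivity > 1) {
    stop("target permissivity must be in (0, 1]")
  }
  S_star_target <- target_niche_saturation * R
  S <- max(1L, as.integer(round(S_star_target / target_permissivity)))
  if (S_star_target > R + 1e-9) stop("target S* exceeds the resource count")

  key <- paste("cal", target_niche_saturation, target_permissivity, R, R0,
               env$R, signif(env$cv2, 8), scheme, n_rep, seed, rel_tol,
               sep = "|")
  if (!is.null(.crevo_cache[[key]])) return(.crevo_cache[[key]])

  s0 <- max(sqrt((1 - R0 / R) / R0), 1e-3) # community strategy-spread scale
  x_min <- 1e-3 * s0
  target <- target_niche_saturation
  probes <- data.frame(std_X = numeric(), mean_sat = numeric())
  mfun <- function(x, pid) {
    m <- pilot_saturation(R, R0, S, x, env, scheme, n_rep, seed, pid)
    probes[nrow(probes) + 1L, ] <<- c(x, m)
    m
  }

  x_lo <- NA_real_; m_lo <- NA_real_ # below-target spread (sat too high)
  x_hi <- NA_real_; m_hi <- NA_real_ # above-target spread (sat too low)
  x <- 0.2 * s0
  best <- NULL
  feasible <- TRUE
  for (p in seq_len(max_probes)) {
    m <- mfun(x, p)
    if (is.null(best) || abs(m - target) < abs(best$m - target)) {
      best <- list(x = x, m = m)
    }
    if (abs(m - target) <= rel_tol * target) break
    if (m > target) {
      x_lo <- x; m_lo <- m
    } else {
      x_hi <- x; m_hi <- m
    }
    if (is.na(x_hi)) {
      x <- x * 3 # saturation still too high: widen the budget spread
    } else if (is.na(x_lo)) {
      x <- x / 3
      if (x < x_min) {
        m_min <- mfun(x_min, max_probes + 1L)
        if (is.null(best) || abs(m_min - target) < abs(best$m - target)) {
          best <- list(x = x_min, m = m_min)
        }
        if (m_min < target * (1 - rel_tol)) feasible <- FALSE
        break
      }
    } else {
      # secant in (log std_X, saturation), clamped inside the bracket
      t_ <- (target - m_lo) / (m_hi - m_lo)
      t_ <- min(max(t_, 0.1), 0.9)
      x <- exp(log(x_lo) + t_ * (log(x_hi) - log(x_lo)))
    }
  }
  res <- list(S = S, std_X = best$x, achieved_saturation = best$m,
              achieved_permissivity = best$m * R / S,
              feasible = feasible && abs(best$m - target) <= 2 * rel_tol * target,
              probes = probes, n_rep = n_rep, path = "pilot-simulation")
  .crevo_cache[[key]] <- res
  res
}
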