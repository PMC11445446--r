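# Shared fixtures and memoized ensembles for the test suite.  Everything is
# generated in code; expensive calibrations are cached per session by the
# package itself (keyed by their full argument list), so repeated use across
# test files costs nothing extra.

# Two perfect specialists on two uniformly supplied resources.
specialist_pair <- function() {
  pool <- sample_pool(2, 1, 2, 0, seed = 1)
  pool$alpha <- diag(2)
  pool$X <- c(0, 0)
  pool
}

# Single generalist strain r = (1/2, 1/2) used in the worked monoculture
# example with supply shares (3/4, 1/4).
worked_monoculture <- function() {
  env <- make_environment(2, "uniform")
  env$K <- c(3, 1)
  env$kappa <- c(0.75, 0.25)
  pool <- sample_pool(2, 2, 1, 0, seed = 1)
  pool$alpha <- matrix(c(0.5, 0.5), 1)
  pool$X <- 0
  list(pool = pool, env = env)
}

# Random small instance for program-vs-ODE cross-validation.
random_small_instance <- function(seed) {
  set.seed(seed)
  R <- sample(4:20, 1)
  R0 <- sample(2:max(2, floor(R / 2)), 1)
  S <- sample(5:40, 1)
  env <- make_environment(R, "uniform")
  pool <- sample_pool(R, R0, S, stats::runif(1, 0.05, 0.3), seed = seed + 1)
  list(pool = pool, env = env)
}

# Memoized mid-size community ensemble used by several mutation/invasion
# tests (R = 60, R0 = 12, moderate saturation).
.test_cache <- new.env(parent = emptyenv())
midsize_states <- function(n = 3) {
  key <- paste0("mid", n)
  if (is.null(.test_cache[[key]])) {
    env <- make_environment(60, "uniform")
    .test_cache[[key]] <- lapply(seq_len(n), function(k) {
      assemble_community(60, 12, 180, 0.05, env, seed = 7000 + k)
    })
  }
  .test_cache[[key]]
}

# Minimal synthetic invasion records for extinction_statistics unit tests.
fake_invasion <- function(n_extinct, S_star = 50, kind = "knockout") {
  n_sp <- S_star - 1
  ext <- rep(FALSE, n_sp)
  if (n_extinct > 0) ext[seq_len(n_extinct)] <- TRUE
  structure(list(
    fate = "REPLACES_PARENT", kind = kind, n_extinct = n_extinct,
    pre_S_star = S_star,
    species = data.frame(
      id = paste0("s", seq_len(n_sp)),
      f_pre = rep(1 / S_star, n_sp),
      shared = rep(3L, n_sp),
      uses_target = rep(c(TRUE, FALSE), length.out = n_sp),
      extinct = ext, stringsAsFactors = FALSE)
  ), class = "cr_invasion")
}
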