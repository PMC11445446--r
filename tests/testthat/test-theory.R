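# Mean-field predictions: closed forms, limits, and internal consistency.

test_that("the perfect-trade-off coexistence closed form and its limits", {
  par <- theory_params(R = 200, R0 = 40, S = 2000, S_star = 200, C = 1)
  co <- predict_coexistence(par, norm_d_alpha = 1 / 40)
  expect_equal(co$P_coex_closed, 0.03125, tolerance = 1e-12)
  # vanishing phenotypic effect: no coexistence
  co0 <- predict_coexistence(par, norm_d_alpha = 1e-6)
  expect_lt(co0$P_coex_closed, 1e-8)
  expect_lt(co0$P_coex, 1e-6)
  # decreasing in niche saturation and in R0; proportional to ||d_alpha||^2
  sats <- c(0.3, 0.6, 0.9)
  vals <- vapply(sats, function(s) {
    predict_coexistence(theory_params(200, 40, 2000, 200 * s, C = 1),
                        1 / 40)$P_coex_closed
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  r0s <- c(20, 40, 80)
  vals2 <- vapply(r0s, function(r0) {
    predict_coexistence(theory_params(200, r0, 2000, 120, C = 1),
                        1 / r0)$P_coex_closed
  }, numeric(1))
  expect_true(all(diff(vals2) < 0))
  expect_equal(
    predict_coexistence(par, 2 / 40)$P_coex_closed / co$P_coex_closed, 4,
    tolerance = 1e-10)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("the quadrature reduces to the closed form for perfect trade-offs", {
  # s_bar << sigma: the integral and the closed form agree
  par <- theory_params(R = 400, R0 = 80, S = 4000, S_star = 360, C = 1)
  co <- predict_coexistence(par, norm_d_alpha = 0.2 / 80)
  sbar_over_sigma <- co$s_bar_coex / co$sigma_inv
  expect_lt(sbar_over_sigma, 0.05)
  expect_equal(co$P_coex, co$P_coex_closed,
               tolerance = 3 * sbar_over_sigma)
})

test_that("budget-shift regimes match the quadrature within a factor of two", {
  par <- theory_params(R = 400, R0 = 80, S = 4000, S_star = 360, C = 1)
  nda <- 0.3 / 80
  base <- predict_coexistence(par, nda, dX = 0)
  sigma <- base$sigma_inv
  for (x in c(-3, -2, -0.3, 0.3, 2, 3)) {
    co <- predict_coexistence(par, nda, dX = x * sigma)
    ratio_quad <- co$P_coex / base$P_coex
    expect_gt(co$delta_X_factor / ratio_quad, 0.5)
    expect_lt(co$delta_X_factor / ratio_quad, 2)
  }
  # regime tags
  expect_identical(predict_coexistence(par, nda, dX = 3 * sigma)$regime,
                   "strongly_beneficial")
  expect_identical(predict_coexistence(par, nda, dX = -3 * sigma)$regime,
                   "strongly_costly")
  expect_identical(predict_coexistence(par, nda, dX = 0.1 * sigma)$regime,
                   "negligible_budget_shift")
})

test_that("excess-availability statistics vanish at full saturation", {
  env <- make_environment(50, "cv", cv = 0.2)
  par1 <- theory_params(50, 10, 500, 50, C = 1, env = env)
  gs1 <- g_statistics(par1, env)
  expect_equal(gs1$mean, rep(0, 50))
  expect_equal(gs1$sd, 0)
  par2 <- theory_params(50, 10, 500, 25, C = 1.2, env = env)
  gs2 <- g_statistics(par2, env)
  expect_equal(mean(gs2$mean), 0, tolerance = 1e-12)
  expect_gt(gs2$sd, 0)
  # uniform supply: zero means
  envu <- make_environment(50, "uniform")
  expect_equal(g_statistics(theory_params(50, 10, 500, 25, C = 1,
                                          env = envu), envu)$mean,
               rep(0, 50))
})

test_that("DFE width prediction has the stated scaling and limits", {
  par <- theory_params(200, 40, 2000, 100, C = 1)
  sig <- predict_sigma_inv(par, 1 / 40)
  # sigma = ||d_alpha|| (1-sat) sat^{-1/2} sqrt((1-R0/R)/R0) C
  expect_equal(sig$sigma_inv,
               (1 / 40) * 0.5 * sqrt(2) * sqrt(0.8 / 40), tolerance = 1e-12)
  expect_equal(predict_sigma_inv(theory_params(200, 40, 2000, 200, C = 1),
                                 1 / 40)$sigma_inv, 0)
  expect_equal(predict_sigma_inv(theory_params(200, 200, 2000, 100, C = 1),
                                 1 / 200)$sigma_inv, 0)
  expect_equal(sig$dfe$sd, sig$sigma_inv)
})

test_that("monoculture-community correlation limits", {
  envu <- make_environment(100, "uniform")
  par <- theory_params(100, 20, 1000, 50, C = 1, env = envu)
  expect_equal(predict_dfe_correlation(par, envu)$r, 0)
  envb <- make_environment(100, "cv", cv = 3, method = "gaussian", seed = 1)
  parb <- theory_params(100, 20, 1000, 50, C = 1, env = envb)
  expect_gt(predict_dfe_correlation(parb, envb)$r, 0.9)
})

test_that("theory parameter validation and validity flags", {
  expect_error(theory_params(100, 20, 1000, 0), "S_star")
  expect_error(theory_params(100, 20, 1000, 50, C = -1), "C")
  par <- theory_params(100, 20, 1000, 10)
  expect_false(par$validity[["dense_consumption"]])
  expect_warning(g_statistics(par, make_environment(100, "uniform")),
                 "validity")
})

test_that("the survivor-count surrogate respects the exclusion ceiling", {
  env <- make_environment(30, "uniform")
  suppressWarnings(
    ps <- predict_survivors(S = 200, std_X = 0, R = 30, R0 = 6, env = env,
                            n_rep = 3, seed = 2))
  expect_lte(ps$S_star, 30)
  expect_gt(ps$S_star, 20) # dense pool saturates most niches
  expect_identical(ps$path, "monte-carlo-surrogate")
})
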