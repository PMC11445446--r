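# Mutant construction, invasion fitness, and DFE machinery.

test_that("knockout renormalization and effect sizes are exact", {
  pool <- sample_pool(4, 2, 1, 0, seed = 1)
  pool$alpha <- matrix(c(0.5, 0.5, 0, 0), 1)
  mut <- knockout(pool, 1, 2)
  expect_equal(mut$alpha_new, c(1, 0, 0, 0))
  expect_equal(mut$d_alpha, c(0.5, -0.5, 0, 0))
  expect_equal(mut$norm_d_alpha, 1 / sqrt(2))
  # equal-share parent on k resources: ||d_alpha|| = 1/sqrt(k(k-1))
  for (k in c(3, 10, 40)) {
    pk <- sample_pool(50, k, 1, 0, seed = 2)
    pk$alpha <- matrix(0, 1, 50); pk$alpha[1, seq_len(k)] <- 1 / k
    mk <- knockout(pk, 1, 1)
    expect_equal(mk$norm_d_alpha, 1 / sqrt(k * (k - 1)), tolerance = 1e-12)
  }
  expect_error(knockout(pool, 1, 3), "not used")
  p1 <- pool; p1$alpha <- matrix(c(1, 0, 0, 0), 1)
  expect_error(knockout(p1, 1, 1), "last used")
})

test_that("knockin grants the mean share and reports the right magnitude", {
  pool <- sample_pool(3, 2, 1, 0, seed = 1)
  pool$alpha <- matrix(c(0.5, 0.5, 0), 1)
  mut <- knockin(pool, 1, 3)
  expect_equal(mut$alpha_new, rep(1 / 3, 3))
  expect_equal(mut$norm_d_alpha, sqrt(1 / 6), tolerance = 1e-12)
  expect_error(knockin(pool, 1, 2), "already used")
  pfull <- pool; pfull$alpha <- matrix(rep(1 / 3, 3), 1)
  expect_error(knockin(pfull, 1, 1), "already")
})

test_that("multi mutations validate the simplex and classify budget shifts", {
  pool <- sample_pool(4, 4, 1, 0, seed = 1) # alpha = 1/4 each
  mb <- multi_mutation(pool, 1, rep(0, 4), dX = 0.01)
  expect_identical(mb$kind, "budget_only")
  mm <- multi_mutation(pool, 1, c(0.1, -0.1, 0, 0))
  expect_identical(mm$kind, "multi")
  expect_error(multi_mutation(pool, 1, c(0.1, 0, 0, 0)), "sum to zero")
  expect_error(multi_mutation(pool, 1, c(0.3, -0.3, 0, 0)), "negative")
})

test_that("invasion fitness: worked cases and exact identities", {
  wm <- worked_monoculture()
  st <- compute_equilibrium(wm$pool, wm$env)
  # knockout of the scarce resource: s_exact = s_approx = 0.5
  mut <- knockout(wm$pool, 1, 2)
  fi <- invasion_fitness(st, mut)
  expect_equal(fi$s_exact, 0.5, tolerance = 1e-10)
  expect_equal(fi$s_approx, 0.5, tolerance = 1e-10)
  expect_equal(monoculture_fitness(wm$pool, wm$env, mut), 0.5,
               tolerance = 1e-10)
  # reintroducing the survivor unchanged is neutral
  null_mut <- multi_mutation(wm$pool, 1, c(0, 0), dX = 0)
  expect_equal(invasion_fitness(st, null_mut)$s_exact, 0, tolerance = 1e-10)
  # budget-only: s_exact = e^dX - 1 exactly, s_approx = dX
  bm <- multi_mutation(wm$pool, 1, c(0, 0), dX = 0.03)
  fib <- invasion_fitness(st, bm)
  expect_equal(fib$s_exact, exp(0.03) - 1, tolerance = 1e-12)
  expect_equal(fib$s_approx, 0.03, tolerance = 1e-12)
  expect_equal(monoculture_fitness(wm$pool, wm$env, bm), 0.03)
})

test_that("knock-ins on unconsumed resources are rejected", {
  env <- make_environment(3, "uniform")
  pool <- sample_pool(3, 1, 2, 0, seed = 5)
  pool$alpha <- rbind(c(1, 0, 0), c(0, 1, 0))
  suppressWarnings(st <- compute_equilibrium(pool, env))
  mut <- knockin(pool, 1, 3) # resource 3 has no consumer
  expect_error(invasion_fitness(st, mut), "no current consumer")
  expect_error(monoculture_fitness(pool, env, knockin(pool, 1, 3)),
               "knock-ins")
})

test_that("enumerate_dfe matches per-mutation invasion_fitness and counts", {
  st <- midsize_states(1)[[1]]
  dfe <- enumerate_dfe(st, kinds = c("knockout", "knockin"), dX = 0)
  supp <- rowSums(st$pool$alpha[st$survivors, ] > 0)
  n_ko_expected <- sum(supp[supp >= 2])
  expect_equal(sum(dfe$kind == "knockout"), n_ko_expected)
  n_ki_expected <- sum(vapply(st$survivors, function(mu) {
    sum(st$pool$alpha[mu, ] == 0 & st$consumed)
  }, numeric(1)))
  expect_equal(sum(dfe$kind == "knockin"), n_ki_expected)
  # spot-check rows against the scalar path
  set.seed(3)
  for (i in sample.int(nrow(dfe), 12)) {
    row <- dfe[i, ]
    mut <- if (row$kind == "knockout") {
      knockout(st$pool, row$parent_index, row$target)
    } else knockin(st$pool, row$parent_index, row$target)
    fi <- invasion_fitness(st, mut)
    expect_equal(row$s_exact, fi$s_exact, tolerance = 1e-10)
    expect_equal(row$s_approx, fi$s_approx, tolerance = 1e-10)
    expect_equal(row$norm_d_alpha, mut$norm_d_alpha, tolerance = 1e-10)
  }
})

test_that("uniform supply makes every knockout neutral in monoculture", {
  env <- make_environment(20, "uniform")
  pool <- sample_pool(20, 6, 5, 0.1, seed = 9)
  for (mu in 1:5) {
    supp <- which(pool$alpha[mu, ] > 0)
    for (i in supp[1:2]) {
      m <- knockout(pool, mu, i, dX = 0.02)
      expect_equal(monoculture_fitness(pool, env, m), 0.02,
                   tolerance = 1e-10)
    }
  }
})

test_that("a constant budget shift translates the whole DFE", {
  st <- midsize_states(1)[[1]]
  d0 <- enumerate_dfe(st, dX = 0)
  d1 <- enumerate_dfe(st, dX = -0.01)
  expect_equal(d1$s_approx, d0$s_approx - 0.01, tolerance = 1e-12)
  # exact fitness: s(dX) = e^dX (1 + s(0)) - 1, a near-constant shift
  expect_equal(d1$s_exact, exp(-0.01) * (1 + d0$s_exact) - 1,
               tolerance = 1e-12)
  dev_bound <- abs(exp(-0.01) - 1) * max(abs(d0$s_exact)) + 1e-12
  expect_lt(max(abs((d1$s_exact - d0$s_exact) - (exp(-0.01) - 1))),
            dev_bound * 1.01)
})

test_that("exact and mean-field invasion fitness agree in the dense regime", {
  # R0/R = 0.2, uniform supply: median relative gap below 5%
  sts <- midsize_states(2)
  dfe <- do.call(rbind, lapply(sts, enumerate_dfe, kinds = "knockout"))
  gap <- abs(dfe$s_exact - dfe$s_approx) / pmax(abs(dfe$s_exact), 1e-12)
  expect_lt(median(gap), 0.05)
})

test_that("knockout, knockin and norm-matched multi DFEs are indistinguishable", {
  sts <- midsize_states(3)
  ko <- do.call(rbind, lapply(sts, enumerate_dfe, kinds = "knockout"))
  ki <- do.call(rbind, lapply(sts, enumerate_dfe, kinds = "knockin"))
  expect_gt(nrow(ko) + nrow(ki), 1000)
  # location/scale comparison at alpha = 0.01
  expect_gt(stats::ks.test(ko$s_exact, ki$s_exact)$p.value, 0.01)
  # multi mutations with the matched magnitude, random survivors
  set.seed(11)
  s_multi <- unlist(lapply(sts, function(st) {
    surv <- sample(st$survivors, 25)
    vapply(surv, function(mu) {
      m <- random_multi_mutation(st$pool, mu, norm = 1 / sqrt(12 * 11))
      invasion_fitness(st, m)$s_exact
    }, numeric(1))
  }))
  expect_gt(stats::ks.test(s_multi, ko$s_exact)$p.value, 0.01)
})

test_that("per-strain DFE width does not depend on the parent strain", {
  st <- midsize_states(3)[[2]]
  dfe <- enumerate_dfe(st, kinds = "knockout")
  # widths are compared per unit phenotypic effect: parents with smaller
  # supports make intrinsically larger moves, which is not a parent effect
  s_unit <- dfe$s_exact / dfe$norm_d_alpha
  centered <- abs(s_unit - stats::ave(s_unit, dfe$parent_id))
  kw <- stats::kruskal.test(centered, factor(dfe$parent_id))
  expect_gt(kw$p.value, 0.01)
})

test_that("community-monoculture DFE correlation handles degeneracy", {
  # uniform supply: monoculture fitness has zero variance, flagged r = 0
  sts <- midsize_states(2)
  dc <- dfe_correlation(sts)
  expect_true(dc$degenerate)
  expect_identical(dc$r, 0)
  # variable supply: a genuine correlation, not flagged
  envk <- make_environment(60, "cv", cv = 0.4)
  stk <- compute_equilibrium(sample_pool(60, 12, 180, 0.05, seed = 31), envk)
  dck <- dfe_correlation(stk)
  expect_false(dck$degenerate)
  expect_gt(dck$r, 0)
  expect_lte(dck$r, 1)
  expect_error(dfe_correlation(list()), NULL)
})
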