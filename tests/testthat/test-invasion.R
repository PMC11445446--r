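# Invasion resolution, fate bookkeeping, and ensemble statistics.

test_that("pure budget mutations always replace their parent", {
  st <- midsize_states(1)[[1]]
  for (mu in st$survivors[1:5]) {
    mut <- multi_mutation(st$pool, mu, rep(0, st$pool$R), dX = 0.05)
    res <- resolve_invasion(st, mut)
    expect_identical(res$fate, "REPLACES_PARENT")
    expect_true(res$parent_extinct)
  }
})

test_that("deleterious mutations leave the community untouched", {
  st <- midsize_states(1)[[1]]
  mut <- multi_mutation(st$pool, st$survivors[1], rep(0, st$pool$R),
                        dX = -0.05)
  res <- resolve_invasion(st, mut)
  expect_identical(res$fate, "NOT_BENEFICIAL")
  expect_identical(res$n_extinct, 0L)
})

test_that("invasion bookkeeping is internally consistent", {
  sts <- midsize_states(2)
  res <- sample_invasions(sts, n = 60, seed = 14)
  for (x in res) {
    expect_true(x$fate %in% c("COEXISTS", "REPLACES_PARENT", "MUTANT_DIES"))
    expect_identical(x$n_extinct, length(x$extinct_ids))
    expect_identical(sum(x$species$extinct), length(x$extinct_ids))
    expect_false(x$parent_id %in% x$species$id)
    if (x$fate == "COEXISTS") expect_false(x$parent_extinct)
    if (x$fate == "REPLACES_PARENT") expect_true(x$parent_extinct)
    expect_identical(length(x$rescued_ids), 0L) # sequential policy
  }
  fates <- vapply(res, function(x) x$fate, character(1))
  expect_equal(sum(fates %in% c("COEXISTS", "REPLACES_PARENT",
                                "MUTANT_DIES")), length(res))
})

test_that("reinvasion policy can rescue assembly losers", {
  st <- midsize_states(2)[[2]]
  res <- sample_invasions(st, n = 30, seed = 15, policy = "reinvasion")
  rescued <- unlist(lapply(res, function(x) x$rescued_ids))
  excluded_ids <- st$pool$id[-st$survivors]
  expect_true(all(rescued %in% excluded_ids))
  expect_gt(length(rescued), 0) # at 80% saturation rescues do occur
})

test_that("successful-mutation sampling follows its weight contract", {
  st <- midsize_states(1)[[1]]
  dfe <- enumerate_dfe(st)
  n_elig <- table(dfe$parent_index)
  w <- dfe$f_parent / as.numeric(n_elig[as.character(dfe$parent_index)]) *
    pmax(dfe$s_exact, 0)
  w <- w / sum(w)
  set.seed(8)
  draws <- replicate(8000, {
    m <- sample_successful_mutation(st, dfe = dfe)
    paste(m$parent_index, m$target)
  })
  keys <- paste(dfe$parent_index, dfe$target)
  emp <- as.numeric(table(factor(draws, levels = keys))) / 8000
  big <- w > 0.005 # well-estimated categories
  se <- sqrt(w[big] * (1 - w[big]) / 8000)
  expect_true(all(abs(emp[big] - w[big]) < 4 * se))
  # parents with zero beneficial mutations are never drawn
  expect_true(all(w[match(unique(draws), keys)] > 0))
})

test_that("exhaustion is signalled when no mutation is beneficial", {
  st <- midsize_states(1)[[1]]
  expect_null(sample_successful_mutation(st, dX = -10))
})

test_that("coexistence probability: budget-only mutations give zero", {
  st <- midsize_states(2)[[1]]
  # resolve budget mutations for several survivors: never coexistence
  fates <- vapply(st$survivors[1:10], function(mu) {
    mut <- multi_mutation(st$pool, mu, rep(0, st$pool$R), dX = 0.02)
    resolve_invasion(st, mut)$fate
  }, character(1))
  expect_true(all(fates == "REPLACES_PARENT"))
})

test_that("coexisting mutants sit at low fitness and abundant parents", {
  sts <- midsize_states(3)
  cp <- coexistence_probability(sts, n_samples = 150, seed = 23)
  expect_gt(cp$n_successful, 100)
  res <- cp$results
  fates <- vapply(res, function(x) x$fate, character(1))
  s <- vapply(res, function(x) x$s_inv, numeric(1))
  fp <- vapply(res, function(x) x$f_parent, numeric(1))
  ok <- fates %in% c("COEXISTS", "REPLACES_PARENT")
  expect_lt(mean(s[fates == "COEXISTS"]), mean(s[fates == "REPLACES_PARENT"]))
  expect_gt(mean(fp[fates == "COEXISTS"]),
            mean(fp[fates == "REPLACES_PARENT"]))
  expect_true(cp$estimate >= 0 && cp$estimate <= 1)
})

test_that("extinction statistics: definitions and degenerate cases", {
  # zero-matched Poisson: P(0) = e^-1 gives lambda = 1
  counts <- c(rep(0L, 368), rep(1L, 400), rep(2L, 180), rep(3L, 52))
  res <- lapply(counts, fake_invasion)
  xs <- extinction_statistics(res)
  expect_equal(xs$p_zero, 0.368)
  expect_equal(xs$poisson_lambda, -log(0.368), tolerance = 1e-12)
  expect_equal(xs$mean_extinctions, mean(counts))
  expect_equal(sum(xs$count_hist), length(counts))
  # no extinctions anywhere: mean zero, fold changes flagged undefined
  res0 <- lapply(rep(0L, 25), fake_invasion)
  xs0 <- extinction_statistics(res0)
  expect_equal(xs0$mean_extinctions, 0)
  expect_true(all(is.na(xs0$fold_change$fold_change)))
  expect_error(extinction_statistics(list()), "no successful")
})
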