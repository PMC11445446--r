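# Mutation-limited multi-step evolution and lineage statistics.
# Runs use a small community (R = 40) so whole trajectories stay cheap.

evo_fixture <- function() {
  if (is.null(.test_cache$evo)) {
    env <- make_environment(40, "uniform")
    st <- assemble_community(40, 8, 120, 0.06, env, seed = 71)
    .test_cache$evo <- run_evolution(st, seed = 72, max_mutations = 4,
                                     max_steps = 200)
  }
  .test_cache$evo
}

test_that("evolution runs are reproducible and respect the stop rule", {
  log <- evo_fixture()
  env <- log$initial_state$env
  log2 <- run_evolution(log$initial_state, seed = 72, max_mutations = 4,
                        max_steps = 200)
  expect_identical(log$events, log2$events)
  expect_identical(log$lineage, log2$lineage)
  if (log$stop_reason == "max_mutations") {
    expect_identical(max(log$final_state$pool$n_mutations), 4L)
    # the stop fires exactly when the threshold is first reached
    expect_true(all(log$events$max_n_mutations[-nrow(log$events)] < 4))
  }
  expect_gt(log$n_steps, 10)
})

test_that("the event log and lineage table are mutually consistent", {
  log <- evo_fixture()
  ev <- log$events
  expect_identical(ev$step, seq_len(nrow(ev)))
  lin <- log$lineage
  expect_identical(anyDuplicated(lin$id), 0L)
  for (i in seq_len(nrow(ev))) {
    m <- ev$mutant_id[i]
    j <- match(m, lin$id)
    expect_identical(lin$birth_step[j], ev$step[i])
    expect_identical(lin$parent_id[j], ev$parent_id[i])
    # the parent was alive when it mutated
    pj <- match(ev$parent_id[i], lin$id)
    expect_lt(lin$birth_step[pj], ev$step[i] + 1)
    expect_true(is.na(lin$death_step[pj]) ||
                  lin$death_step[pj] >= ev$step[i])
  }
  # every death recorded corresponds to an extinction or replacement event
  dead <- lin$id[!is.na(lin$death_step)]
  ext_all <- unlist(c(strsplit(ev$extinct_ids, ";"),
                      ev$parent_id[ev$parent_extinct]))
  expect_true(all(dead %in% ext_all))
  # survivor count never exceeds the resource count, KKT certified
  expect_true(all(ev$post_S_star <= 40))
  expect_lte(log$final_state$residuals[["survivor"]], 1e-9)
})

test_that("step-0 DFE snapshot equals a fresh enumeration", {
  log <- evo_fixture()
  expect_equal(log$dfe_snapshots[["0"]],
               enumerate_dfe(log$initial_state, kinds = "knockout", dX = 0))
  cmp <- dfe_snapshot_compare(log, c(0, log$n_steps))
  expect_identical(nrow(cmp), 2L)
  expect_true(all(is.finite(cmp$sd)))
  expect_error(dfe_snapshot_compare(log, 999999), "no DFE snapshot")
})

test_that("lineage statistics: counts, divergences, censoring", {
  log <- evo_fixture()
  ls_ <- lineage_statistics(log)
  sc <- ls_$strain_counts
  expect_identical(nrow(sc), log$n_steps + 1L)
  expect_identical(sc$n_strains[1], length(log$initial_state$survivors))
  # independent recomputation of the final related-strain count
  fin <- log$final_state
  tab <- table(fin$pool$lineage_id[fin$survivors])
  expect_identical(sc$n_related[nrow(sc)],
                   as.integer(sum(tab[tab >= 2])))
  expect_identical(sc$n_strains[nrow(sc)], length(fin$survivors))
  # divergences: one per COEXISTS event; durations positive; censored ones
  # run to the end of the simulation
  n_co <- sum(log$events$fate == "COEXISTS")
  if (n_co > 0) {
    expect_identical(nrow(ls_$divergences), n_co)
    expect_true(all(ls_$divergences$duration >= 0))
    cens <- ls_$divergences[ls_$divergences$censored, ]
    expect_true(all(cens$duration == log$n_steps - cens$step))
    if (any(!ls_$divergences$censored)) {
      expect_identical(ls_$mean_coexistence_duration,
                       mean(ls_$divergences$duration[
                         !ls_$divergences$censored]))
    }
    expect_s3_class(ls_$maintenance_km, "survfit")
  }
  expect_identical(nrow(ls_$decile_coexistence), 10L)
})

test_that("a log without diversification has no related strains", {
  lin <- data.frame(id = c("a", "b", "c"),
                    parent_id = c(NA, NA, "a"),
                    lineage_id = c("a", "b", "a"),
                    birth_step = c(0L, 0L, 1L),
                    death_step = c(1L, NA_integer_, NA_integer_),
                    n_mutations = c(0L, 0L, 1L), stringsAsFactors = FALSE)
  ev <- data.frame(step = 1L, parent_id = "a", mutant_id = "c",
                   kind = "knockout", target = 1L, dX = 0, s_inv = 0.01,
                   fate = "REPLACES_PARENT", parent_extinct = TRUE,
                   n_extinct = 0L, extinct_ids = "", f_parent_pre = 0.5,
                   pre_S_star = 2L, post_S_star = 2L,
                   max_n_mutations = 1L, stringsAsFactors = FALSE)
  fake <- structure(list(events = ev, lineage = lin, n_steps = 1L,
                         initial_state = NULL, final_state = NULL,
                         abundance_at = list()), class = "cr_evolution")
  ls_ <- lineage_statistics(fake)
  # "a" is replaced by its own descendant "c": same founder lineage, but at
  # any time only one of them is alive, so nothing is "related"
  expect_true(all(ls_$strain_counts$n_related == 0L))
  expect_null(ls_$divergences)
})

test_that("newick export is balanced and covers every strain", {
  log <- evo_fixture()
  nwk <- lineage_newick(log)
  expect_identical(length(nwk),
                   sum(is.na(log$lineage$parent_id) |
                         !(log$lineage$parent_id %in% log$lineage$id)))
  allstr <- paste(nwk, collapse = "")
  expect_identical(lengths(regmatches(allstr, gregexpr("\\(", allstr))),
                   lengths(regmatches(allstr, gregexpr("\\)", allstr))))
  for (id in log$lineage$id[1:10]) {
    expect_true(grepl(id, allstr, fixed = TRUE))
  }
  path <- tempfile(fileext = ".nwk")
  lineage_newick(log, path)
  expect_identical(readLines(path), nwk)
  unlink(path)
})

test_that("extinction happens to rarer strains than diversification", {
  log <- evo_fixture()
  ab <- log$abundance_at
  if (length(ab$extinction) > 10 && length(ab$diversification) > 10) {
    expect_lt(median(ab$extinction), median(ab$diversification))
  }
  expect_identical(length(ab$mutation), log$n_steps)
})
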