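# Fate of a single successful mutant: coexistence with the parent,
# replacement, and the collateral extinctions it causes in the community.

#' Resolve the fate of a mutant invasion
#'
#' Evaluates the mutant's invasion fitness at the resident equilibrium and,
#' if beneficial, computes the new uninvadable equilibrium.  Three policies
#' control which strains compete in the new equilibrium:
#'
#' * `"sequential"` (default): the pre-invasion survivors plus the mutant;
#'   species that went extinct during assembly stay extinct.
#' * `"reinvasion"`: the full original pool plus the mutant, i.e. extinct
#'   species are allowed to re-invade and can be "rescued".
#' * `"simultaneous"`: mutant and parent are assembled together with the
#'   full pool from scratch.  Because the equilibrium is the optimum of a
#'   concave potential, this coincides with `"reinvasion"` in this model;
#'   both switches are kept for protocol clarity.
#'
#' @param pre_state A `cr_state`.
#' @param mut A `cr_mutation` whose parent survives in `pre_state`.
#' @param policy One of `"sequential"`, `"reinvasion"`, `"simultaneous"`.
#' @param mutant_id Identifier for the mutant strain.
#' @param keep_post Keep the full post-invasion `cr_state` in the result
#'   (costs memory in large ensembles).
#' @param tol KKT tolerance for the post-invasion equilibrium.
#' @return An object of class `cr_invasion`: list with `fate`, `s_inv`,
#'   `s_approx`, `kind`, `target`, `dX`, `norm_d_alpha`, `parent_id`,
#'   `f_parent`, `parent_extinct`, `extinct_ids` (non-parent pre-survivors
#'   lost), `n_extinct`, `rescued_ids`, `pre_S_star`, `degenerate`,
#'   `policy`, `species` (per non-parent resident: pre-invasion abundance,
#'   resources shared with the mutant, whether it uses the mutation's
#'   target resource, extinction flag), `mutant_id`, `f_mutant`, and
#'   optionally `post_state`.
#' @export
resolve_invasion <- function(pre_state, mut,
                             policy = c("sequential", "reinvasion",
                                        "simultaneous"),
                             mutant_id = NULL, keep_post = FALSE,
                             tol = 1e-10) {
  policy <- match.arg(policy)
  pool <- pre_state$pool
  if (!(mut$parent_index %in% pre_state$survivors)) {
    stop("mutation parent is not alive in the pre-invasion state")
  }
  if (is.null(mutant_id)) mutant_id <- paste0(mut$parent_id, "+m")
  s <- invasion_fitness(pre_state, mut)
  f_parent <- pre_state$f[mut$parent_index]
  pre_surv_ids <- pool$id[pre_state$survivors]

  mk_species <- function(extinct_ids) {
    keep <- setdiff(pre_state$survivors, mut$parent_index)
    ids <- pool$id[keep]
    supp_mut <- mut$alpha_new > 0
    shared <- as.integer((pool$alpha[keep, , drop = FALSE] > 0) %*% supp_mut)
    uses_target <- if (!is.null(mut$target) && !is.na(mut$target)) {
      pool$alpha[keep, mut$target] > 0
    } else rep(NA, length(keep))
    data.frame(id = ids, f_pre = pre_state$f[keep], shared = shared,
               uses_target = uses_target, extinct = ids %in% extinct_ids,
               stringsAsFactors = FALSE)
  }

  base <- list(
    kind = mut$kind, target = mut$target, dX = mut$dX,
    norm_d_alpha = mut$norm_d_alpha, parent_id = mut$parent_id,
    mutant_id = mutant_id, s_inv = s$s_exact, s_approx = s$s_approx,
    f_parent = f_parent, pre_S_star = length(pre_state$survivors),
    policy = policy
  )

  if (s$s_exact <= 0) {
    out <- c(base, list(
      fate = "NOT_BENEFICIAL", parent_extinct = FALSE,
      extinct_ids = character(), n_extinct = 0L, rescued_ids = character(),
      degenerate = pre_state$degenerate, species = mk_species(character()),
      f_mutant = 0))
    if (keep_post) out$post_state <- pre_state
    return(structure(out, class = "cr_invasion"))
  }

  cand <- if (policy == "sequential") pre_state$survivors else seq_len(pool$S)
  sub <- pool[cand]
  newpool <- pool_append(
    sub, id = mutant_id, lineage_id = pool$lineage_id[mut$parent_index],
    parent_id = mut$parent_id, X = mut$X_new, alpha = mut$alpha_new,
    n_mutations = pool$n_mutations[mut$parent_index] + 1L)
  f0 <- if (policy == "simultaneous") NULL else {
    c(pmax(pre_state$f[cand], 1e-10), 1e-6)
  }
  post <- compute_equilibrium(newpool, pre_state$env, tol = tol, f0 = f0)
  post_ids <- newpool$id[post$survivors]

  mutant_alive <- mutant_id %in% post_ids
  parent_alive <- mut$parent_id %in% post_ids
  fate <- if (!mutant_alive) "MUTANT_DIES"
          else if (parent_alive) "COEXISTS" else "REPLACES_PARENT"
  extinct_ids <- setdiff(setdiff(pre_surv_ids, mut$parent_id), post_ids)
  rescued_ids <- setdiff(setdiff(post_ids, pre_surv_ids), mutant_id)
  out <- c(base, list(
    fate = fate, parent_extinct = !parent_alive, extinct_ids = extinct_ids,
    n_extinct = length(extinct_ids), rescued_ids = rescued_ids,
    degenerate = post$degenerate, species = mk_species(extinct_ids),
    f_mutant = if (mutant_alive) post$f[newpool$S] else 0))
  if (keep_post) out$post_state <- post
  structure(out, class = "cr_invasion")
}

#' @export
print.cr_invasion <- function(x, ...) {
  cat(sprintf(
    "<cr_invasion> %s %s (s_inv = %.3g): %s, %d non-parent extinction(s)\n",
    x$kind, x$parent_id, x$s_inv, x$fate, x$n_extinct))
  invisible(x)
}

#' Sample one successful (established) mutation
#'
#' Draws a mutation from the state's enumerated single-resource mutations
#' with probability proportional to
#' `f_parent / n_eligible(parent) * max(s_inv, 0)`: parents are picked in
#' proportion to their abundance (mutational supply), the target resource
#' uniformly among the parent's eligible targets, and establishment is
#' weighted by the invasion fitness (the establishment probability of a
#' beneficial mutant is proportional to its fitness effect; only relative
#' weights matter for the reported statistics).  Uses R's ambient RNG
#' stream.
#'
#' @param state A `cr_state`.
#' @param kinds Mutation kinds to enumerate.
#' @param dX Budget change.
#' @param parent_weight `"abundance"` (default) or `"uniform"` (sensitivity
#'   switch).
#' @param dfe Optional pre-computed enumeration (from [enumerate_dfe()]
#'   with the same `kinds` and `dX`) to avoid recomputation.
#' @return A `cr_mutation` with attribute `"s_inv"`, or `NULL` if no
#'   beneficial mutation exists (evolutionary exhaustion).
#' @export
sample_successful_mutation <- function(state, kinds = "knockout", dX = 0,
                                       parent_weight = c("abundance",
                                                         "uniform"),
                                       dfe = NULL) {
  parent_weight <- match.arg(parent_weight)
  if (is.null(dfe)) dfe <- enumerate_dfe(state, kinds = kinds, dX = dX)
  if (nrow(dfe) == 0) return(NULL)
  n_elig <- table(dfe$parent_index)
  ne <- as.numeric(n_elig[as.character(dfe$parent_index)])
  wpar <- if (parent_weight == "abundance") dfe$f_parent else 1
  w <- wpar / ne * pmax(dfe$s_exact, 0)
  if (!any(w > 0)) return(NULL)
  row <- dfe[sample.int(nrow(dfe), 1L, prob = w), ]
  mut <- if (row$kind == "knockout") {
    knockout(state$pool, row$parent_index, row$target, dX)
  } else {
    knockin(state$pool, row$parent_index, row$target, dX)
  }
  attr(mut, "s_inv") <- row$s_exact
  mut
}

#' Monte-Carlo ensemble of first-step invasions
#'
#' Repeatedly samples a successful mutation (cycling over the supplied
#' replicate states) and resolves its invasion.  The workhorse behind
#' [coexistence_probability()] and [extinction_statistics()].
#'
#' @param states A `cr_state` or list of them.
#' @param kinds,dX Mutation class.
#' @param n Number of attempted invasions.
#' @param seed Master seed (one child stream per invasion).
#' @param policy Passed to [resolve_invasion()].
#' @param parent_weight Passed to [sample_successful_mutation()].
#' @return List of `cr_invasion` objects (states whose beneficial mutations
#'   are exhausted are skipped).
#' @export
sample_invasions <- function(states, kinds = "knockout", dX = 0, n = 100L,
                             seed = 1L, policy = "sequential",
                             parent_weight = "abundance") {
  if (inherits(states, "cr_state")) states <- list(states)
  # enumerate each state's DFE once
  dfes <- lapply(states, enumerate_dfe, kinds = kinds, dX = dX)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    j <- (k - 1L) %% length(states) + 1L
    st <- states[[j]]
    res <- with_seed(derive_seed(seed, k), {
      mut <- sample_successful_mutation(st, kinds = kinds, dX = dX,
                                        parent_weight = parent_weight,
                                        dfe = dfes[[j]])
      if (is.null(mut)) NULL
      else resolve_invasion(st, mut, policy = policy,
                            mutant_id = paste0("m", k))
    })
    out[[k]] <- res
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Mutant-parent coexistence probability
#'
#' Monte-Carlo estimate of the probability that a successful mutant stably
#' coexists with its parent strain: the fraction of established invasions
#' with fate `COEXISTS` among all established invasions (rare events where
#' the accepted mutant nonetheless dies at the new equilibrium are excluded
#' from both numerator and denominator, and counted separately).
#'
#' @inheritParams sample_invasions
#' @param n_samples Number of sampled invasions.
#' @return List with `estimate`, `se` (binomial), `n_successful`,
#'   `n_coexist`, `n_mutant_dies`, and `results` (the invasion records).
#' @export
coexistence_probability <- function(states, kinds = "knockout", dX = 0,
                                    n_samples = 200L, seed = 1L,
                                    policy = "sequential",
                                    parent_weight = "abundance") {
  res <- sample_invasions(states, kinds = kinds, dX = dX, n = n_samples,
                          seed = seed, policy = policy,
                          parent_weight = parent_weight)
  fates <- vapply(res, function(x) x$fate, character(1))
  n_died <- sum(fates == "MUTANT_DIES")
  ok <- fates %in% c("COEXISTS", "REPLACES_PARENT")
  n_succ <- sum(ok)
  if (n_succ == 0) stop("no successful invasions in the ensemble")
  p <- mean(fates[ok] == "COEXISTS")
  list(estimate = p, se = sqrt(p * (1 - p) / n_succ), n_successful = n_succ,
       n_coexist = sum(fates[ok] == "COEXISTS"), n_mutant_dies = n_died,
       results = res)
}

#' Extinction statistics over an invasion ensemble
#'
#' Summarizes the collateral extinctions caused by successful mutants
#' (parents are excluded from all extinction tallies):
#'
#' * mean number of extinctions per successful invasion;
#' * the full extinction-count histogram together with a Poisson reference
#'   matched on the fraction of zero counts (`lambda = -log P(0)`);
#' * the distribution of the number of resources jointly utilized by the
#'   displaced species and the invading mutant, and the background
#'   distribution over all resident species;
#' * extinction probability binned by pre-invasion relative abundance.
#'   Abundances are scaled by the pre-invasion survivor count (so 1 is the
#'   mean abundance) and binned on the default log-like breaks, which
#'   resolve the limit of very rare species where the extinction risk
#'   concentrates;
#' * the fold change in the probability that a displaced species uses the
#'   resource targeted by the mutation, relative to the background resource
#'   use, separately per mutation kind.
#'
#' @param results List of `cr_invasion` objects (non-established invasions
#'   are dropped).
#' @param abundance_breaks Bin breaks for the scaled abundance
#'   `f * S*` (units of the mean survivor abundance).
#' @return List with `n_invasions`, `mean_extinctions`, `count_hist`,
#'   `p_zero`, `poisson_lambda`, `poisson_ref`, `shared_displaced`,
#'   `shared_background`, `abundance_bins` (data frame), and `fold_change`
#'   (data frame per kind).
#' @export
extinction_statistics <- function(results,
                                  abundance_breaks = c(0, 0.01, 0.02, 0.05,
                                                       0.1, 0.15, 0.25, 0.5,
                                                       1, 2, Inf)) {
  fates <- vapply(results, function(x) x$fate, character(1))
  results <- results[fates %in% c("COEXISTS", "REPLACES_PARENT")]
  if (length(results) == 0) stop("no successful invasions supplied")

  n_ext <- vapply(results, function(x) x$n_extinct, numeric(1))
  counts <- table(factor(n_ext, levels = 0:max(n_ext)))
  p0 <- mean(n_ext == 0)
  lambda <- if (p0 > 0) -log(p0) else NA_real_
  pois <- if (p0 > 0) stats::dpois(0:max(n_ext), lambda) else NULL

  species <- do.call(rbind, lapply(seq_along(results), function(i) {
    sp <- results[[i]]$species
    sp$invasion <- i
    sp$kind <- results[[i]]$kind
    sp$x <- sp$f_pre * results[[i]]$pre_S_star # abundance / mean abundance
    sp
  }))

  breaks <- abundance_breaks
  bin <- cut(species$x, breaks = breaks, right = FALSE)
  ab <- data.frame(
    bin = levels(bin),
    lower = breaks[-length(breaks)],
    n = as.integer(tapply(species$extinct, bin, length)),
    n_extinct = as.integer(tapply(species$extinct, bin, sum))
  )
  ab$n[is.na(ab$n)] <- 0L
  ab$n_extinct[is.na(ab$n_extinct)] <- 0L
  ab$p_extinct <- ifelse(ab$n > 0, ab$n_extinct / ab$n, NA_real_)

  fold <- do.call(rbind, lapply(split(species, species$kind), function(sp) {
    sp <- sp[!is.na(sp$uses_target), ]
    disp <- sp[sp$extinct, ]
    if (nrow(disp) == 0 || nrow(sp) == 0) {
      return(data.frame(kind = sp$kind[1] %||% NA_character_,
                        p_displaced = NA_real_, p_background = NA_real_,
                        fold_change = NA_real_, n_displaced = nrow(disp)))
    }
    pd <- mean(disp$uses_target)
    pb <- mean(sp$uses_target)
    data.frame(kind = sp$kind[1], p_displaced = pd, p_background = pb,
               fold_change = pd / pb, n_displaced = nrow(disp))
  }))
  rownames(fold) <- NULL

  list(n_invasions = length(results), mean_extinctions = mean(n_ext),
       count_hist = counts, p_zero = p0, poisson_lambda = lambda,
       poisson_ref = pois,
       shared_displaced = species$shared[species$extinct],
       shared_background = species$shared,
       abundance_bins = ab, fold_change = fold)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
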