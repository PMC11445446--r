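# Mutation-limited (strong-selection weak-mutation) multi-step evolution.
#
# Exactly one mutation segregates at a time: a successful mutation is
# sampled (parents by abundance, establishment by fitness), its invasion is
# resolved sequentially, the community relaxes to the new uninvadable
# equilibrium, and the process repeats.  "Time" is the counter of
# successful mutations.  The default stop rule fires when some surviving
# strain has accumulated 10 mutations since the start.

#' Run mutation-limited evolution
#'
#' @param init A `cr_state` (assembled community) or a `cr_pool` (assembled
#'   internally first).
#' @param env A `cr_env`; may be omitted when `init` is a `cr_state`.
#' @param kinds Mutation kinds offered at each step (default knock-outs
#'   only: resident strains can lose any resource they currently utilize).
#' @param dX Budget change of every mutation.
#' @param max_mutations Stop once some surviving strain has accumulated
#'   this many mutations (default 10).
#' @param max_steps Hard cap on the number of successful mutations.
#' @param seed Master seed; the whole trajectory is reproducible.
#' @param parent_weight Parent sampling weight, `"abundance"` or
#'   `"uniform"`.
#' @param snapshot_dfe_at Steps at which the full enumerated DFE is stored
#'   (step 0 and the final step are always stored).
#' @param max_establish_tries Resampling cap for the rare case where an
#'   accepted mutant dies at the new equilibrium.
#' @return An object of class `cr_evolution`: list with `events` (data
#'   frame, one row per successful mutation), `lineage` (strain table:
#'   id, parent_id, lineage_id, birth_step, death_step, n_mutations),
#'   `dfe_stats` (per-step DFE summary), `dfe_snapshots` (full DFE data
#'   frames, named by step), `abundance_at` (abundances at mutation,
#'   diversification and extinction events), `initial_state`,
#'   `final_state`, `stop_reason`, `n_steps`, and the configuration.
#' @export
run_evolution <- function(init, env = NULL, kinds = "knockout", dX = 0,
                          max_mutations = 10L, max_steps = 5000L, seed = 1L,
                          parent_weight = "abundance",
                          snapshot_dfe_at = integer(),
                          max_establish_tries = 50L) {
  if (inherits(init, "cr_pool")) {
    if (is.null(env)) stop("env required when init is a pool")
    st <- compute_equilibrium(init, env)
  } else if (inherits(init, "cr_state")) {
    st <- init
    env <- st$env
  } else stop("init must be a cr_state or cr_pool")
  initial_state <- st

  surv0 <- st$survivors
  lineage <- data.frame(
    id = st$pool$id[surv0], parent_id = st$pool$parent_id[surv0],
    lineage_id = st$pool$lineage_id[surv0],
    birth_step = 0L, death_step = NA_integer_,
    n_mutations = st$pool$n_mutations[surv0], stringsAsFactors = FALSE)

  events <- list()
  dfe_stats <- list()
  dfe_snapshots <- list()
  ab_mut <- numeric(0); ab_div <- numeric(0); ab_ext <- numeric(0)
  stop_reason <- "max_steps"

  step <- 0L
  repeat {
    dfe <- enumerate_dfe(st, kinds = kinds, dX = dX)
    sm <- dfe_summary(dfe)
    dfe_stats[[length(dfe_stats) + 1L]] <- data.frame(
      step = step, n = sm$n, mean = sm$mean_hat, sd = sm$sigma_hat,
      beneficial_fraction = sm$beneficial_fraction,
      excess_kurtosis = sm$excess_kurtosis,
      S_star = length(st$survivors))
    if (step %in% snapshot_dfe_at || step == 0L) {
      dfe_snapshots[[as.character(step)]] <- dfe
    }
    if (step >= max_steps) break

    res <- with_seed(derive_seed(seed, step + 1L), {
      out <- NULL
      for (try_ in seq_len(max_establish_tries)) {
        mut <- sample_successful_mutation(st, kinds = kinds, dX = dX,
                                          parent_weight = parent_weight,
                                          dfe = dfe)
        if (is.null(mut)) break
        r <- resolve_invasion(st, mut, policy = "sequential",
                              mutant_id = sprintf("m%d", step + 1L),
                              keep_post = TRUE)
        if (r$fate %in% c("COEXISTS", "REPLACES_PARENT")) { out <- r; break }
      }
      out
    })
    if (is.null(res)) {
      stop_reason <- "exhausted"
      break
    }
    step <- step + 1L
    post <- res$post_state

    dead <- c(res$extinct_ids, if (res$parent_extinct) res$parent_id)
    lineage$death_step[lineage$id %in% dead] <- step
    lineage <- rbind(lineage, data.frame(
      id = res$mutant_id, parent_id = res$parent_id,
      lineage_id = post$pool$lineage_id[post$pool$id == res$mutant_id],
      birth_step = step, death_step = NA_integer_,
      n_mutations = post$pool$n_mutations[post$pool$id == res$mutant_id],
      stringsAsFactors = FALSE))

    ab_mut <- c(ab_mut, res$f_parent)
    if (res$fate == "COEXISTS") ab_div <- c(ab_div, res$f_parent)
    if (res$n_extinct > 0) {
      ab_ext <- c(ab_ext, res$species$f_pre[res$species$extinct])
    }
    if (res$parent_extinct) ab_ext <- c(ab_ext, res$f_parent)

    events[[step]] <- data.frame(
      step = step, parent_id = res$parent_id, mutant_id = res$mutant_id,
      kind = res$kind, target = res$target, dX = dX, s_inv = res$s_inv,
      fate = res$fate, parent_extinct = res$parent_extinct,
      n_extinct = res$n_extinct,
      extinct_ids = paste(res$extinct_ids, collapse = ";"),
      f_parent_pre = res$f_parent, pre_S_star = res$pre_S_star,
      post_S_star = length(post$survivors),
      max_n_mutations = max(post$pool$n_mutations[post$survivors]),
      stringsAsFactors = FALSE)

    # carry only the living community forward; excluded strains contribute
    # nothing to the resource balance, so the restricted state is the same
    # equilibrium and needs no re-solve
    st <- subset_state(post)
    if (max(st$pool$n_mutations) >= max_mutations) {
      stop_reason <- "max_mutations"
    }
    if (stop_reason == "max_mutations") break
  }

  events <- if (length(events)) do.call(rbind, events) else NULL
  if (!is.null(events) && !(as.character(step) %in% names(dfe_snapshots))) {
    dfe_snapshots[[as.character(step)]] <-
      enumerate_dfe(st, kinds = kinds, dX = dX)
  }
  structure(list(
    events = events, lineage = lineage,
    dfe_stats = do.call(rbind, dfe_stats), dfe_snapshots = dfe_snapshots,
    abundance_at = list(mutation = ab_mut, diversification = ab_div,
                        extinction = ab_ext),
    initial_state = initial_state, final_state = st,
    stop_reason = stop_reason, n_steps = step,
    config = list(kinds = kinds, dX = dX, max_mutations = max_mutations,
                  max_steps = max_steps, seed = seed,
                  parent_weight = parent_weight)
  ), class = "cr_evolution")
}

#' @export
print.cr_evolution <- function(x, ...) {
  cat(sprintf(
    "<cr_evolution> %d successful mutations (%s); %d -> %d strains\n",
    x$n_steps, x$stop_reason,
    length(x$initial_state$survivors), length(x$final_state$survivors)))
  invisible(x)
}

# Alive mask at step t (strains born at or before t, not yet dead at t).
alive_at <- function(lineage, t) {
  lineage$birth_step <= t &
    (is.na(lineage$death_step) | lineage$death_step > t)
}

# Members of the branch rooted at `root` from step `from`: the root plus
# all descendants whose ancestry path stays inside the branch, excluding
# the subtree rooted at `exclude`.
branch_members <- function(lineage, root, exclude = NULL) {
  children <- split(lineage$id, lineage$parent_id)
  members <- character(0)
  queue <- root
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    members <- c(members, node)
    kids <- setdiff(children[[node]], exclude)
    queue <- c(queue, kids)
  }
  members
}

#' Lineage and diversification statistics of an evolution run
#'
#' Computes, from an [run_evolution()] log:
#'
#' * the survivor-count trajectory and the trajectory of "related" strains
#'   (strains sharing a surviving relative through one or more in-situ
#'   diversification events, i.e. members of founder lineages with at
#'   least two living strains);
#' * per-diversification coexistence durations: for every `COEXISTS` event
#'   the number of subsequent successful mutations until one of the two
#'   branches loses all members, right-censored at the end of the run,
#'   with a Kaplan-Meier maintenance curve;
#' * the fraction of mutation events resulting in coexistence, overall and
#'   per decile of evolutionary time;
#' * the abundance distributions at mutation, diversification and
#'   extinction events.
#'
#' @param log A `cr_evolution`.
#' @return List with `strain_counts` (data frame step / n_strains /
#'   n_related), `divergences` (data frame with `step`, `duration`,
#'   `censored`), `mean_coexistence_duration` (uncensored divergences
#'   only), `maintenance_km` (a [survival::survfit] object, or `NULL` if
#'   there are no divergences), `coexistence_fraction`,
#'   `decile_coexistence` (data frame), and `abundance_at`.
#' @export
lineage_statistics <- function(log) {
  lineage <- log$lineage
  T_end <- log$n_steps
  steps <- 0:T_end
  n_alive <- integer(length(steps))
  n_related <- integer(length(steps))
  for (i in seq_along(steps)) {
    al <- alive_at(lineage, steps[i])
    n_alive[i] <- sum(al)
    tab <- table(lineage$lineage_id[al])
    n_related[i] <- sum(al & lineage$lineage_id %in%
                          names(tab)[tab >= 2])
  }
  strain_counts <- data.frame(step = steps, n_strains = n_alive,
                              n_related = n_related)

  ev <- log$events
  div <- NULL
  km <- NULL
  mean_dur <- NA_real_
  if (!is.null(ev)) {
    co <- ev[ev$fate == "COEXISTS", , drop = FALSE]
    if (nrow(co) > 0) {
      durs <- numeric(nrow(co)); cens <- logical(nrow(co))
      for (i in seq_len(nrow(co))) {
        e <- co$step[i]
        bm <- branch_members(lineage, co$mutant_id[i])
        bp <- branch_members(lineage, co$parent_id[i],
                             exclude = co$mutant_id[i])
        ext_time <- function(members) {
          d <- lineage$death_step[lineage$id %in% members]
          if (any(is.na(d))) Inf else max(d)
        }
        tdie <- min(ext_time(bm), ext_time(bp))
        if (is.finite(tdie)) {
          durs[i] <- tdie - e; cens[i] <- FALSE
        } else {
          durs[i] <- T_end - e; cens[i] <- TRUE
        }
      }
      div <- data.frame(step = co$step, duration = durs, censored = cens)
      if (any(!cens)) mean_dur <- mean(durs[!cens])
      km <- survival::survfit(
        survival::Surv(time = durs, event = !cens) ~ 1)
    }
    dec <- cut(seq_len(nrow(ev)), breaks = 10, labels = FALSE)
    decile_coex <- data.frame(
      decile = 1:10,
      n = as.integer(tapply(ev$fate, dec, length)),
      coexistence_fraction = as.numeric(
        tapply(ev$fate == "COEXISTS", dec, mean)))
  } else {
    decile_coex <- NULL
  }
  list(strain_counts = strain_counts, divergences = div,
       mean_coexistence_duration = mean_dur, maintenance_km = km,
       coexistence_fraction = if (!is.null(ev)) mean(ev$fate == "COEXISTS")
                              else NA_real_,
       decile_coexistence = decile_coex,
       abundance_at = log$abundance_at)
}

#' Compare DFE snapshots along an evolution run
#'
#' Summarizes the full enumerated DFE stored at the requested steps:
#' moments, beneficial fraction, and excess kurtosis (0 for a Gaussian,
#' 3 for a two-tailed exponential), to quantify how the fitness landscape
#' deforms as mutations accumulate.
#'
#' @param log A `cr_evolution`.
#' @param at_steps Steps to compare (must have been snapshotted).
#' @return Data frame, one row per snapshot.
#' @export
dfe_snapshot_compare <- function(log, at_steps) {
  out <- lapply(at_steps, function(s) {
    key <- as.character(s)
    if (!key %in% names(log$dfe_snapshots)) {
      stop("no DFE snapshot stored at step ", s)
    }
    sm <- dfe_summary(log$dfe_snapshots[[key]])
    data.frame(step = s, n = sm$n, mean = sm$mean_hat, sd = sm$sigma_hat,
               beneficial_fraction = sm$beneficial_fraction,
               excess_kurtosis = sm$excess_kurtosis)
  })
  do.call(rbind, out)
}

#' Export a lineage forest as Newick-like text
#'
#' One line per founder lineage; node labels are strain ids and branch
#' lengths are measured in successful-mutation steps (tips run to their
#' death step, or to the end of the run if still alive).
#'
#' @param log A `cr_evolution`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of Newick strings, invisibly if written.
#' @export
lineage_newick <- function(log, path = NULL) {
  lineage <- log$lineage
  T_end <- log$n_steps
  children <- split(seq_len(nrow(lineage)), lineage$parent_id)
  node_str <- function(i) {
    id <- lineage$id[i]
    kids <- children[[id]]
    death <- lineage$death_step[i]
    len <- (if (is.na(death)) T_end else death) - lineage$birth_step[i]
    if (is.null(kids) || length(kids) == 0) {
      sprintf("%s:%d", id, len)
    } else {
      sprintf("(%s)%s:%d",
              paste(vapply(kids, node_str, character(1)), collapse = ","),
              id, len)
    }
  }
  roots <- which(is.na(lineage$parent_id) |
                   !(lineage$parent_id %in% lineage$id))
  lines <- vapply(roots, function(i) paste0(node_str(i), ";"), character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
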