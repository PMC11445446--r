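# Experiment driver: configs, seeding, run directories, and flat-file
# outputs (TSV tables + JSON manifests).

#' Experiment configuration
#'
#' Builds and validates a configuration for [run_experiment()].  The
#' configuration is a plain list and round-trips losslessly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param experiment One of `"assemble"`, `"dfe"`, `"firststep"`,
#'   `"evolve"`, `"theory"`.
#' @param R,R0 Pool dimensions.
#' @param niche_saturation,permissivity Calibration targets.
#' @param kinds Mutation kinds (where relevant).
#' @param dX Budget change.
#' @param cv Supply coefficient of variation (0 = uniform).
#' @param replicates Replicate communities / runs.
#' @param n_invasions Invasions for the `firststep` recipe.
#' @param max_mutations Stop rule for the `evolve` recipe.
#' @param policy Invasion policy.
#' @param seed Master seed.
#' @param scheme Sampling scheme.
#' @param calibration_reps Pilot replicates per calibration probe.
#' @return A validated `cr_config` list.
#' @export
experiment_config <- function(experiment, R = 200L, R0 = 40L,
                              niche_saturation = 0.9, permissivity = 0.1,
                              kinds = "knockout", dX = 0, cv = 0,
                              replicates = 10L, n_invasions = 100L,
                              max_mutations = 10L, policy = "sequential",
                              seed = 1L, scheme = "binary",
                              calibration_reps = 20L) {
  cfg <- list(experiment = experiment, R = as.integer(R), R0 = R0,
              niche_saturation = niche_saturation,
              permissivity = permissivity, kinds = kinds, dX = dX, cv = cv,
              replicates = as.integer(replicates),
              n_invasions = as.integer(n_invasions),
              max_mutations = as.integer(max_mutations), policy = policy,
              seed = as.integer(seed), scheme = scheme,
              calibration_reps = as.integer(calibration_reps))
  validate_config(cfg)
  structure(cfg, class = "cr_config")
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$experiment %in% c("assemble", "dfe", "firststep", "evolve",
                            "theory"),
      "experiment must be one of assemble/dfe/firststep/evolve/theory")
  chk(is.numeric(cfg$R) && cfg$R >= 2, "R must be an integer >= 2")
  chk(is.numeric(cfg$R0) && cfg$R0 >= 1 && cfg$R0 <= cfg$R,
      "R0 must satisfy 1 <= R0 <= R")
  chk(cfg$niche_saturation > 0 && cfg$niche_saturation <= 1,
      "niche_saturation must be in (0, 1]")
  chk(cfg$permissivity > 0 && cfg$permissivity <= 1,
      "permissivity must be in (0, 1]")
  chk(all(cfg$kinds %in% c("knockout", "knockin")),
      "kinds must be a subset of knockout/knockin")
  chk(cfg$cv >= 0, "cv must be non-negative")
  chk(cfg$replicates >= 1, "replicates must be >= 1")
  chk(cfg$policy %in% c("sequential", "reinvasion", "simultaneous"),
      "unknown policy")
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' @rdname experiment_config
#' @param cfg A `cr_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$kinds <- as.character(cfg$kinds)
  validate_config(cfg)
  structure(cfg, class = "cr_config")
}

# FNV-1a hash of a string (no external digest dependency); used only to
# fingerprint configurations in run manifests.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Serialize a community state to JSON
#'
#' Writes survivor ids, abundances, availabilities, excess availabilities,
#' KKT residuals and flags to a JSON file (and reads them back as a plain
#' list; the full pool is not round-tripped, use [write_pool()] for that).
#'
#' @param state A `cr_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state <- function(state, path) {
  jsonlite::write_json(list(
    survivor_ids = state$pool$id[state$survivors],
    f = state$f[state$survivors],
    h = state$h, g = state$g, h_bar = state$h_bar,
    residuals = as.list(state$residuals),
    degenerate = state$degenerate, tol = state$tol,
    S_star = length(state$survivors), R = state$env$R
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a trajectory from [integrate_dynamics()] as TSV
#'
#' @param traj Trajectory matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(format(as.data.frame(traj), digits = 12), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a canned experiment recipe
#'
#' Executes the configured recipe with per-replicate child seeds derived
#' deterministically from the master seed, and writes flat-file outputs to
#' `out_dir`: the exact configuration (`config.json`), a manifest with the
#' package version and a configuration fingerprint (`manifest.json`), and
#' recipe-specific TSV tables:
#'
#' * `assemble`: `assemblies.tsv` (replicate, S*, saturation, Std(g));
#' * `dfe`: `dfe.tsv` (all enumerated mutations of every replicate) and
#'   `dfe_summary.tsv` with the mean-field width prediction alongside;
#' * `firststep`: `invasions.tsv` (one row per established invasion) and
#'   `extinctions.json` (summary statistics);
#' * `evolve`: per-replicate `events_<k>.tsv`, `lineage_<k>.tsv` and
#'   `tree_<k>.nwk`, plus `evolve_summary.tsv`;
#' * `theory`: `theory_overlay.tsv`, simulated means with standard errors
#'   and the corresponding closed-form columns over a niche-saturation
#'   sweep.
#'
#' @param cfg A `cr_config`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
run_experiment <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(cfg, file.path(out_dir, "config.json"))
  env <- make_environment(cfg$R, mode = if (cfg$cv > 0) "cv" else "uniform",
                          cv = cfg$cv)
  cal <- calibrate_pool(cfg$niche_saturation, cfg$permissivity, cfg$R,
                        cfg$R0, env, scheme = cfg$scheme,
                        n_rep = cfg$calibration_reps, seed = cfg$seed)
  states <- function(n) {
    lapply(seq_len(n), function(k) {
      assemble_community(cfg$R, cfg$R0, cal$S, cal$std_X, env,
                         scheme = cfg$scheme,
                         seed = derive_seed(cfg$seed, 100000L + k))
    })
  }

  if (cfg$experiment == "assemble") {
    sts <- states(cfg$replicates)
    tab <- do.call(rbind, lapply(seq_along(sts), function(k) {
      st <- sts[[k]]
      data.frame(replicate = k, S = cal$S, std_X = cal$std_X,
                 S_star = length(st$survivors),
                 niche_saturation = length(st$survivors) / sum(st$consumed),
                 std_g = stats::sd(st$g[st$consumed]),
                 kkt_survivor = st$residuals[["survivor"]],
                 kkt_excluded = st$residuals[["excluded"]])
    }))
    write_tsv(tab, file.path(out_dir, "assemblies.tsv"))
  } else if (cfg$experiment == "dfe") {
    sts <- states(cfg$replicates)
    dfes <- lapply(seq_along(sts), function(k) {
      d <- enumerate_dfe(sts[[k]], kinds = cfg$kinds, dX = cfg$dX,
                         monoculture = cfg$cv > 0)
      d$replicate <- k
      d
    })
    dfe <- do.call(rbind, dfes)
    write_tsv(dfe, file.path(out_dir, "dfe.tsv"))
    Cc <- calibrate_C(cfg$R, cfg$R0, permissivity = cfg$permissivity,
                      seed = cfg$seed)
    S_star <- mean(vapply(sts, function(s) length(s$survivors), numeric(1)))
    par <- theory_params(cfg$R, cfg$R0, cal$S, S_star, C = Cc$C, env = env)
    pred <- predict_sigma_inv(par, mean(dfe$norm_d_alpha), dX = cfg$dX)
    sm <- dfe_summary(dfe)
    write_tsv(data.frame(
      n = sm$n, mean = sm$mean_hat, sd = sm$sigma_hat,
      beneficial_fraction = sm$beneficial_fraction,
      sigma_theory = pred$sigma_inv, C = Cc$C, S_star = S_star),
      file.path(out_dir, "dfe_summary.tsv"))
  } else if (cfg$experiment == "firststep") {
    sts <- states(cfg$replicates)
    res <- sample_invasions(sts, kinds = cfg$kinds, dX = cfg$dX,
                            n = cfg$n_invasions, seed = cfg$seed,
                            policy = cfg$policy)
    tab <- do.call(rbind, lapply(seq_along(res), function(k) {
      x <- res[[k]]
      data.frame(invasion = k, parent_id = x$parent_id, f_parent = x$f_parent,
                 kind = x$kind, target = x$target, dX = x$dX,
                 s_inv = x$s_inv, fate = x$fate, n_extinct = x$n_extinct,
                 extinct_ids = paste(x$extinct_ids, collapse = ";"),
                 pre_S_star = x$pre_S_star, stringsAsFactors = FALSE)
    }))
    write_tsv(tab, file.path(out_dir, "invasions.tsv"))
    fates <- vapply(res, function(x) x$fate, character(1))
    ok <- fates %in% c("COEXISTS", "REPLACES_PARENT")
    if (any(ok)) {
      xs <- extinction_statistics(res)
      jsonlite::write_json(list(
        n_invasions = xs$n_invasions, mean_extinctions = xs$mean_extinctions,
        p_zero = xs$p_zero, poisson_lambda = xs$poisson_lambda,
        p_coexist = mean(fates[ok] == "COEXISTS"),
        abundance_bins = xs$abundance_bins, fold_change = xs$fold_change),
        file.path(out_dir, "extinctions.json"),
        auto_unbox = TRUE, digits = NA, na = "null")
    }
  } else if (cfg$experiment == "evolve") {
    summ <- list()
    for (k in seq_len(cfg$replicates)) {
      st <- assemble_community(cfg$R, cfg$R0, cal$S, cal$std_X, env,
                               scheme = cfg$scheme,
                               seed = derive_seed(cfg$seed, 100000L + k))
      log <- run_evolution(st, kinds = cfg$kinds, dX = cfg$dX,
                           max_mutations = cfg$max_mutations,
                           seed = derive_seed(cfg$seed, 200000L + k))
      write_tsv(log$events, file.path(out_dir, sprintf("events_%d.tsv", k)))
      write_tsv(log$lineage, file.path(out_dir, sprintf("lineage_%d.tsv", k)))
      lineage_newick(log, file.path(out_dir, sprintf("tree_%d.nwk", k)))
      ls_ <- lineage_statistics(log)
      summ[[k]] <- data.frame(
        replicate = k, n_steps = log$n_steps, stop_reason = log$stop_reason,
        coexistence_fraction = ls_$coexistence_fraction,
        mean_coexistence_duration = ls_$mean_coexistence_duration,
        final_strains = length(log$final_state$survivors))
    }
    write_tsv(do.call(rbind, summ), file.path(out_dir, "evolve_summary.tsv"))
  } else if (cfg$experiment == "theory") {
    Cc <- calibrate_C(cfg$R, cfg$R0, permissivity = cfg$permissivity,
                      seed = cfg$seed)
    sats <- seq(0.2, 1.0, by = 0.2)
    rows <- lapply(sats, function(sat) {
      calx <- calibrate_pool(sat, cfg$permissivity, cfg$R, cfg$R0, env,
                             n_rep = cfg$calibration_reps, seed = cfg$seed)
      sts <- lapply(seq_len(cfg$replicates), function(k) {
        assemble_community(cfg$R, cfg$R0, calx$S, calx$std_X, env,
                           seed = derive_seed(cfg$seed, 300000L + k))
      })
      dfe <- do.call(rbind, lapply(sts, enumerate_dfe, kinds = "knockout",
                                   dX = cfg$dX))
      S_star <- mean(vapply(sts, function(s) length(s$survivors), numeric(1)))
      par <- theory_params(cfg$R, cfg$R0, calx$S, S_star, C = Cc$C,
                           env = env)
      co <- predict_coexistence(par, mean(dfe$norm_d_alpha), dX = cfg$dX)
      data.frame(
        target_saturation = sat, S = calx$S, std_X = calx$std_X,
        S_star_sim = S_star, sigma_sim = stats::sd(dfe$s_exact),
        sigma_theory = predict_sigma_inv(
          par, mean(dfe$norm_d_alpha))$sigma_inv,
        P_coex_closed = co$P_coex_closed, P_coex_quadrature = co$P_coex,
        C = Cc$C)
    })
    write_tsv(do.call(rbind, rows), file.path(out_dir, "theory_overlay.tsv"))
  }

  manifest <- list(
    package = "crevo",
    version = as.character(utils::packageVersion("crevo")),
    config_hash = fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)),
    seed = cfg$seed,
    calibration = list(S = cal$S, std_X = cal$std_X,
                       achieved_saturation = cal$achieved_saturation,
                       feasible = cal$feasible, path = cal$path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
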