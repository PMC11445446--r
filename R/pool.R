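# Random species pools: binary resource-usage sampling and serialization.
#
# A pool holds S strains on R resources.  Each strain mu has a log uptake
# budget X_mu and a consumption strategy alpha_mu on the resource simplex;
# its uptake rates are r_mu,i = exp(X_mu) * alpha_mu,i.

#' Sample a random species pool
#'
#' Draws `S` strains for an environment with `R` resources.  Under the
#' default binary scheme each strain uses each resource independently with
#' probability `R0 / R`, splits its consumption strategy `alpha` uniformly
#' (equal shares) over the used set, and draws its log uptake budget
#' `X ~ Normal(0, std_X^2)`.  Strains that sample an empty resource set are
#' redrawn, so every strain uses at least one resource.  The alternate
#' `"dirichlet"` scheme draws `alpha` from a symmetric Dirichlet over all `R`
#' resources (concentration `R0`-matched so the effective participation
#' ratio is comparable); it exercises the same interface and downstream code.
#'
#' `X` is centered at zero: the relative-abundance dynamics are covariant
#' under a common shift of all budgets, so only the spread `std_X` matters.
#'
#' @param R Number of resources.
#' @param R0 Expected number of resources used per strain (`1 <= R0 <= R`).
#' @param S Number of strains to draw (`S >= 1`).
#' @param std_X Standard deviation of the log uptake budget.
#' @param scheme Sampling scheme, `"binary"` (default) or `"dirichlet"`.
#' @param seed Optional integer seed; pools are bit-reproducible given a seed.
#' @return An object of class `cr_pool`: list with `R`, `R0`, `S`, `std_X`,
#'   `scheme`, `seed`, `id`, `lineage_id`, `parent_id`, `n_mutations`,
#'   budget vector `X`, and the `S x R` strategy matrix `alpha` (rows on the
#'   simplex).
#' @export
#' @examples
#' pool <- sample_pool(R = 20, R0 = 5, S = 10, std_X = 0.1, seed = 1)
#' rowSums(pool$alpha) # all 1
sample_pool <- function(R, R0, S, std_X, scheme = c("binary", "dirichlet"),
                        seed = NULL) {
  scheme <- match.arg(scheme)
  R <- as.integer(R); S <- as.integer(S)
  if (R0 < 1 || R0 > R) stop("R0 must satisfy 1 <= R0 <= R")
  if (S < 1) stop("S must be at least 1")
  if (std_X < 0) stop("std_X must be non-negative")
  with_seed(seed, {
    alpha <- matrix(0, S, R)
    if (scheme == "binary") {
      use <- matrix(stats::runif(S * R) < R0 / R, S, R)
      empty <- which(rowSums(use) == 0L)
      while (length(empty) > 0) { # resample empty supports, never clip
        use[empty, ] <- stats::runif(length(empty) * R) < R0 / R
        empty <- empty[rowSums(use[empty, , drop = FALSE]) == 0L]
      }
      alpha <- use / rowSums(use)
    } else {
      # symmetric Dirichlet over all R resources, concentration R0/R
      gm <- matrix(stats::rgamma(S * R, shape = R0 / R, rate = 1), S, R)
      bad <- which(rowSums(gm) == 0)
      while (length(bad) > 0) {
        gm[bad, ] <- stats::rgamma(length(bad) * R, shape = R0 / R, rate = 1)
        bad <- bad[rowSums(gm[bad, , drop = FALSE]) == 0]
      }
      alpha <- gm / rowSums(gm)
    }
    X <- if (std_X > 0) stats::rnorm(S, 0, std_X) else numeric(S)
    new_pool(R = R, R0 = R0, std_X = std_X, scheme = scheme, seed = seed,
             id = paste0("s", seq_len(S)),
             lineage_id = paste0("s", seq_len(S)),
             parent_id = rep(NA_character_, S),
             n_mutations = integer(S), X = X, alpha = alpha)
  })
}

new_pool <- function(R, R0, std_X, scheme, seed, id, lineage_id, parent_id,
                     n_mutations, X, alpha) {
  structure(list(
    R = as.integer(R), R0 = R0, S = length(id), std_X = std_X,
    scheme = scheme, seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    id = id, lineage_id = lineage_id, parent_id = parent_id,
    n_mutations = as.integer(n_mutations), X = as.numeric(X),
    alpha = alpha
  ), class = "cr_pool")
}

#' @export
print.cr_pool <- function(x, ...) {
  cat(sprintf(
    "<cr_pool> S = %d strains, R = %d resources, R0 = %g, std_X = %g, scheme = %s\n",
    x$S, x$R, x$R0, x$std_X, x$scheme))
  invisible(x)
}

#' Subset a species pool
#'
#' @param x A `cr_pool`.
#' @param i Strain indices (integer or logical).
#' @param ... Unused.
#' @return A `cr_pool` restricted to the selected strains.
#' @export
`[.cr_pool` <- function(x, i, ...) {
  new_pool(R = x$R, R0 = x$R0, std_X = x$std_X, scheme = x$scheme,
           seed = x$seed, id = x$id[i], lineage_id = x$lineage_id[i],
           parent_id = x$parent_id[i], n_mutations = x$n_mutations[i],
           X = x$X[i], alpha = x$alpha[i, , drop = FALSE])
}

#' Uptake-rate matrix of a pool
#'
#' Returns the `S x R` matrix of uptake rates `r_mu,i = exp(X_mu) alpha_mu,i`.
#'
#' @param pool A `cr_pool`.
#' @return Numeric matrix.
#' @export
pool_uptake <- function(pool) {
  exp(pool$X) * pool$alpha
}

#' Append a strain to a pool
#'
#' @param pool A `cr_pool`.
#' @param id,lineage_id,parent_id Identifiers for the new strain.
#' @param X Log uptake budget.
#' @param alpha Strategy vector (length `R`, on the simplex).
#' @param n_mutations Accumulated mutation count.
#' @return A `cr_pool` with `S + 1` strains.
#' @export
pool_append <- function(pool, id, lineage_id, parent_id, X, alpha,
                        n_mutations = 0L) {
  stopifnot(length(alpha) == pool$R)
  new_pool(R = pool$R, R0 = pool$R0, std_X = pool$std_X, scheme = pool$scheme,
           seed = pool$seed, id = c(pool$id, id),
           lineage_id = c(pool$lineage_id, lineage_id),
           parent_id = c(pool$parent_id, parent_id),
           n_mutations = c(pool$n_mutations, as.integer(n_mutations)),
           X = c(pool$X, X), alpha = rbind(pool$alpha, alpha))
}

#' Write / read a pool as delimited text plus a JSON sidecar
#'
#' The strain table (one row per strain: id, lineage_id, parent_id,
#' n_mutations, X, then the `R` strategy entries) is written as
#' tab-separated text at `path`; the pool metadata (R, R0, S, std_X, scheme,
#' seed) goes to `<path>.json`.
#'
#' @param pool A `cr_pool`.
#' @param path Output file path for the strain table.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  tab <- data.frame(id = pool$id, lineage_id = pool$lineage_id,
                    parent_id = pool$parent_id,
                    n_mutations = pool$n_mutations, X = pool$X,
                    stringsAsFactors = FALSE)
  amat <- pool$alpha
  colnames(amat) <- paste0("alpha_", seq_len(pool$R))
  utils::write.table(cbind(tab, amat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(R = pool$R, R0 = pool$R0, S = pool$S, std_X = pool$std_X,
               scheme = pool$scheme, seed = pool$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  acol <- grep("^alpha_", names(tab))
  new_pool(R = meta$R, R0 = meta$R0, std_X = meta$std_X, scheme = meta$scheme,
           seed = if (is.null(meta$seed) || is.na(meta$seed)) NULL else meta$seed,
           id = as.character(tab$id), lineage_id = as.character(tab$lineage_id),
           parent_id = as.character(tab$parent_id),
           n_mutations = tab$n_mutations, X = tab$X,
           alpha = as.matrix(tab[, acol]))
}
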