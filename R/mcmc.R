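#' Run the Metropolis-within-Gibbs sampler for the mating model
#'
#' Samples the posterior of the exponential-power kernel parameters `(a, b)`,
#' the log-fecundity variance `sigma2` and the per-candidate relative male
#' fecundities `F_j`, given fixed within-plot paternity counts. Proposals are
#' log-scale random walks for `a`, `b` and each `log F_j` (scales adapted
#' towards 20-40% acceptance during burn-in, frozen afterwards); `sigma2` is
#' updated by an independence Metropolis-Hastings step using the Gamma
#' conditional of the precision at the current mean as proposal. Chains are
#' initialised over-dispersed by drawing `a` and `b` from broad log-uniform
#' ranges. With `config$seed` set, runs are exactly reproducible.
#'
#' @param data a `mating_data` object.
#' @param config an [analysis_config()] (iterations, burn-in, thinning,
#'   chains, priors, seed).
#' @return An object of class `pollen_mcmc`: list with `chains` (one matrix
#'   per chain, `iterations/thin` rows, columns `a`, `b`, `sigma2` and
#'   `F_<candidate>`), `accept` (per-chain acceptance rates), `data`,
#'   `config`.
#' @export
run_mcmc <- function(data, config = analysis_config()) {
  stopifnot(inherits(data, "mating_data"), config$chains >= 2)
  if (!is.null(config$seed)) set.seed(config$seed)
  J <- length(data$candidates)
  chains <- vector("list", config$chains)
  accept <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    fit <- NULL
    for (attempt in 1:25) {
      a0 <- exp(runif(1, log(1e-4), log(0.1)))
      b0 <- exp(runif(1, log(0.3), log(3)))
      ok <- tryCatch({
        fit <- mcmc_chain_cpp(
          data$n, data$dist, data$self,
          iterations = config$iterations, burnin = config$burnin,
          thin = config$thin, a_init = a0, b_init = b0,
          sigma2_init = 1, theta_init = rep(0, J),
          prior_shape = config$prior_shape, prior_rate = config$prior_rate
        )
        TRUE
      }, error = function(e) {
        if (grepl("non-finite likelihood", conditionMessage(e))) FALSE else stop(e)
      })
      if (ok) break
      if (attempt == 25) stop("could not find finite-posterior initial values")
    }
    dr <- fit$draws
    colnames(dr) <- c("a", "b", "sigma2", paste0("F_", data$candidates))
    chains[[ch]] <- dr
    accept[[ch]] <- fit$accept
  }
  structure(list(chains = chains, accept = accept,
                 data = data, config = config),
            class = "pollen_mcmc")
}

#' @export
print.pollen_mcmc <- function(x, ...) {
  cat(sprintf("MCMC draws: %d chains x %d retained iterations x %d parameters\n",
              length(x$chains), nrow(x$chains[[1]]), ncol(x$chains[[1]])))
  invisible(x)
}

# Stack retained draws of one or more named columns across chains
pooled_draws <- function(samples, cols) {
  do.call(rbind, lapply(samples$chains, function(m) m[, cols, drop = FALSE]))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classical between/within-chain variance diagnostic: with `m` chains of
#' length `n`, `W` the mean within-chain variance and `B/n` the variance of
#' the chain means, \deqn{\hat R = \sqrt{((n-1)/n\,W + B/n) / W}.}
#' Values near 1 indicate convergence.
#'
#' @param chains a `pollen_mcmc` object, or a list (length >= 2) of equal-length
#'   numeric vectors or of matrices with matching columns.
#' @return Named numeric vector of `R-hat` per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "pollen_mcmc")) chains <- chains$chains
  stopifnot(is.list(chains))
  if (length(chains) < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains")
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1, dimnames = list(NULL, "par")) else ch
  })
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 2) stop("chains must have length >= 2")
  m <- length(chains)
  params <- colnames(chains[[1]])
  out <- vapply(seq_along(params), function(p) {
    x <- vapply(chains, function(ch) ch[, p], numeric(n))   # n x m
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(out) <- params
  out
}
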