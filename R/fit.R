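#' Fit the Bayesian mating model
#'
#' The package's central fitting function. Combines a paternity table and a
#' tree map into the mating-model data ([mating_data()]), samples the
#' posterior of the dispersal kernel `(a, b)`, the fecundity log-variance
#' `sigma2` and the per-candidate fecundities `F_j` by MCMC ([run_mcmc()]),
#' and attaches convergence diagnostics plus per-draw derived functionals
#' (mean dispersal distance `delta` and donor-density ratio
#' `d_obs/d_ep = exp(sigma2)`).
#'
#' @param paternity a `paternity_table` from [assign_paternity()], or a
#'   ready-made `mating_data` object.
#' @param tree_map a [tree_map] (ignored when `paternity` is already a
#'   `mating_data`).
#' @param season season label; defaults to the paternity table's season.
#' @param config an [analysis_config()].
#' @return An object of class `pollen_mating_model` with components
#'   `samples` (a `pollen_mcmc`), `data`, `rhat` (Gelman-Rubin for `a`, `b`,
#'   `sigma2`), `derived` (per-draw `delta`, `sigma`, `d_ratio`), `config`.
#'   Methods: [print()], [summary()], [coef()], [plot()], [predict()],
#'   [simulate()], [posterior_summary()].
#' @examples
#' \donttest{
#' pop <- generate_population(n_adults = 60, seed = 1)
#' sim <- simulate_mating(pop, season = "2005", mothers = 4,
#'                        seeds_per_mother = 30, seed = 2)
#' md <- true_mating_data(pop, sim)
#' fit <- pollen_mating_model(md, config = analysis_config(
#'   iterations = 3000, burnin = 1000, chains = 2, seed = 3))
#' summary(fit)
#' }
#' @export
pollen_mating_model <- function(paternity, tree_map = NULL, season = NULL,
                                config = analysis_config()) {
  data <- if (inherits(paternity, "mating_data")) {
    paternity
  } else {
    if (is.null(tree_map)) stop("tree_map is required with a paternity table")
    mating_data(paternity, tree_map, season)
  }
  if (sum(data$n) == 0) {
    warning("no within-plot paternity counts; the posterior equals the prior")
  }
  samples <- run_mcmc(data, config)
  ab <- pooled_by_chain(samples, c("a", "b", "sigma2"))
  rhat <- gelman_rubin(ab)
  a <- pooled_draws(samples, "a")[, 1]
  b <- pooled_draws(samples, "b")[, 1]
  s2 <- pooled_draws(samples, "sigma2")[, 1]
  derived <- data.frame(
    delta = mean_dispersal_distance(a, b),
    sigma = sqrt(s2),
    d_ratio = exp(s2)
  )
  structure(list(samples = samples, data = data, rhat = rhat,
                 derived = derived, config = config,
                 call = match.call()),
            class = "pollen_mating_model")
}

pooled_by_chain <- function(samples, cols) {
  lapply(samples$chains, function(m) m[, cols, drop = FALSE])
}

#' @export
print.pollen_mating_model <- function(x, digits = 4, ...) {
  cat("Bayesian mating model (exponential-power kernel, log-normal fecundity)\n")
  cat(sprintf("  %d mothers, %d candidate donors, %d within-plot seeds\n",
              length(x$data$mothers), length(x$data$candidates), sum(x$data$n)))
  cm <- coef(x)
  cat(sprintf("  posterior medians: a = %.*g, b = %.*g, sigma = %.*g, delta = %.1f m\n",
              digits, cm[["a"]], digits, cm[["b"]], digits, cm[["sigma"]],
              median(x$derived$delta)))
  cat(sprintf("  Gelman-Rubin R-hat: a %.3f, b %.3f, sigma2 %.3f\n",
              x$rhat[["a"]], x$rhat[["b"]], x$rhat[["sigma2"]]))
  invisible(x)
}

#' @export
coef.pollen_mating_model <- function(object, ...) {
  c(a = median(pooled_draws(object$samples, "a")),
    b = median(pooled_draws(object$samples, "b")),
    sigma = median(object$derived$sigma))
}

#' Posterior quantiles of model parameters and derived quantities
#'
#' Empirical 2.5/25/50/75/97.5% quantiles of the retained draws, pooled over
#' chains. Derived quantities are computed per draw and then summarised
#' (never evaluated at parameter medians): `delta` from the closed form
#' `Gamma(3/b)/(a Gamma(2/b))`, `d_ratio` as `exp(sigma2)`, and the
#' pollen-cloud functionals `N_ep`, `N_epi`, `rho` from the per-draw mating
#' probabilities.
#'
#' @param samples a `pollen_mating_model` (or `pollen_mcmc`) object.
#' @param quantity one of `"a"`, `"b"`, `"sigma"`, `"sigma2"`, `"delta"`,
#'   `"d_ratio"`, `"F"`, `"N_ep"`, `"N_epi"`, `"rho"`.
#' @return For scalar quantities, a named vector of the five quantiles; for
#'   per-mother (`N_epi`, `rho`) or per-candidate (`F`) quantities, a matrix
#'   with one row per unit.
#' @export
posterior_summary <- function(samples, quantity = "delta") {
  if (!inherits(samples, c("pollen_mating_model", "pollen_mcmc"))) {
    stop("samples must be a pollen_mating_model or pollen_mcmc object")
  }
  fit <- samples
  if (inherits(fit, "pollen_mcmc")) fit <- list(samples = samples, data = samples$data)
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  qn <- function(v) quantile(v, probs, names = TRUE)
  sc <- fit$samples
  derived <- function(what) {
    if (!is.null(fit$derived)) return(fit$derived[[what]])
    s2 <- pooled_draws(sc, "sigma2")[, 1]
    switch(what,
           sigma = sqrt(s2),
           d_ratio = exp(s2),
           delta = mean_dispersal_distance(pooled_draws(sc, "a")[, 1],
                                           pooled_draws(sc, "b")[, 1]))
  }
  switch(quantity,
    a = qn(pooled_draws(sc, "a")[, 1]),
    b = qn(pooled_draws(sc, "b")[, 1]),
    sigma2 = qn(pooled_draws(sc, "sigma2")[, 1]),
    sigma = qn(derived("sigma")),
    delta = qn(derived("delta")),
    d_ratio = qn(derived("d_ratio")),
    F = {
      f <- pooled_draws(sc, grep("^F_", colnames(sc$chains[[1]]), value = TRUE))
      t(apply(f, 2, qn))
    },
    N_ep = qn(donor_structure(fit)$N_ep),
    N_epi = t(apply(donor_structure(fit)$N_epi, 2, qn)),
    rho = t(apply(donor_structure(fit)$rho, 2, qn)),
    stop("unknown quantity: ", quantity)
  )
}

#' Per-draw pollen-cloud functionals of a fitted mating model
#'
#' For every retained posterior draw, computes the outcross pollen-cloud
#' shares and from them the global effective number of pollen donors `N_ep`
#' (seed-count-weighted over mothers), the per-mother `N_epi`, and the
#' self-pollen share `rho_i` (mother included as a donor at distance zero).
#' Results are cached inside the fit object's environment on first use.
#'
#' @param fit a `pollen_mating_model` (or the list form used internally).
#' @return List with `N_ep` (vector over draws), `N_epi` and `rho` (draws x
#'   mothers matrices).
#' @export
donor_structure <- function(fit) {
  sc <- fit$samples
  data <- fit$data
  a <- pooled_draws(sc, "a")[, 1]
  b <- pooled_draws(sc, "b")[, 1]
  f <- pooled_draws(sc, grep("^F_", colnames(sc$chains[[1]]), value = TRUE))
  n_i <- data$n_analysed   # seeds analysed per mother (N_ep pooling weights)
  res <- derived_cloud_cpp(a, b, f, data$dist, data$self, n_i)
  colnames(res$N_epi) <- colnames(res$rho) <- data$mothers
  res
}

#' @export
summary.pollen_mating_model <- function(object, donors = TRUE, ...) {
  rows <- c("a", "b", "delta", "sigma", "d_ratio", if (donors) "N_ep")
  tab <- do.call(rbind, lapply(rows, function(q) posterior_summary(object, q)))
  rownames(tab) <- rows
  structure(list(quantiles = tab, rhat = object$rhat,
                 n_draws = sum(vapply(object$samples$chains, nrow, integer(1)))),
            class = "summary.pollen_mating_model")
}

#' @export
print.summary.pollen_mating_model <- function(x, digits = 4, ...) {
  cat("Posterior quantiles (", x$n_draws, " pooled draws)\n", sep = "")
  print(round(x$quantiles, digits))
  cat("Gelman-Rubin R-hat:\n")
  print(round(x$rhat, 3))
  invisible(x)
}

#' @export
plot.pollen_mating_model <- function(x, which = c("kernel", "trace"),
                                     max_distance = 500, ...) {
  which <- match.arg(which)
  if (which == "kernel") {
    r <- seq(0, max_distance, length.out = 200)
    a <- pooled_draws(x$samples, "a")[, 1]
    b <- pooled_draws(x$samples, "b")[, 1]
    idx <- round(seq(1, length(a), length.out = min(500, length(a))))
    dens <- vapply(idx, function(i) kernel_density(r, a[i], b[i]),
                   numeric(length(r)))
    med <- apply(dens, 1, median)
    lo <- apply(dens, 1, quantile, 0.25)
    hi <- apply(dens, 1, quantile, 0.75)
    graphics::plot(r, med, type = "l", lwd = 2,
                   xlab = "distance (m)", ylab = "pollen density (1/m^2)",
                   main = "Posterior pollen dispersal kernel", ...)
    graphics::lines(r, lo, lty = 3)
    graphics::lines(r, hi, lty = 3)
  } else {
    op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
    on.exit(graphics::par(op))
    for (p in c("a", "b", "sigma2")) {
      graphics::matplot(vapply(x$samples$chains, function(m) m[, p],
                               numeric(nrow(x$samples$chains[[1]]))),
                        type = "l", lty = 1, ylab = p, xlab = "")
    }
  }
  invisible(x)
}

#' @export
predict.pollen_mating_model <- function(object, distance = seq(0, 500, by = 10), ...) {
  a <- pooled_draws(object$samples, "a")[, 1]
  b <- pooled_draws(object$samples, "b")[, 1]
  idx <- round(seq(1, length(a), length.out = min(2000, length(a))))
  dens <- vapply(idx, function(i) kernel_density(distance, a[i], b[i]),
                 numeric(length(distance)))
  data.frame(distance = distance,
             median = apply(dens, 1, median),
             q2.5 = apply(dens, 1, quantile, 0.025),
             q97.5 = apply(dens, 1, quantile, 0.975))
}

#' Posterior-predictive simulation of within-plot paternity counts
#'
#' Draws parameter vectors from the retained posterior and simulates new
#' multinomial within-plot paternity counts for each mother at her observed
#' within-plot seed total.
#'
#' @param object a `pollen_mating_model`.
#' @param nsim number of simulated count tables.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of `nsim` mothers x candidates count matrices.
#' @export
simulate.pollen_mating_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sc <- object$samples
  a <- pooled_draws(sc, "a")[, 1]
  b <- pooled_draws(sc, "b")[, 1]
  f <- pooled_draws(sc, grep("^F_", colnames(sc$chains[[1]]), value = TRUE))
  data <- object$data
  idx <- sample.int(length(a), nsim, replace = TRUE)
  lapply(idx, function(i) {
    pi <- mating_probabilities(a[i], b[i], data, fecundity = f[i, ])
    out <- data$n * 0L
    for (r in seq_along(data$mothers)) {
      if (data$A[r] > 0) out[r, ] <- rmultinom(1, data$A[r], pi[r, ])[, 1]
    }
    out
  })
}
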