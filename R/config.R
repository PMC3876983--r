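#' Analysis configuration
#'
#' Bundles the tunable settings of the paternity-assignment and MCMC stages.
#' Defaults follow common practice for microsatellite paternity studies of
#' canopy trees: a 1% mistyping rate, at most two tolerated locus mismatches,
#' a 10,000-offspring Delta-criterion simulation, and 60,000 MCMC iterations
#' after a 10,000-iteration burn-in, thinned by 3, over 3 chains.
#'
#' @param season season label (character) the analysis refers to; `NULL` lets
#'   downstream functions pick the season recorded in the data.
#' @param mistyping_rate per-locus genotype mistyping rate `e` used in the LOD
#'   likelihood and in the Delta simulation; in `[0, 1)`.
#' @param max_mismatch maximum number of mismatching loci tolerated before the
#'   best candidate is declared an outside-plot (immigrant) father.
#' @param delta_sim number of simulated offspring used to calibrate the
#'   critical Delta (gap between best and second-best LOD).
#' @param delta_candidates number of paternal candidates in the Delta
#'   simulation; `NULL` (default) uses the size of the actual candidate set.
#' @param confidence assignment confidence level gating Delta (strict 0.95 by
#'   default; 0.80 is the customary relaxed level).
#' @param iterations,burnin,thin,chains MCMC run length (post burn-in
#'   iterations), burn-in length, thinning interval and number of chains.
#' @param prior_shape,prior_rate shape and rate of the Gamma priors placed on
#'   the kernel parameters `a`, `b` and on the fecundity log-variance
#'   precision `1/sigma^2`.
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' analysis_config(season = "2005", iterations = 2000, burnin = 500)
#' @export
analysis_config <- function(season = NULL,
                            mistyping_rate = 0.01,
                            max_mismatch = 2,
                            delta_sim = 10000,
                            delta_candidates = NULL,
                            confidence = 0.95,
                            iterations = 60000,
                            burnin = 10000,
                            thin = 3,
                            chains = 3,
                            prior_shape = 0.001,
                            prior_rate = 0.001,
                            seed = NULL) {
  stopifnot(
    is.numeric(mistyping_rate), length(mistyping_rate) == 1,
    mistyping_rate >= 0, mistyping_rate < 1,
    max_mismatch >= 0,
    delta_sim >= 1,
    is.null(delta_candidates) || delta_candidates >= 2,
    confidence > 0, confidence < 1,
    iterations > 0, burnin >= 0, iterations > 0,
    thin >= 1, chains >= 2,
    prior_shape > 0, prior_rate > 0
  )
  if (!(iterations > 0 && burnin >= 0)) stop("iterations must exceed 0 and burnin be >= 0")
  cfg <- list(
    season = season,
    mistyping_rate = mistyping_rate,
    max_mismatch = as.integer(max_mismatch),
    delta_sim = as.integer(delta_sim),
    delta_candidates = if (is.null(delta_candidates)) NULL else as.integer(delta_candidates),
    confidence = confidence,
    iterations = as.integer(iterations),
    burnin = as.integer(burnin),
    thin = as.integer(thin),
    chains = as.integer(chains),
    prior_shape = prior_shape,
    prior_rate = prior_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  season: %s  mistyping e: %g  max mismatches: %d\n",
              if (is.null(x$season)) "<from data>" else x$season,
              x$mistyping_rate, x$max_mismatch))
  cat(sprintf("  Delta simulation: %d offspring x %s candidates, confidence %.2f\n",
              x$delta_sim,
              if (is.null(x$delta_candidates)) "<candidate-set size>" else x$delta_candidates,
              x$confidence))
  cat(sprintf("  MCMC: %d iterations + %d burn-in, thin %d, %d chains\n",
              x$iterations, x$burnin, x$thin, x$chains))
  invisible(x)
}
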