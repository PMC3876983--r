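#' Write fitted-model outputs to a directory
#'
#' Emits (i) the thinned posterior draws as delimited text (one row per
#' retained iteration per chain, with a chain id column), (ii) a per-parameter
#' summary table with the 2.5/25/50/75/97.5% posterior quantiles, (iii) when a
#' paternity table is supplied, the per-mother mating-system table, and (iv)
#' the parameter summary again as a machine-readable JSON document.
#'
#' @param fit a `pollen_mating_model`.
#' @param outdir output directory (created if absent).
#' @param paternity optional `paternity_table` whose mating-system table is
#'   written alongside.
#' @return Invisibly, a named vector of the written file paths.
#' @export
write_results <- function(fit, outdir, paternity = NULL) {
  stopifnot(inherits(fit, "pollen_mating_model"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory ", outdir)
  }
  chains <- fit$samples$chains
  draws <- do.call(rbind, lapply(seq_along(chains), function(ch) {
    data.frame(chain = ch, iteration = seq_len(nrow(chains[[ch]])),
               as.data.frame(chains[[ch]]), check.names = FALSE)
  }))
  paths <- c(draws = file.path(outdir, "draws.csv"),
             summary = file.path(outdir, "params_summary.csv"),
             json = file.path(outdir, "params_summary.json"))
  write.csv(draws, paths[["draws"]], row.names = FALSE)

  sm <- summary(fit)
  tab <- data.frame(parameter = rownames(sm$quantiles), sm$quantiles,
                    check.names = FALSE, row.names = NULL)
  names(tab) <- c("parameter", "2.50%", "25%", "50%", "75%", "97.50%")
  tab$R_hat <- fit$rhat[match(tab$parameter, names(fit$rhat))]
  write.csv(tab, paths[["summary"]], row.names = FALSE)

  jsonlite::write_json(
    list(quantiles = split(as.data.frame(sm$quantiles), tab$parameter),
         rhat = as.list(fit$rhat), n_draws = sm$n_draws),
    paths[["json"]], auto_unbox = TRUE, digits = NA)

  if (!is.null(paternity)) {
    paths <- c(paths, mating_system = file.path(outdir, "mating_system.csv"))
    write.csv(paternity$mothers, paths[["mating_system"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Published reference estimates for the Pasoh Shorea maxwelliana plot
#'
#' Reference values from a 40-ha (500 x 800 m) plot of *Shorea maxwelliana*
#' at the Pasoh Forest Reserve, observed over a sporadic (2002) and a mass
#' (2005) general-flowering season: the per-mother mating-system table
#' (seeds analysed, immigration, selfing, within-plot allogamy, donor
#' counts) and the posterior summaries of the fitted mating model (kernel
#' parameters, mean dispersal distance, fecundity variance, donor-density
#' ratio, effective donor numbers). Shipped as plain-text tables and used by
#' the package's internal-consistency checks.
#'
#' @param table `"mating_system"` or `"posterior"`.
#' @return A data.frame.
#' @export
pasoh_reference <- function(table = c("mating_system", "posterior")) {
  table <- match.arg(table)
  f <- switch(table,
              mating_system = "pasoh_mating_system.csv",
              posterior = "pasoh_posterior_summaries.csv")
  path <- system.file("extdata", f, package = "pollenflow", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$season <- as.character(df$season)
  df
}
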