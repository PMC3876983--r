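#' Assemble the data object for the Bayesian mating model
#'
#' Packs together everything the multinomial mating likelihood needs: the
#' mothers with their within-plot paternity counts `n_ij` (from a paternity
#' table), the season's candidate donors with coordinates, the mother-donor
#' distance matrix, and the fixed per-mother selfing and immigration rates
#' (`s_i`, `m_i`), which enter the analysis as known constants, not model
#' parameters.
#'
#' @param paternity a `paternity_table` from [assign_paternity()].
#' @param tree_map a [tree_map] containing every mother and candidate.
#' @param season season label; defaults to the paternity table's season.
#' @return An object of class `mating_data`: list with `mothers`, `candidates`
#'   (ids), `n` (M x J count matrix), `dist` (M x J metres), `self` (M x J
#'   logical, candidate is the mother), `A` (within-plot seed totals), `s`,
#'   `m`.
#' @export
mating_data <- function(paternity, tree_map, season = NULL) {
  stopifnot(inherits(paternity, "paternity_table"))
  if (is.null(season)) season <- attr(paternity, "season")
  cand <- candidate_ids(tree_map, season)
  counts <- paternity$counts
  extra <- setdiff(colnames(counts), cand)
  if (length(extra)) stop("paternity counts name non-candidate father(s): ",
                          paste(extra, collapse = ", "))
  n <- matrix(0L, nrow(counts), length(cand),
              dimnames = list(rownames(counts), cand))
  n[, colnames(counts)] <- counts
  mothers <- rownames(n)
  ms <- paternity$mothers
  ms <- ms[match(mothers, ms$mother_id), ]
  new_mating_data(
    mothers = mothers, candidates = cand,
    dist = tree_distances(tree_map, mothers, cand),
    n = n, s = ms$s, m = ms$m, n_analysed = ms$A
  )
}

#' Low-level constructor for mating-model data
#'
#' Used by the synthetic-data generator and in tests; [mating_data()] is the
#' high-level route from a paternity table.
#'
#' @param mothers,candidates character id vectors (length M and J).
#' @param dist M x J distance matrix in metres.
#' @param n M x J integer matrix of within-plot paternity counts.
#' @param s,m per-mother selfing and immigration rates (fixed).
#' @param self optional M x J logical matrix marking the mother's own column;
#'   derived from ids when omitted.
#' @return A `mating_data` object.
#' @export
new_mating_data <- function(mothers, candidates, dist, n,
                            s = rep(0, length(mothers)),
                            m = rep(0, length(mothers)),
                            self = NULL, n_analysed = NULL) {
  M <- length(mothers); J <- length(candidates)
  stopifnot(all(dim(dist) == c(M, J)), all(dim(n) == c(M, J)),
            length(s) == M, length(m) == M, all(n >= 0),
            all(dist >= 0), all(s >= 0), all(m >= 0), all(s + m <= 1 + 1e-9))
  if (is.null(self)) self <- outer(mothers, candidates, "==")
  stopifnot(all(dim(self) == c(M, J)))
  if (any(n[self] > 0)) stop("self column of a mother carries within-plot counts")
  dimnames(n) <- dimnames(dist) <- dimnames(self) <- list(mothers, candidates)
  if (is.null(n_analysed)) {
    n_analysed <- ifelse(s + m < 1, rowSums(n) / pmax(1 - s - m, 1e-12), rowSums(n))
  }
  structure(list(mothers = mothers, candidates = candidates,
                 dist = dist, n = n, self = self,
                 A = rowSums(n), n_analysed = as.numeric(n_analysed),
                 s = as.numeric(s), m = as.numeric(m)),
            class = "mating_data")
}

#' @export
print.mating_data <- function(x, ...) {
  cat(sprintf("Mating data: %d mothers x %d candidate donors, %d within-plot seeds\n",
              length(x$mothers), length(x$candidates), sum(x$n)))
  invisible(x)
}

#' Expected within-plot mating probabilities
#'
#' The probability that an allogamous within-plot seed of mother `i` is sired
#' by candidate `j`: fecundity-weighted, kernel-weighted and normalised over
#' the mother's candidates (excluding the mother herself),
#' \deqn{\pi_{ij} = F_j\,p(d_{ij}) / \sum_{k \ne i} F_k\,p(d_{ik}).}
#' The kernel's normalising constant cancels.
#'
#' @param a,b exponential-power kernel parameters.
#' @param fecundity vector of relative male fecundities `F_j` over the
#'   candidates (default equifertile).
#' @param data a `mating_data` object.
#' @param mother optional single mother id (returns that row only).
#' @return M x J matrix of probabilities with rows summing to 1 (or a single
#'   named row when `mother` is given).
#' @export
mating_probabilities <- function(a, b, data,
                                 fecundity = rep(1, length(data$candidates)),
                                 mother = NULL) {
  stopifnot(inherits(data, "mating_data"), a > 0, b > 0,
            length(fecundity) == length(data$candidates), all(fecundity > 0))
  u <- exp(-(a * data$dist)^b)
  u[data$self] <- 0
  w <- sweep(u, 2, fecundity, "*")
  tot <- rowSums(w)
  if (any(tot <= 0 | !is.finite(tot))) {
    stop("pollen-cloud weights underflow for mother(s) ",
         paste(data$mothers[tot <= 0 | !is.finite(tot)], collapse = ", "),
         "; rescale distances or parameters")
  }
  pi <- w / tot
  if (!is.null(mother)) {
    i <- match(mother, data$mothers)
    if (is.na(i)) stop("unknown mother ", mother)
    return(pi[i, , drop = TRUE])
  }
  pi
}

#' Multinomial log-likelihood of the mating model
#'
#' Conditional on within-plot allogamy: `sum_ij n_ij log pi_ij` (the
#' multinomial log-pmf without its combinatorial constant). Selfed and
#' immigrant seeds enter the analysis only through the fixed `s_i`, `m_i`.
#'
#' @inheritParams mating_probabilities
#' @return Scalar log-likelihood; `-Inf` (with a diagnostic attribute naming
#'   the offending mother-father pair) when an observed father has zero
#'   probability.
#' @export
mating_log_likelihood <- function(a, b, data,
                                  fecundity = rep(1, length(data$candidates))) {
  pi <- mating_probabilities(a, b, data, fecundity)
  nz <- data$n > 0
  if (!any(nz)) return(0)
  if (any(pi[nz] == 0)) {
    bad <- which(nz & pi == 0, arr.ind = TRUE)[1, ]
    return(structure(-Inf, offending = c(mother = data$mothers[bad[1]],
                                         father = data$candidates[bad[2]])))
  }
  sum(data$n[nz] * log(pi[nz]))
}

#' Unnormalised log-posterior of the mating model
#'
#' Log-likelihood plus the log priors: Gamma(`prior_shape`, `prior_rate`) on
#' `a` and `b`; log-fecundities i.i.d. Normal with mean `-sigma2/2` (so that
#' mean fecundity is 1) and variance `sigma2`; and a
#' Gamma(`prior_shape`, `prior_rate`) prior on the precision `1/sigma2`
#' (including the Jacobian of the precision-to-variance map, so the value is
#' a density in `sigma2`).
#'
#' @inheritParams mating_probabilities
#' @param sigma2 variance of log fecundity.
#' @param prior_shape,prior_rate Gamma hyper-parameters (default 0.001 both,
#'   an uninformative choice).
#' @return Scalar unnormalised log-posterior density.
#' @export
mating_log_posterior <- function(a, b, data,
                                 fecundity = rep(1, length(data$candidates)),
                                 sigma2 = 1,
                                 prior_shape = 0.001, prior_rate = 0.001) {
  stopifnot(sigma2 > 0)
  ll <- mating_log_likelihood(a, b, data, fecundity)
  lp <- dgamma(a, prior_shape, prior_rate, log = TRUE) +
    dgamma(b, prior_shape, prior_rate, log = TRUE) +
    sum(dnorm(log(fecundity), -sigma2 / 2, sqrt(sigma2), log = TRUE)) +
    dgamma(1 / sigma2, prior_shape, prior_rate, log = TRUE) - 2 * log(sigma2)
  ll + lp
}
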