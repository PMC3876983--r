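#' Modelled pollen cloud of a mother tree
#'
#' Fecundity-weighted kernel contributions of every flowering candidate to a
#' mother's pollen pool, including the mother herself as a self-pollen donor
#' at distance zero (the kernel is finite at 0:
#' `p(0) = a^2 b / (2 pi Gamma(2/b))`). Shares are the contributions
#' normalised over the whole cloud; `rho` is the self-pollen share.
#'
#' @param a,b kernel parameters.
#' @param tree_map a [tree_map].
#' @param mother mother tree id (must be flowering in `season`).
#' @param season season label.
#' @param fecundity named vector of relative fecundities over tree ids
#'   (default equifertile); missing names default to 1.
#' @return Object of class `pollen_cloud`: list with `mother`, `donors`
#'   (data.frame id, distance, fecundity, contribution, share) and `rho`.
#' @export
pollen_cloud <- function(a, b, tree_map, mother, season,
                         fecundity = NULL) {
  st <- flowering_status(tree_map, season)
  if (!mother %in% names(st)) stop("unknown mother ", mother)
  if (st[[mother]] == "not_flowering") stop("mother ", mother, " was not flowering in ", season)
  ids <- names(st)[st == "flowering"]
  ids <- union(ids, mother)
  d <- tree_distances(tree_map, mother, ids)[1, ]
  f <- rep(1, length(ids)); names(f) <- ids
  if (!is.null(fecundity)) {
    common <- intersect(names(fecundity), ids)
    f[common] <- fecundity[common]
  }
  dens <- kernel_density(d, a, b)
  if (any(!is.finite(dens))) stop("kernel density overflow; check a and b")
  contrib <- f * dens
  share <- contrib / sum(contrib)
  donors <- data.frame(id = ids, distance = unname(d), fecundity = unname(f),
                       contribution = unname(contrib), share = unname(share),
                       stringsAsFactors = FALSE)
  structure(list(mother = mother, season = season, donors = donors,
                 rho = unname(share[ids == mother])),
            class = "pollen_cloud")
}

#' @export
print.pollen_cloud <- function(x, ...) {
  cat(sprintf("Pollen cloud of %s (season %s): %d flowering donors, rho = %.3f\n",
              x$mother, x$season, nrow(x$donors) - 1, x$rho))
  invisible(x)
}

#' Effective number of pollen donors
#'
#' The inverse probability of paternal identity of two randomly drawn seeds.
#' Per mother, two seeds share a father with probability `sum_j pi_ij^2`, so
#' `N_epi = 1 / sum_j pi_ij^2`; globally, a random seed comes from mother `i`
#' with probability `n_i/n` and the pooled donor share is
#' `q_j = sum_i (n_i/n) pi_ij`, giving `N_ep = 1 / sum_j q_j^2`. The shares
#' `pi_ij` describe the outcross (within-plot) pollen cloud; rows must sum
#' to 1.
#'
#' @param pi mothers x donors matrix of outcross pollen shares (each row sums
#'   to 1).
#' @param n_i per-mother analysed seed counts (pooling weights).
#' @return List with `N_ep` (scalar) and `N_epi` (per-mother vector).
#' @export
effective_pollen_donors <- function(pi, n_i) {
  pi <- rbind(pi)
  stopifnot(nrow(pi) == length(n_i), all(n_i >= 0), all(pi >= 0))
  if (sum(n_i) == 0) stop("all seed counts are zero")
  rs <- rowSums(pi)
  if (any(abs(rs - 1) > 1e-6)) stop("pi rows must sum to 1")
  N_epi <- 1 / rowSums(pi^2)
  w <- n_i / sum(n_i)
  q <- colSums(w * pi)
  list(N_ep = 1 / sum(q^2),
       N_epi = stats::setNames(N_epi, rownames(pi)))
}

#' Flowering neighbourhood of a mother tree
#'
#' Number of flowering trees within a radius (typically the mean dispersal
#' distance `delta`) of the mother, and the distance to her nearest flowering
#' neighbour, both excluding the mother herself. Unknown-status trees are not
#' counted.
#'
#' @param tree_map a [tree_map].
#' @param mother mother tree id.
#' @param season season label.
#' @param delta neighbourhood radius in metres, `> 0`.
#' @return List with `n_within` and `nearest` (`NA` when no flowering
#'   neighbour exists).
#' @export
neighborhood_metrics <- function(tree_map, mother, season, delta) {
  stopifnot(delta > 0)
  st <- flowering_status(tree_map, season)
  ids <- setdiff(names(st)[st == "flowering"], mother)
  if (!length(ids)) return(list(n_within = 0L, nearest = NA_real_))
  d <- tree_distances(tree_map, mother, ids)[1, ]
  list(n_within = sum(d <= delta), nearest = min(d))
}
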