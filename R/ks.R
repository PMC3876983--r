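#' Distance-class donor counts and their two-season comparison
#'
#' For each season, counts flowering candidates within increasing radii of
#' each mother (the field's standard bar chart of donor availability), and
#' compares the two seasons' pollen-donor distance distributions with a
#' two-sample Kolmogorov-Smirnov statistic over the distance classes:
#' `D` is the maximum absolute difference between the binned cumulative
#' relative frequency curves, with the standard asymptotic p-value computed
#' from the total mother-candidate pair counts.
#'
#' @param tree_map a [tree_map].
#' @param mothers_a,mothers_b character vectors of mother tree ids sampled in
#'   each season.
#' @param seasons_ab length-2 character vector naming the two seasons.
#' @param radii strictly increasing distance-class boundaries in metres
#'   (default eight 25-m classes up to 200 m).
#' @return List with `D`, `p_value`, `mean_counts` (radii x season matrix of
#'   mean cumulative candidate counts per mother), `class_counts` (per-class
#'   totals) and `n` (total pair counts per season).
#' @export
ks_distance_classes <- function(tree_map, mothers_a, mothers_b, seasons_ab,
                                radii = seq(25, 200, by = 25)) {
  stopifnot(length(seasons_ab) == 2, length(radii) >= 2, all(diff(radii) > 0))
  count_season <- function(mothers, season) {
    cand <- setdiff(tree_map$tree_id[
      flowering_status(tree_map, season) == "flowering"], NULL)
    per_class <- matrix(0, length(mothers), length(radii),
                        dimnames = list(mothers, radii))
    for (i in seq_along(mothers)) {
      others <- setdiff(cand, mothers[i])
      if (!length(others)) next
      d <- tree_distances(tree_map, mothers[i], others)[1, ]
      per_class[i, ] <- vapply(radii, function(r) sum(d <= r), numeric(1))
    }
    per_class
  }
  ca <- count_season(mothers_a, seasons_ab[1])
  cb <- count_season(mothers_b, seasons_ab[2])
  tot_a <- sum(ca[, ncol(ca)]); tot_b <- sum(cb[, ncol(cb)])
  if (tot_a + tot_b == 0) stop("no flowering candidates within the radii in either season")
  if (tot_a == 0 || tot_b == 0) stop("no flowering candidates within the radii in one season")

  # per-class (annulus) totals and cumulative relative frequencies
  cum_a <- colSums(ca); cum_b <- colSums(cb)
  crf_a <- cum_a / tot_a; crf_b <- cum_b / tot_b
  D <- max(abs(crf_a - crf_b))
  n_eff <- tot_a * tot_b / (tot_a + tot_b)
  p <- ks_asymptotic_p(D, n_eff)
  list(D = D, p_value = p,
       mean_counts = cbind(stats::setNames(colMeans(ca), radii),
                           colMeans(cb)),
       class_counts = rbind(a = c(cum_a[1], diff(cum_a)),
                            b = c(cum_b[1], diff(cum_b))),
       n = c(a = tot_a, b = tot_b))
}

# Asymptotic two-sample KS tail probability (Kolmogorov series with the
# usual small-sample continuity correction of the argument).
ks_asymptotic_p <- function(D, n_eff) {
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  if (lambda < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample KS statistic on pre-binned class counts
#'
#' Convenience form used when class counts are already tabulated: `D` is the
#' maximum absolute difference of the two cumulative relative frequency
#' curves.
#'
#' @param counts_a,counts_b per-class counts (same number of classes).
#' @return List with `D` and `p_value` (asymptotic).
#' @export
ks_binned <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), sum(counts_a) > 0, sum(counts_b) > 0)
  crf_a <- cumsum(counts_a) / sum(counts_a)
  crf_b <- cumsum(counts_b) / sum(counts_b)
  D <- max(abs(crf_a - crf_b))
  n_eff <- sum(counts_a) * sum(counts_b) / (sum(counts_a) + sum(counts_b))
  list(D = D, p_value = ks_asymptotic_p(D, n_eff))
}
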