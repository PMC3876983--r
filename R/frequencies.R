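#' Allele frequencies and locus diversity from adult genotypes
#'
#' Relative allele frequencies per locus from direct allele counts in the
#' adult (candidate-parent) population, together with the number of alleles,
#' observed heterozygosity (share of complete genotypes carrying two distinct
#' alleles) and expected heterozygosity (1 - sum p^2).
#'
#' @param adults an adult [genotype_table].
#' @return An object of class `frequency_table`: list with `freq` (per locus,
#'   a named numeric vector of frequencies), `n_alleles`, `H_obs`, `H_exp`,
#'   and `n_genes` (number of scored allele copies per locus).
#' @export
allele_frequencies <- function(adults) {
  stopifnot(inherits(adults, "genotype_table"))
  lc <- loci(adults)
  freq <- vector("list", length(lc)); names(freq) <- lc
  n_alleles <- H_obs <- H_exp <- n_genes <- stats::setNames(numeric(length(lc)), lc)
  for (loc in lc) {
    m <- locus_matrix(adults, loc)
    al <- as.vector(m); al <- al[!is.na(al)]
    if (!length(al)) stop("locus ", loc, " has no scored genotypes")
    tab <- table(al)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    freq[[loc]] <- p
    n_alleles[loc] <- length(p)
    n_genes[loc] <- sum(tab)
    complete <- !is.na(m[, 1]) & !is.na(m[, 2])
    H_obs[loc] <- if (any(complete)) mean(m[complete, 1] != m[complete, 2]) else NA_real_
    H_exp[loc] <- 1 - sum(p^2)
  }
  structure(list(freq = freq, n_alleles = n_alleles, H_obs = H_obs,
                 H_exp = H_exp, n_genes = n_genes),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("Allele frequencies: %d loci, %.1f alleles/locus (range %d-%d)\n",
              length(x$freq), mean(x$n_alleles),
              min(x$n_alleles), max(x$n_alleles)))
  cat(sprintf("  mean H_obs %.3f, mean H_exp %.3f\n",
              mean(x$H_obs, na.rm = TRUE), mean(x$H_exp, na.rm = TRUE)))
  invisible(x)
}

# Frequency lookup for one locus with a floor for alleles unseen among adults
# (seed mutations / immigrant alleles); floor = one copy in the scored sample.
locus_freq_lookup <- function(freqs, locus, alleles) {
  p <- freqs$freq[[locus]]
  floorf <- 1 / (freqs$n_genes[[locus]] + 1)
  out <- p[as.character(alleles)]
  out[is.na(out)] <- floorf
  unname(out)
}

#' Combined second-parent exclusion probability
#'
#' Probability that a random non-father is genetically excluded when the
#' mother is known, under Hardy-Weinberg genotype proportions and Mendelian
#' transmission. Per locus the exact value is obtained by marginalising over
#' the transmitted maternal allele `u`, the non-transmitted maternal allele
#' `v` and the paternal allele `f`: the offspring's admissible paternal-allele
#' set is `{f}` plus `u` when `f` occurs in the mother, and a random candidate
#' is excluded when neither of its two alleles falls in that set. Loci combine
#' as `Q = 1 - prod(1 - Q_l)`.
#'
#' @param freqs a [frequency_table].
#' @return Total exclusion probability (scalar) with attribute `per_locus`.
#' @export
exclusion_probability <- function(freqs) {
  stopifnot(inherits(freqs, "frequency_table"))
  per <- vapply(freqs$freq, locus_exclusion_probability, numeric(1))
  structure(1 - prod(1 - per), per_locus = per)
}

# Exact per-locus second-parent (known mother) exclusion probability.
locus_exclusion_probability <- function(p) {
  p <- as.numeric(p)
  k <- length(p)
  if (k < 2) return(0)
  # paternal allele equals transmitted maternal allele u: S = {u}
  q_hom <- sum(p^2 * (1 - p)^2)
  # T = E_f[(1 - p_f)^2] over f not in {u, v}; assembled from power sums
  tot <- sum(p * (1 - p)^2)
  q_het <- 0
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      w <- p[u] * p[v]
      if (w == 0) next
      # f == v (in mother, != u): S = {f, u}
      if (v != u) q_het <- q_het + w * p[v] * (1 - p[v] - p[u])^2
      # f outside {u, v}: S = {f}
      rest <- tot - p[u] * (1 - p[u])^2 -
        (if (v != u) p[v] * (1 - p[v])^2 else 0)
      q_het <- q_het + w * max(rest, 0)
    }
  }
  q_hom + q_het
}
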