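# LOD machinery: trio transmission probabilities, mistyping-tolerant
# likelihood ratios, mismatch counts, and the simulated Delta criterion.

# Mendelian probability pieces for one seed/mother pair against a block of
# candidate fathers, one locus at a time. Loci where the seed or the mother is
# not fully scored are skipped (contribution 0); candidates unscored at a
# locus contribute 0 there and accrue no mismatch.
trio_lod <- function(seed, mother, candidates, freqs, e) {
  lc <- loci(candidates)
  n_cand <- nrow(candidates)
  lod <- numeric(n_cand)
  mism <- integer(n_cand)
  for (loc in lc) {
    sg <- c(seed[[paste0(loc, "_1")]], seed[[paste0(loc, "_2")]])
    mg <- c(mother[[paste0(loc, "_1")]], mother[[paste0(loc, "_2")]])
    if (anyNA(sg) || anyNA(mg)) next
    sx <- sg[1]; sy <- sg[2]
    pm_x <- mean(mg == sx); pm_y <- mean(mg == sy)
    if (pm_x + pm_y == 0 && e == 0) next   # maternal conflict, uninformative at e = 0
    cm <- locus_matrix(candidates, loc)
    ok <- !is.na(cm[, 1]) & !is.na(cm[, 2])
    pf_x <- (as.numeric(cm[, 1] == sx) + as.numeric(cm[, 2] == sx)) / 2
    pf_y <- (as.numeric(cm[, 1] == sy) + as.numeric(cm[, 2] == sy)) / 2
    f2 <- locus_freq_lookup(freqs, loc, c(sx, sy))
    fx <- f2[1]; fy <- f2[2]
    if (sx == sy) {
      tr <- pm_x * pf_x
      bg <- pm_x * fx
      hw <- fx^2
    } else {
      tr <- pm_x * pf_y + pm_y * pf_x
      bg <- pm_x * fy + pm_y * fx
      hw <- 2 * fx * fy
    }
    num <- (1 - e) * tr + e * hw
    den <- (1 - e) * bg + e * hw
    if (den == 0) next
    contrib <- log(num) - log(den)
    contrib[!ok] <- 0
    lod <- lod + contrib
    mism <- mism + as.integer(ok & tr == 0)
  }
  list(lod = lod, mismatch = mism)
}

#' Paternity LOD score of a candidate father
#'
#' Log-likelihood ratio, summed over loci, of the hypothesis that `candidate`
#' sired `seed` (mother known) against the hypothesis that the father is a
#' random male drawn from the population allele frequencies. Genotyping error
#' is modelled by mistyping rate `e`: with probability `e` the recorded
#' single-locus seed genotype is a random Hardy-Weinberg draw, and both
#' likelihoods integrate over that event, which keeps the score finite for
#' candidates mismatching at a few loci. With `e = 0` an incompatible
#' candidate scores `-Inf`. Loci with missing data contribute 0.
#'
#' @param seed,mother,candidate one-row subsets of a [genotype_table] (or
#'   single-row data.frames with the same `<locus>_1/_2` columns).
#' @param freqs a [frequency_table] from [allele_frequencies()].
#' @param e per-locus mistyping rate in `[0, 1)`.
#' @return Scalar LOD with attribute `mismatch` (number of loci at which the
#'   trio is Mendelian-incompatible).
#' @export
lod_score <- function(seed, mother, candidate, freqs, e = 0.01) {
  stopifnot(e >= 0, e < 1)
  cand <- candidate
  if (!inherits(cand, "genotype_table")) {
    cand <- genotype_table(as.data.frame(candidate), role = "adult")
  }
  res <- trio_lod(seed, mother, cand, freqs, e)
  structure(res$lod[1], mismatch = res$mismatch[1])
}

# Draw n Hardy-Weinberg genotypes per locus from a frequency table; returns a
# list (per locus) of n x 2 matrices of allele codes.
draw_hw_genotypes <- function(freqs, n) {
  out <- lapply(names(freqs$freq), function(loc) {
    p <- freqs$freq[[loc]]
    al <- as.integer(names(p))
    cbind(sample(al, n, replace = TRUE, prob = p),
          sample(al, n, replace = TRUE, prob = p))
  })
  names(out) <- names(freqs$freq)
  out
}

#' Critical Delta thresholds from offspring simulation
#'
#' Calibrates the Delta criterion (gap between the best and second-best
#' candidate LOD) by simulating offspring of known fathers: mothers and a
#' candidate pool are drawn in Hardy-Weinberg proportions from the observed
#' allele frequencies, each offspring receives one Mendelian allele from its
#' mother and one from a randomly chosen candidate, mistyping is applied at
#' rate `e`, and LODs are computed against the whole pool. The critical value
#' at confidence level `c` is the smallest threshold such that, among
#' simulated offspring whose Delta exceeds it, the best candidate is the true
#' father in at least a fraction `c` of cases.
#'
#' @param freqs a [frequency_table].
#' @param n_candidates size of the simulated candidate pool.
#' @param n_sim number of simulated offspring.
#' @param e mistyping rate.
#' @param confidence vector of confidence levels (strict 0.95 and relaxed
#'   0.80 by default).
#' @return Named numeric vector of critical Delta values (one per confidence
#'   level), with attribute `assignment_rate` (fraction of simulated offspring
#'   exceeding each threshold).
#' @export
critical_delta <- function(freqs, n_candidates = 800, n_sim = 10000,
                           e = 0.01, confidence = c(strict = 0.95, relaxed = 0.80)) {
  stopifnot(n_candidates >= 2, n_sim >= 10)
  lc <- names(freqs$freq)
  cand <- draw_hw_genotypes(freqs, n_candidates)
  moth <- draw_hw_genotypes(freqs, n_sim)
  father <- sample.int(n_candidates, n_sim, replace = TRUE)

  # offspring: one maternal + one paternal allele per locus, then mistyping
  off <- lapply(lc, function(loc) {
    m <- moth[[loc]]
    f <- cand[[loc]][father, , drop = FALSE]
    o <- cbind(m[cbind(seq_len(n_sim), sample(1:2, n_sim, replace = TRUE))],
               f[cbind(seq_len(n_sim), sample(1:2, n_sim, replace = TRUE))])
    mis <- runif(n_sim) < e
    if (any(mis)) {
      p <- freqs$freq[[loc]]; al <- as.integer(names(p)); k <- sum(mis)
      o[mis, ] <- cbind(sample(al, k, replace = TRUE, prob = p),
                        sample(al, k, replace = TRUE, prob = p))
    }
    o
  })
  names(off) <- lc

  lodm <- matrix(0, n_sim, n_candidates)
  chunk <- 1000L
  for (loc in lc) {
    p <- freqs$freq[[loc]]
    al <- as.integer(names(p))
    c1 <- cand[[loc]][, 1]; c2 <- cand[[loc]][, 2]
    ptr <- (outer(al, c1, "==") + outer(al, c2, "==")) / 2  # k x n_cand
    o <- off[[loc]]; m <- moth[[loc]]
    sx <- o[, 1]; sy <- o[, 2]
    pm_x <- ((m[, 1] == sx) + (m[, 2] == sx)) / 2
    pm_y <- ((m[, 1] == sy) + (m[, 2] == sy)) / 2
    fx <- unname(p[match(sx, al)]); fy <- unname(p[match(sy, al)])
    het <- sx != sy
    bg <- ifelse(het, pm_x * fy + pm_y * fx, pm_x * fx)
    hw <- ifelse(het, 2 * fx * fy, fx^2)
    den <- (1 - e) * bg + e * hw
    ix <- match(sx, al); iy <- match(sy, al)
    for (s0 in seq(1L, n_sim, by = chunk)) {
      s1 <- min(s0 + chunk - 1L, n_sim)
      rows <- s0:s1
      pfX <- ptr[ix[rows], , drop = FALSE]
      pfY <- ptr[iy[rows], , drop = FALSE]
      tr <- pm_x[rows] * pfY + pm_y[rows] * pfX
      hom <- !het[rows]
      if (any(hom)) tr[hom, ] <- (pm_x[rows] * pfX)[hom, ]
      lodm[rows, ] <- lodm[rows, ] + log((1 - e) * tr + e * hw[rows]) - log(den[rows])
    }
  }

  best_idx <- max.col(lodm, ties.method = "first")
  best <- lodm[cbind(seq_len(n_sim), best_idx)]
  lodm[cbind(seq_len(n_sim), best_idx)] <- -Inf
  second <- lodm[cbind(seq_len(n_sim), max.col(lodm, ties.method = "first"))]
  delta <- best - second
  correct <- best_idx == father

  ord <- order(delta, decreasing = TRUE)
  d_s <- delta[ord]
  cumprop <- cumsum(correct[ord]) / seq_len(n_sim)
  crit <- vapply(confidence, function(cf) {
    if (cumprop[n_sim] >= cf) return(0)
    idx <- which(cumprop >= cf)
    if (!length(idx)) return(Inf)
    d_s[max(idx)]
  }, numeric(1))
  names(crit) <- names(confidence)
  rate <- vapply(crit, function(d) mean(delta > d), numeric(1))
  structure(crit, assignment_rate = rate)
}
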