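# Synthetic-data generator: mapped populations, Hardy-Weinberg genotypes and
# kernel-driven seed arrays with full ground truth, so that the paternity and
# mating-model stages can be validated end to end without field data.

rdirichlet1 <- function(k, alpha = 1) {
  g <- rgamma(k, alpha)
  g / sum(g)
}

#' Generate a synthetic mapped adult population
#'
#' Adults placed uniformly at random in the plot; per-locus allele
#' frequencies drawn from a symmetric Dirichlet; adult genotypes in
#' Hardy-Weinberg proportions; flowering flags drawn so that the requested
#' number (or fraction) of adults flowers in each season. Defaults emulate a
#' 40-ha dipterocarp plot: 144 adults in 500 x 800 m (3.6 trees/ha), 11
#' microsatellite loci with 9-21 alleles, and two general-flowering seasons —
#' a sporadic one with 77 flowering trees (1.925/ha) and a mass one with 107
#' (2.675/ha).
#'
#' @param n_adults number of adults.
#' @param plot_dim plot width and height in metres.
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus (scalar or length-`n_loci` vector;
#'   default a 9-21 spread).
#' @param flowering named vector giving, per season, the number (if `>= 1`)
#'   or fraction (if `< 1`) of flowering adults.
#' @param dirichlet concentration of the symmetric Dirichlet for allele
#'   frequencies.
#' @param seed optional RNG seed.
#' @return Object of class `pollen_population`: list with `tree_map`,
#'   `adults` (genotype table), `freqs` (the *true* frequency_table used to
#'   generate genotypes).
#' @export
generate_population <- function(n_adults = 144, plot_dim = c(500, 800),
                                n_loci = 11, n_alleles = NULL,
                                flowering = c("2002" = 77, "2005" = 107),
                                dirichlet = 1, seed = NULL) {
  stopifnot(n_adults >= 1, length(plot_dim) == 2, all(plot_dim > 0), n_loci >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_alleles)) n_alleles <- round(seq(9, 21, length.out = n_loci))
  n_alleles <- rep(as.integer(n_alleles), length.out = n_loci)
  locus_names <- sprintf("L%02d", seq_len(n_loci))

  ids <- sprintf("T%03d", seq_len(n_adults))
  df <- data.frame(tree_id = ids,
                   x = runif(n_adults, 0, plot_dim[1]),
                   y = runif(n_adults, 0, plot_dim[2]),
                   dbh = round(30 + rgamma(n_adults, shape = 2, scale = 15), 1),
                   stringsAsFactors = FALSE)
  for (season in names(flowering)) {
    k <- flowering[[season]]
    k <- if (k < 1) round(k * n_adults) else min(round(k), n_adults)
    fl <- rep("not_flowering", n_adults)
    fl[sample.int(n_adults, k)] <- "flowering"
    df[[paste0("flowering_", season)]] <- fl
  }
  tm <- tree_map(df, plot_width = plot_dim[1], plot_height = plot_dim[2])

  freq <- vector("list", n_loci); names(freq) <- locus_names
  geno <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (l in seq_len(n_loci)) {
    k <- n_alleles[l]
    p <- rdirichlet1(k, dirichlet)
    codes <- 100L + 2L * seq_len(k)       # microsatellite-style size codes
    names(p) <- codes
    freq[[l]] <- p
    geno[[paste0(locus_names[l], "_1")]] <- sample(codes, n_adults, TRUE, prob = p)
    geno[[paste0(locus_names[l], "_2")]] <- sample(codes, n_adults, TRUE, prob = p)
  }
  freqs <- structure(list(freq = freq,
                          n_alleles = stats::setNames(n_alleles, locus_names),
                          H_obs = vapply(freq, function(p) 1 - sum(p^2), numeric(1)),
                          H_exp = vapply(freq, function(p) 1 - sum(p^2), numeric(1)),
                          n_genes = stats::setNames(rep(2 * n_adults, n_loci), locus_names)),
                     class = "frequency_table")
  structure(list(tree_map = tm,
                 adults = genotype_table(geno, role = "adult"),
                 freqs = freqs),
            class = "pollen_population")
}

#' @export
print.pollen_population <- function(x, ...) {
  cat("Synthetic population\n")
  print(x$tree_map)
  print(x$adults)
  invisible(x)
}

#' Simulate seed arrays under the mating model
#'
#' For each seed of each mother, a category is drawn — selfed with
#' probability `s`, immigrant (outside-plot father) with probability `m`,
#' otherwise a within-plot father sampled from the true mating probabilities
#' `pi_ij` built from the exponential-power kernel `(a, b)` and log-normal
#' fecundities (mean 1, log-sd `sigma`) over the season's flowering trees.
#' Seed genotypes receive one Mendelian allele from the mother and one from
#' the father; immigrant paternal alleles are drawn from the population
#' allele frequencies. Optionally a fraction of seeds are contaminants
#' (collected under the wrong canopy): their genotypes are independent
#' Hardy-Weinberg draws. The full ground truth is returned.
#'
#' @param population a `pollen_population` from [generate_population()].
#' @param season season label (must exist in the population's tree map).
#' @param mothers number of mothers (sampled from flowering adults) or a
#'   character vector of flowering adult ids.
#' @param seeds_per_mother seeds collected per mother (scalar or vector).
#' @param a,b true kernel parameters.
#' @param sigma true standard deviation of log fecundity.
#' @param s,m true selfing and immigration probabilities (scalar or
#'   per-mother).
#' @param contamination fraction of seeds that are foreign contaminants.
#' @param mistyping per-locus mistyping rate applied to the seed genotypes
#'   (see [apply_mistyping()]).
#' @param seed optional RNG seed.
#' @return Object of class `synthetic_mating`: list with `seeds` (seed
#'   [genotype_table]), `truth` (per-seed data.frame: category, true father)
#'   and `params` (list incl. the per-adult true fecundities `F`).
#' @export
simulate_mating <- function(population, season, mothers = 11,
                            seeds_per_mother = 48,
                            a = 0.005, b = 1, sigma = 1.5,
                            s = 0.10, m = 0.40,
                            contamination = 0, mistyping = 0,
                            seed = NULL) {
  stopifnot(inherits(population, "pollen_population"),
            a > 0, b > 0, sigma >= 0, all(s >= 0), all(m >= 0), all(s + m <= 1),
            contamination >= 0, contamination < 1)
  if (!is.null(seed)) set.seed(seed)
  tm <- population$tree_map
  st <- flowering_status(tm, season)
  flowering <- names(st)[st == "flowering"]
  if (length(flowering) < 2) stop("need at least two flowering adults")

  if (is.character(mothers)) {
    if (!all(mothers %in% flowering)) stop("mothers must be flowering adults")
    mother_ids <- mothers
  } else {
    mother_ids <- sort(sample(flowering, mothers))
  }
  M <- length(mother_ids)
  spm <- rep(seeds_per_mother, length.out = M)
  s <- rep(s, length.out = M); m <- rep(m, length.out = M)

  Fj <- stats::setNames(rlnorm(nrow(tm), -sigma^2 / 2, sigma), tm$tree_id)
  dist <- tree_distances(tm, mother_ids, flowering)
  u <- exp(-(a * dist)^b)
  w <- sweep(u, 2, Fj[flowering], "*")
  w[cbind(seq_len(M), match(mother_ids, flowering))] <- 0
  pim <- w / rowSums(w)

  adults <- population$adults
  freqs <- population$freqs
  lc <- loci(adults)
  n_seeds <- sum(spm)
  seed_ids <- sprintf("S%04d", seq_len(n_seeds))
  truth <- data.frame(seed_id = seed_ids,
                      mother_id = rep(mother_ids, spm),
                      category = NA_character_, father_id = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(M)) {
    rows <- which(truth$mother_id == mother_ids[i])
    cat_draw <- runif(length(rows))
    categ <- ifelse(cat_draw < s[i], "self",
                    ifelse(cat_draw < s[i] + m[i], "immigrant", "within_plot"))
    truth$category[rows] <- categ
    wp <- rows[categ == "within_plot"]
    if (length(wp)) {
      truth$father_id[wp] <- sample(flowering, length(wp), TRUE, prob = pim[i, ])
    }
    truth$father_id[rows[categ == "self"]] <- mother_ids[i]
  }
  if (contamination > 0) {
    contam <- runif(n_seeds) < contamination
    truth$category[contam] <- "contaminant"
    truth$father_id[contam] <- NA_character_
  }

  gdf <- data.frame(individual_id = seed_ids, mother_id = truth$mother_id,
                    stringsAsFactors = FALSE)
  midx <- match(truth$mother_id, adults$individual_id)
  fidx <- match(truth$father_id, adults$individual_id)
  for (loc in lc) {
    am <- locus_matrix(adults, loc)
    p <- freqs$freq[[loc]]
    codes <- as.integer(names(p))
    mat_al <- am[cbind(midx, sample(1:2, n_seeds, TRUE))]
    pat_al <- integer(n_seeds)
    known_f <- !is.na(fidx)
    pat_al[known_f] <- am[cbind(fidx[known_f], sample(1:2, sum(known_f), TRUE))]
    pat_al[!known_f] <- sample(codes, sum(!known_f), TRUE, prob = p)
    a1 <- mat_al; a2 <- pat_al
    contam_rows <- truth$category == "contaminant"
    if (any(contam_rows)) {
      k <- sum(contam_rows)
      a1[contam_rows] <- sample(codes, k, TRUE, prob = p)
      a2[contam_rows] <- sample(codes, k, TRUE, prob = p)
    }
    gdf[[paste0(loc, "_1")]] <- a1
    gdf[[paste0(loc, "_2")]] <- a2
  }
  seeds_gt <- genotype_table(gdf, role = "seed", adults = adults)
  if (mistyping > 0) {
    seeds_gt <- apply_mistyping(seeds_gt, freqs, mistyping)
  }
  structure(list(seeds = seeds_gt, truth = truth,
                 params = list(a = a, b = b, sigma = sigma, s = s, m = m,
                               mothers = mother_ids, season = season,
                               seeds_per_mother = spm, F = Fj,
                               contamination = contamination,
                               mistyping = mistyping)),
            class = "synthetic_mating")
}

#' @export
print.synthetic_mating <- function(x, ...) {
  cat(sprintf("Synthetic seed arrays: %d seeds from %d mothers (season %s)\n",
              nrow(x$truth), length(x$params$mothers), x$params$season))
  print(table(x$truth$category))
  invisible(x)
}

#' Apply genotype mistyping
#'
#' Each single-locus genotype is independently replaced, with probability
#' `e`, by a Hardy-Weinberg draw from the population allele frequencies —
#' the same error model the LOD likelihood integrates over.
#'
#' @param genotypes a [genotype_table].
#' @param freqs a [frequency_table].
#' @param e mistyping rate in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return The genotype table with errors applied.
#' @export
apply_mistyping <- function(genotypes, freqs, e, seed = NULL) {
  stopifnot(e >= 0, e <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (e == 0) return(genotypes)
  n <- nrow(genotypes)
  for (loc in loci(genotypes)) {
    hit <- runif(n) < e
    if (!any(hit)) next
    p <- freqs$freq[[loc]]
    codes <- as.integer(names(p))
    k <- sum(hit)
    a1 <- sample(codes, k, TRUE, prob = p)
    a2 <- sample(codes, k, TRUE, prob = p)
    genotypes[[paste0(loc, "_1")]][hit] <- pmin(a1, a2)
    genotypes[[paste0(loc, "_2")]][hit] <- pmax(a1, a2)
  }
  genotypes
}

#' True mating-model data from a synthetic simulation
#'
#' Bypasses paternity assignment: builds the `mating_data` object directly
#' from the simulation's ground truth (true within-plot father counts and
#' true per-mother selfing/immigration rates). Useful for validating the
#' sampler in isolation from assignment error.
#'
#' @param population a `pollen_population`.
#' @param sim a `synthetic_mating`.
#' @return A `mating_data` object over the season's flowering candidates.
#' @export
true_mating_data <- function(population, sim) {
  tm <- population$tree_map
  season <- sim$params$season
  st <- flowering_status(tm, season)
  cand <- names(st)[st != "not_flowering"]
  mother_ids <- sim$params$mothers
  truth <- sim$truth
  keep <- truth$category == "within_plot"
  n <- table(factor(truth$mother_id[keep], mother_ids),
             factor(truth$father_id[keep], cand))
  n <- matrix(as.integer(n), nrow = length(mother_ids),
              dimnames = list(mother_ids, cand))
  per_mother <- split(truth$category, factor(truth$mother_id, mother_ids))
  s_hat <- vapply(per_mother, function(cc) mean(cc == "self"), numeric(1))
  m_hat <- vapply(per_mother, function(cc) mean(cc == "immigrant"), numeric(1))
  new_mating_data(mothers = mother_ids, candidates = cand,
                  dist = tree_distances(tm, mother_ids, cand),
                  n = n, s = s_hat, m = m_hat,
                  n_analysed = lengths(per_mother))
}
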