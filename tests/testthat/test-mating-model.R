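# hand-built mating data: one mother at the origin, candidates on the x-axis
md_line <- function(dists, counts, mother_at = 0) {
  ids <- paste0("C", seq_along(dists))
  new_mating_data(
    mothers = "M", candidates = ids,
    dist = matrix(dists, 1, dimnames = list("M", ids)),
    n = matrix(as.integer(counts), 1, dimnames = list("M", ids))
  )
}

test_that("mating probabilities are normalised kernel-fecundity weights", {
  md <- md_line(c(100, 100), c(0, 0))
  expect_equal(unname(mating_probabilities(0.01, 1, md)[1, ]), c(.5, .5))

  md1 <- md_line(150, 0)
  expect_equal(unname(mating_probabilities(0.02, 0.8, md1)[1, ]), 1)

  # three candidates at 50/100/200 m, a = 0.01, b = 1, F = 1
  md3 <- md_line(c(50, 100, 200), c(0, 0, 0))
  w <- exp(-0.01 * c(50, 100, 200))
  expect_equal(unname(mating_probabilities(0.01, 1, md3)[1, ]), w / sum(w),
               tolerance = 1e-12)

  # unequal fecundity reweights linearly
  pf <- mating_probabilities(0.01, 1, md, fecundity = c(3, 1))
  expect_equal(unname(pf[1, ]), c(.75, .25))

  # the mother's own column is excluded from her cloud
  ids <- c("M", "C1")
  md_self <- new_mating_data(
    mothers = "M", candidates = ids,
    dist = matrix(c(0, 80), 1, dimnames = list("M", ids)),
    n = matrix(c(0L, 4L), 1, dimnames = list("M", ids)))
  expect_equal(unname(mating_probabilities(0.01, 1, md_self)[1, ]), c(0, 1))
})

test_that("the multinomial log-likelihood matches closed forms and dmultinom", {
  md0 <- md_line(c(60, 90), c(0, 0))
  expect_equal(mating_log_likelihood(0.01, 1, md0), 0)

  md <- md_line(c(100, 100), c(3, 1))
  expect_equal(mating_log_likelihood(0.005, 1.2, md), 4 * log(0.5))

  set.seed(91)
  dists <- runif(5, 20, 300)
  counts <- c(4, 0, 2, 7, 1)
  mdr <- md_line(dists, counts)
  fec <- rlnorm(5, 0, 0.5)
  pi <- mating_probabilities(0.008, 0.9, mdr, fecundity = fec)[1, ]
  oracle <- dmultinom(counts, prob = pi, log = TRUE) -
    (lfactorial(sum(counts)) - sum(lfactorial(counts)))
  expect_equal(mating_log_likelihood(0.008, 0.9, mdr, fecundity = fec), oracle,
               tolerance = 1e-10)
})

test_that("an observed father with vanishing kernel weight is diagnosed", {
  md <- md_line(c(1, 500), c(0, 3))
  ll <- mating_log_likelihood(2, 1, md)     # a r = 1000 underflows at 500 m
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(unname(attr(ll, "offending")["father"]), "C2")
})

test_that("the log posterior is the sum of its independently computed terms", {
  md <- md_line(c(50, 150, 250), c(2, 1, 0))
  a <- 0.007; b <- 1.1; s2 <- 1.7
  fec <- c(1.2, 0.4, 2.0)
  got <- mating_log_posterior(a, b, md, fecundity = fec, sigma2 = s2,
                              prior_shape = 0.001, prior_rate = 0.001)
  pi <- mating_probabilities(a, b, md, fecundity = fec)[1, ]
  want <- sum(c(2, 1, 0) * log(pi)) +
    dgamma(a, 0.001, 0.001, log = TRUE) +
    dgamma(b, 0.001, 0.001, log = TRUE) +
    sum(dnorm(log(fec), -s2 / 2, sqrt(s2), log = TRUE)) +
    dgamma(1 / s2, 0.001, 0.001, log = TRUE) - 2 * log(s2)
  expect_equal(got, want, tolerance = 1e-10)

  # with no data the posterior equals the prior
  md0 <- md_line(c(50, 150, 250), c(0, 0, 0))
  got0 <- mating_log_posterior(a, b, md0, fecundity = fec, sigma2 = s2)
  expect_equal(got0, want - sum(c(2, 1, 0) * log(pi)), tolerance = 1e-10)

  # raising the fecundity of the sole observed father raises the likelihood
  md_one <- md_line(c(50, 150, 250), c(2, 0, 0))
  lls <- vapply(c(0.5, 1, 2, 4), function(f1) {
    mating_log_likelihood(a, b, md_one, fecundity = c(f1, 1, 1))
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("the sampler is exactly reproducible under a fixed seed", {
  md <- md_line(c(40, 120, 300), c(5, 3, 1))
  cfg <- analysis_config(iterations = 600, burnin = 200, thin = 3,
                         chains = 2, seed = 101)
  f1 <- run_mcmc(md, cfg)
  f2 <- run_mcmc(md, cfg)
  expect_identical(f1$chains, f2$chains)
  expect_equal(nrow(f1$chains[[1]]), 200)   # iterations / thin
})

test_that("with no data the sampler recovers a moderate Gamma prior", {
  md0 <- md_line(c(100, 200), c(0, 0))
  cfg <- analysis_config(iterations = 30000, burnin = 5000, thin = 3,
                         chains = 2, prior_shape = 3, prior_rate = 300,
                         seed = 102)
  expect_warning(fit <- pollen_mating_model(md0, config = cfg), "prior")
  draws <- c(sapply(fit$samples$chains, function(m) m[, "a"]))
  qs <- quantile(draws, c(.25, .5, .75))
  expect_equal(unname(qs), qgamma(c(.25, .5, .75), 3, 300), tolerance = 0.1)
})

test_that("the posterior is invariant to candidate relabelling", {
  set.seed(103)
  dists <- runif(6, 30, 350)
  counts <- c(6, 2, 0, 4, 1, 3)
  cfg <- analysis_config(iterations = 6000, burnin = 3000, thin = 3,
                         chains = 2, seed = 104)
  f1 <- run_mcmc(md_line(dists, counts), cfg)
  perm <- c(4, 1, 6, 2, 5, 3)
  f2 <- run_mcmc(md_line(dists[perm], counts[perm]), cfg)
  m1 <- median(c(sapply(f1$chains, function(m) m[, "a"])))
  m2 <- median(c(sapply(f2$chains, function(m) m[, "a"])))
  expect_equal(log(m1), log(m2), tolerance = 0.25)
})

test_that("with b fixed at 1 a grid-search MLE sits inside the posterior mass", {
  pop <- generate_population(n_adults = 60, flowering = c("2005" = 45), seed = 105)
  sim <- simulate_mating(pop, season = "2005", mothers = 5, seeds_per_mother = 40,
                         a = 0.008, b = 1, sigma = 0, s = 0, m = 0, seed = 106)
  md <- true_mating_data(pop, sim)
  grid <- exp(seq(log(0.001), log(0.05), length.out = 120))
  ll <- vapply(grid, function(a) mating_log_likelihood(a, 1, md), numeric(1))
  a_mle <- grid[which.max(ll)]
  cfg <- analysis_config(iterations = 6000, burnin = 3000, chains = 2, seed = 107)
  fit <- pollen_mating_model(md, config = cfg)
  ci <- posterior_summary(fit, "a")
  expect_gt(a_mle, ci[["2.5%"]])
  expect_lt(a_mle, ci[["97.5%"]])
  expect_lt(abs(log(a_mle / ci[["50%"]])), 0.7)
})

test_that("Gelman-Rubin matches hand computation and flags divergence", {
  # two hand-written length-4 chains
  c1 <- c(1, 2, 3, 4); c2 <- c(2, 3, 4, 5)
  n <- 4
  W <- mean(c(var(c1), var(c2)))
  B <- n * var(c(mean(c1), mean(c2)))
  hand <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(unname(gelman_rubin(list(c1, c2))), hand, tolerance = 1e-12)

  # identical chains: B = 0, R-hat = sqrt((n-1)/n) ~ 1
  set.seed(108)
  x <- rnorm(200)
  expect_equal(unname(gelman_rubin(list(x, x))), sqrt(199 / 200), tolerance = 1e-10)

  # equal variance, very different means
  expect_gt(unname(gelman_rubin(list(rnorm(100, 0), rnorm(100, 50)))), 10)

  expect_error(gelman_rubin(list(rnorm(10))), "2 chains")
})
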