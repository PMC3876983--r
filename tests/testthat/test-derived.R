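test_that("pollen clouds include the mother as a finite self donor", {
  # isolated mother: the cloud is all self pollen
  tm1 <- tm_from(c("M", "Z"), c(100, 300), c(100, 300),
                 flowering = c("flowering", "not_flowering"))
  pc1 <- pollen_cloud(0.005, 1, tm1, "M", "2005")
  expect_equal(pc1$rho, 1)

  # one equidistant equal-fecundity competitor at r: rho = p(0)/(p(0)+p(r))
  tm2 <- tm_from(c("M", "C"), c(100, 250), c(100, 100),
                 flowering = c("flowering", "flowering"))
  a <- 0.004; b <- 0.9; r <- 150
  pc2 <- pollen_cloud(a, b, tm2, "M", "2005")
  want <- kernel_density(0, a, b) / (kernel_density(0, a, b) + kernel_density(r, a, b))
  expect_equal(pc2$rho, want, tolerance = 1e-12)
  expect_equal(sum(pc2$donors$share), 1)

  tm3 <- tm_from(c("M"), 10, 10, flowering = "not_flowering")
  expect_error(pollen_cloud(0.005, 1, tm3, "M", "2005"), "not flowering")
})

test_that("self-pollen share falls with the number of flowering neighbours", {
  set.seed(111)
  pop <- generate_population(seed = 111)
  tm <- pop$tree_map
  st <- flowering_status(tm, "2005")
  mothers <- sample(names(st)[st == "flowering"], 20)
  delta <- mean_dispersal_distance(0.005, 1)
  rho <- vapply(mothers, function(m) pollen_cloud(0.005, 1, tm, m, "2005")$rho,
                numeric(1))
  nwd <- vapply(mothers, function(m)
    neighborhood_metrics(tm, m, "2005", delta)$n_within, numeric(1))
  expect_lt(cor(rho, nwd, method = "spearman"), 0)
})

test_that("effective donor numbers match their uniform-case identities", {
  for (K in c(1, 4, 25)) {
    pi <- matrix(rep(1 / K, K), 1)
    res <- effective_pollen_donors(pi, n_i = 10)
    expect_equal(unname(res$N_epi), K)
    expect_equal(res$N_ep, K)
  }
})

test_that("effective donor numbers equal brute-force pair enumeration", {
  pi <- rbind(c(0.6, 0.3, 0.1),
              c(0.2, 0.2, 0.6))
  n_i <- c(30, 10)
  res <- effective_pollen_donors(pi, n_i)

  # brute force: enumerate both seeds' (mother, father) combinations
  w <- n_i / sum(n_i)
  p_same <- 0
  for (i1 in 1:2) for (j1 in 1:3) for (i2 in 1:2) for (j2 in 1:3) {
    if (j1 == j2) p_same <- p_same + w[i1] * pi[i1, j1] * w[i2] * pi[i2, j2]
  }
  expect_equal(res$N_ep, 1 / p_same, tolerance = 1e-12)

  p_same_1 <- 0
  for (j1 in 1:3) for (j2 in 1:3) {
    if (j1 == j2) p_same_1 <- p_same_1 + pi[1, j1] * pi[1, j2]
  }
  expect_equal(unname(res$N_epi[1]), 1 / p_same_1, tolerance = 1e-12)

  # bounds: 1 <= N_epi <= positive-share donor count
  expect_true(all(res$N_epi >= 1 & res$N_epi <= 3))
  expect_lte(res$N_ep, 3)
  expect_error(effective_pollen_donors(pi, c(0, 0)), "zero")
  expect_error(effective_pollen_donors(pi / 2, n_i), "sum to 1")
})

test_that("neighbourhood metrics agree with a brute-force scan", {
  tm <- tm_from(c("M", "A", "B", "C"), c(100, 110, 150, 480),
                c(100, 100, 100, 700),
                flowering = c("flowering", "flowering", "flowering", "flowering"))
  nm <- neighborhood_metrics(tm, "M", "2005", delta = 368)
  expect_equal(nm$n_within, 2)
  expect_equal(nm$nearest, 10)

  tm0 <- tm_from(c("M", "A"), c(1, 2), c(1, 1),
                 flowering = c("flowering", "not_flowering"))
  nm0 <- neighborhood_metrics(tm0, "M", "2005", delta = 100)
  expect_equal(nm0$n_within, 0L)
  expect_true(is.na(nm0$nearest))

  set.seed(112)
  pop <- generate_population(n_adults = 80, seed = 112)
  tm2 <- pop$tree_map
  st <- flowering_status(tm2, "2002")
  fl_ids <- names(st)[st == "flowering"]
  m <- fl_ids[1]
  got <- neighborhood_metrics(tm2, m, "2002", delta = 250)
  d_all <- sqrt((tm2$x - tm2$x[tm2$tree_id == m])^2 +
                  (tm2$y - tm2$y[tm2$tree_id == m])^2)
  ok <- tm2$tree_id %in% setdiff(fl_ids, m)
  expect_equal(got$n_within, sum(d_all[ok] <= 250))
  expect_equal(got$nearest, min(d_all[ok]))
})

test_that("posterior summaries are empirical quantiles of the pooled draws", {
  set.seed(113)
  z <- rnorm(10000)
  fake <- structure(list(chains = list(cbind(a = z[1:5000]),
                                       cbind(a = z[5001:10000])),
                         data = NULL), class = "pollen_mcmc")
  q <- posterior_summary(fake, "a")
  expect_equal(unname(q), c(-1.96, -0.674, 0, 0.674, 1.96), tolerance = 0.08)
  expect_error(posterior_summary(fake, "nonsense"), "unknown quantity")
})

test_that("summarising per-draw delta is close to delta at the medians", {
  # synthetic posterior with the scale/shape spread of a typical kernel fit
  set.seed(114)
  n <- 50000
  a <- exp(rnorm(n, log(0.0051), 0.2))
  b <- exp(rnorm(n, log(1.032), 0.12))
  per_draw <- median(mean_dispersal_distance(a, b))
  at_median <- mean_dispersal_distance(median(a), median(b))
  expect_lt(abs(per_draw - at_median) / at_median, 0.02)
})
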