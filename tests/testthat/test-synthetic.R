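test_that("generation is deterministic under a fixed seed", {
  p1 <- generate_population(seed = 121)
  p2 <- generate_population(seed = 121)
  expect_identical(as.data.frame(p1$tree_map), as.data.frame(p2$tree_map))
  expect_identical(as.data.frame(p1$adults), as.data.frame(p2$adults))
  s1 <- simulate_mating(p1, season = "2005", mothers = 3, seeds_per_mother = 10,
                        seed = 122)
  s2 <- simulate_mating(p2, season = "2005", mothers = 3, seeds_per_mother = 10,
                        seed = 122)
  expect_identical(as.data.frame(s1$seeds), as.data.frame(s2$seeds))
  expect_identical(s1$truth, s2$truth)
})

test_that("default population emulates the study plot geometry", {
  pop <- generate_population(seed = 123)
  tm <- pop$tree_map
  expect_equal(nrow(tm), 144)
  dens <- nrow(tm) / (attr(tm, "plot_width") * attr(tm, "plot_height") / 1e4)
  expect_equal(dens, 3.6)                     # trees per hectare
  st02 <- flowering_status(tm, "2002"); st05 <- flowering_status(tm, "2005")
  expect_equal(sum(st02 == "flowering"), 77)  # 1.925 / ha, sporadic season
  expect_equal(sum(st05 == "flowering"), 107) # 2.675 / ha, mass season
  expect_equal(length(loci(pop$adults)), 11)
  expect_true(all(pop$freqs$n_alleles >= 9 & pop$freqs$n_alleles <= 21))
})

test_that("degenerate mating fractions propagate to the truth", {
  pop <- generate_population(n_adults = 30, flowering = c("2005" = 20), seed = 124)
  all_self <- simulate_mating(pop, season = "2005", mothers = 2,
                              seeds_per_mother = 10, s = 1, m = 0, seed = 125)
  expect_true(all(all_self$truth$category == "self"))
  expect_true(all(all_self$truth$father_id == all_self$truth$mother_id))

  all_imm <- simulate_mating(pop, season = "2005", mothers = 2,
                             seeds_per_mother = 10, s = 0, m = 1, seed = 126)
  expect_true(all(all_imm$truth$category == "immigrant"))
  expect_true(all(is.na(all_imm$truth$father_id)))

  one <- generate_population(n_adults = 1, flowering = c("2005" = 1), seed = 127)
  expect_error(simulate_mating(one, season = "2005", mothers = 1,
                               seeds_per_mother = 2), "two flowering")
})

test_that("generated genotypes are in Hardy-Weinberg proportions", {
  pop <- generate_population(n_adults = 10000, n_loci = 1, n_alleles = 4,
                             flowering = c("2005" = 0.5), dirichlet = 5,
                             seed = 128)
  p <- pop$freqs$freq[[1]]
  codes <- as.integer(names(p))
  m <- cbind(pop$adults$L01_1, pop$adults$L01_2)
  # chi-square of observed unordered genotype counts vs HW expectation
  gt_lab <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  combos <- expand.grid(i = seq_along(codes), j = seq_along(codes))
  combos <- combos[combos$i <= combos$j, ]
  expected <- apply(combos, 1, function(z) {
    i <- z[["i"]]; j <- z[["j"]]
    10000 * (if (i == j) p[i]^2 else 2 * p[i] * p[j])
  })
  lab <- paste(codes[combos$i], codes[combos$j])
  observed <- as.numeric(table(factor(gt_lab, lab)))
  keep <- expected >= 5
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi2, qchisq(0.999, df = sum(keep) - 1))
})

test_that("mistyping alters the expected fraction of locus genotypes", {
  pop <- generate_population(n_adults = 9000, n_loci = 11,
                             flowering = c("2005" = 0.5), seed = 129)
  e <- 0.01
  before <- as.data.frame(pop$adults)
  after <- as.data.frame(apply_mistyping(pop$adults, pop$freqs, e, seed = 130))
  changed <- 0; total <- 0
  p_same <- 0
  for (loc in loci(pop$adults)) {
    a1 <- paste(before[[paste0(loc, "_1")]], before[[paste0(loc, "_2")]])
    a2 <- paste(after[[paste0(loc, "_1")]], after[[paste0(loc, "_2")]])
    changed <- changed + sum(a1 != a2)
    total <- total + length(a1)
    p <- pop$freqs$freq[[loc]]
    # P(HW redraw reproduces the original genotype), averaged over genotypes
    op <- outer(p, p)
    p_same <- p_same + sum(p^4) + sum((2 * op[upper.tri(op)])^2)
  }
  p_same <- p_same / length(loci(pop$adults))
  expected <- e * (1 - p_same)
  se <- sqrt(expected * (1 - expected) / total)
  expect_lt(abs(changed / total - expected), 4 * se + 1e-4)

  expect_identical(as.data.frame(apply_mistyping(pop$adults, pop$freqs, 0)),
                   before)
  all_new <- apply_mistyping(pop$adults, pop$freqs, 1, seed = 131)
  frac_same <- mean(paste(all_new$L01_1, all_new$L01_2) ==
                      paste(before$L01_1, before$L01_2))
  expect_lt(frac_same, 0.2)                   # e = 1 redraws every locus
})

test_that("simulated father distances follow the analytic mating probabilities", {
  pop <- generate_population(n_adults = 100, flowering = c("2005" = 70), seed = 132)
  sim <- simulate_mating(pop, season = "2005", mothers = 1,
                         seeds_per_mother = 10000, a = 0.01, b = 1, sigma = 1,
                         s = 0, m = 0, seed = 133)
  tm <- pop$tree_map
  mother <- sim$params$mothers
  st <- flowering_status(tm, "2005")
  cand <- setdiff(names(st)[st == "flowering"], mother)
  ix <- match(cand, tm$tree_id); im <- match(mother, tm$tree_id)
  d <- sqrt((tm$x[ix] - tm$x[im])^2 + (tm$y[ix] - tm$y[im])^2)
  names(d) <- cand
  Fj <- sim$params$F[cand]
  w <- Fj * exp(-0.01 * d)
  pi <- w / sum(w)
  want <- sum(pi * d)                          # analytic mean father distance
  got <- mean(d[match(sim$truth$father_id, cand)])
  sd_d <- sqrt(sum(pi * (d - want)^2))
  expect_lt(abs(got - want), 4 * sd_d / sqrt(10000))
})
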