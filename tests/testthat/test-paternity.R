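test_that("maternal-conflict filtering excludes exactly the incompatible seeds", {
  adults <- gt_from(list(M = list(L1 = c(182, 190), L2 = c(104, 106))))
  seeds <- gt_from(list(s1 = list(L1 = c(178, 182), L2 = c(104, 104)),
                        s2 = list(L1 = c(100, 102), L2 = c(104, 106)),
                        s3 = list(L1 = c(NA, NA), L2 = c(106, 120))),
                   role = "seed", mothers = c("M", "M", "M"), adults = adults)
  flt <- filter_maternal_conflicts(seeds, adults)
  expect_equal(flt$excluded_ids, "s2")      # no shared allele at L1
  expect_equal(nrow(flt$retained), 2)       # missing-data locus is skipped
})

test_that("planted contaminants are excluded at about their planting rate", {
  pop <- generate_population(seed = 31)
  sim <- simulate_mating(pop, season = "2005", mothers = 11,
                         seeds_per_mother = 48, contamination = 0.04,
                         seed = 32)
  flt <- filter_maternal_conflicts(sim$seeds, pop$adults)
  rate <- flt$n_excluded / nrow(sim$seeds)
  n_contam <- sum(sim$truth$category == "contaminant")
  # all excluded seeds are true contaminants; a few contaminants may pass by chance
  expect_true(all(flt$excluded_ids %in%
                    sim$truth$seed_id[sim$truth$category == "contaminant"]))
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.08)
  expect_lte(flt$n_excluded, n_contam)
})

test_that("perfect information recovers every true category and father", {
  pop <- generate_population(n_adults = 50, n_loci = 8,
                             flowering = c("2005" = 35), seed = 41)
  sim <- simulate_mating(pop, season = "2005", mothers = 4, seeds_per_mother = 15,
                         s = 0.2, m = 0.2, mistyping = 0, seed = 42)
  cfg <- analysis_config(season = "2005", mistyping_rate = 0,
                         delta_sim = 500, seed = 43)
  set.seed(43)
  pat <- assign_paternity(sim$seeds, pop$adults, pop$tree_map,
                          config = cfg)
  merged <- merge(pat$seeds, sim$truth, by = "seed_id",
                  suffixes = c("", ".true"))
  settled <- merged$category != "excluded_ambiguous"
  expect_gt(mean(settled), 0.9)
  expect_identical(merged$category[settled], merged$category.true[settled])
  wp <- settled & merged$category == "within_plot"
  expect_identical(merged$father_id[wp], merged$father_id.true[wp])
})

test_that("per-mother statistics satisfy the mating-system identities", {
  pop <- generate_population(n_adults = 60, flowering = c("2005" = 45), seed = 51)
  sim <- simulate_mating(pop, season = "2005", mothers = 5, seeds_per_mother = 20,
                         mistyping = 0.01, seed = 52)
  cfg <- analysis_config(season = "2005", delta_sim = 500, seed = 53)
  set.seed(53)
  pat <- assign_paternity(sim$seeds, pop$adults, pop$tree_map, config = cfg)
  tab <- pat$mothers
  per <- tab[tab$mother_id != "Average", ]
  expect_equal(per$s + per$m + per$allogamous, rep(1, nrow(per)))
  for (i in seq_len(nrow(per))) {
    n_i <- sum(pat$counts[per$mother_id[i], ])
    expect_equal(n_i, round(per$A[i] * per$allogamous[i]))
  }
  avg <- tab[tab$mother_id == "Average", ]
  expect_equal(avg$s, mean(per$s))
  expect_equal(avg$m, mean(per$m))
})

test_that("a fully selfed mother reports s = 1, m = 0 and a single donor", {
  pop <- generate_population(n_adults = 40, n_loci = 8,
                             flowering = c("2005" = 30), seed = 61)
  sim <- simulate_mating(pop, season = "2005", mothers = 1, seeds_per_mother = 20,
                         s = 1, m = 0, seed = 62)
  expect_true(all(sim$truth$category == "self"))
  cfg <- analysis_config(season = "2005", mistyping_rate = 0,
                         delta_sim = 500, seed = 63)
  set.seed(63)
  pat <- assign_paternity(sim$seeds, pop$adults, pop$tree_map, config = cfg)
  per <- pat$mothers[pat$mothers$mother_id != "Average", ]
  expect_equal(per$s, 1)
  expect_equal(per$m, 0)
  expect_equal(per$n_donors, 1)
})

test_that("reference per-mother tables reproduce their printed averages", {
  ref <- pasoh_reference("mating_system")
  for (ss in c("2002", "2005")) {
    tab <- mating_system_summary(ref[ref$season == ss, -1])
    avg <- tab[tab$mother_id == "Average", ]
    expect_equal(avg$s + avg$m + avg$allogamous, 1, tolerance = 2e-3)
  }
  t02 <- mating_system_summary(ref[ref$season == "2002", -1])
  expect_equal(t02$A[t02$mother_id == "Average"], 40.6, tolerance = 0.01)
})
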