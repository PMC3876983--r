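# pollenflow

Pollen dispersal kernels, male fecundity variance and effective pollen-donor
numbers from the paternity of seed arrays in mapped tree populations.

## What it does, and for whom

In low-density, insect-pollinated tree populations — dipterocarp forests are
the motivating case — the questions "how far does successful pollen travel?",
"how unequal is male reproductive success?" and "how many fathers effectively
sire a seed crop?" can be answered when every adult in a plot is mapped and
genotyped and seeds are collected from known mothers. `pollenflow` is for
researchers with exactly that design: a tree map, adult and seed
microsatellite genotypes, and seed arrays per mother.

The pipeline has three stages:

1. **Paternity** (`assign_paternity()`): maternal-conflict filtering, then
   categorical assignment combining simple exclusion (≤ 2 tolerated locus
   mismatches by default) with LOD likelihood ratios under a mistyping rate
   *e*, gated by a simulation-calibrated critical Δ (gap between best and
   second-best LOD, strict 95% confidence). Each seed becomes *self*,
   *within-plot father j*, *immigrant*, or is left ambiguous. Per mother this
   yields the analysed count *Aᵢ*, selfing *sᵢ*, immigration *mᵢ*, allogamy
   *1 − sᵢ − mᵢ* and the father counts *n₍ᵢⱼ₎*.
2. **Mating model** (`pollen_mating_model()`): a hierarchical Bayesian model
   with the exponential-power dispersal kernel

   p(r; a, b) = a²b / (2π Γ(2/b)) · exp(−(a r)ᵇ),

   log-normal male fecundities *Fⱼ* (mean 1, log-variance σ²), and the
   multinomial likelihood π₍ᵢⱼ₎ = Fⱼ p(d₍ᵢⱼ₎) / Σₖ Fₖ p(d₍ᵢₖ₎) over the
   within-plot counts, fitted by Metropolis-within-Gibbs MCMC (Gamma(0.001,
   0.001) priors on a, b and 1/σ²; 60,000 iterations after 10,000 burn-in,
   thinned by 3, 3 chains by default; Gelman–Rubin R̂ reported).
3. **Derived quantities** (per posterior draw, then summarised): mean
   dispersal distance δ = Γ(3/b)/(a Γ(2/b)); donor-density ratio
   d_obs/d_ep = exp(σ²); pollen-cloud composition and self-pollen share ρᵢ;
   effective donor numbers N_ep (global, seed-count-weighted) and N_epᵢ
   (per mother) as inverse probabilities of paternal identity.

A synthetic-data generator (`generate_population()`, `simulate_mating()`)
reproduces the assumed study conditions — 144 adults on 500 × 800 m, 11 loci
with 9–21 alleles, sporadic (77 flowering) and mass (107 flowering) seasons —
with full ground truth, so the whole pipeline is testable end to end.

## Worked example

Simulate a mass-flowering season at the default study scale, assign
paternity, and fit the mating model:

```r
library(pollenflow)

pop <- generate_population(seed = 1)              # 144 adults, 2 seasons
sim <- simulate_mating(pop, season = "2005", mothers = 11,
                       seeds_per_mother = 48, mistyping = 0.01, seed = 2)

cfg <- analysis_config(season = "2005", delta_sim = 2000,
                       iterations = 15000, burnin = 10000, chains = 3, seed = 3)
set.seed(3)
pat <- assign_paternity(sim$seeds, pop$adults, pop$tree_map, config = cfg)
pat
#> Paternity assignment, season 2005: 488 seeds (40 conflict-excluded beforehand)
#>   immigrant            176
#>   self                 65
#>   within_plot          247
#>   critical Delta: strict 0.000, relaxed 0.000

fit <- pollen_mating_model(pat, pop$tree_map, config = cfg)
summary(fit)
#> Posterior quantiles (15000 pooled draws)
#>             2.5%      25%      50%      75%     97.5%
#> a         0.0042   0.0067   0.0102   0.0203    1.0937
#> b         0.2565   0.5287   0.6881   0.8587    1.2356
#> delta   309.4977 405.9890 514.2483 762.5599 5637.7756
#> sigma     1.1595   1.3486   1.4596   1.5881    1.8527
#> d_ratio   3.8360   6.1641   8.4182  12.4531   30.9513
#> N_ep     29.9273  33.7257  35.7979  37.9190   42.1628
#> Gelman-Rubin R-hat:
#>      a      b sigma2
#>  1.006  1.007  1.002
```

Reading the output: the simulation's truth was a = 0.005, b = 1, σ = 1.5
(δ = 400 m), selfing 0.10 and immigration 0.40. The 95% intervals cover all
three parameters; the critical Δ of 0 reflects the very high exclusion power
of 11 polymorphic loci (combined non-exclusion below 10⁻³); about 36
effective donors stand behind the 107 flowering candidates because fecundity
is strongly unequal (d_obs/d_ep ≈ 8 at the posterior median). `plot(fit)`
draws the posterior kernel, `posterior_summary(fit, "N_epi")` and
`posterior_summary(fit, "rho")` give the per-mother donor numbers and
self-pollen shares, and `write_results(fit, outdir)` writes draws and
summary tables as delimited text and JSON.

Published reference estimates for a 40-ha *Shorea maxwelliana* plot (Pasoh,
two general-flowering seasons) ship as plain-text tables —
`pasoh_reference("mating_system")` and `pasoh_reference("posterior")` — and
anchor the package's internal-consistency checks.

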