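Package: pollenflow
Title: Pollen Dispersal Kernels and Mating-System Inference from Seed Paternity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating pollen dispersal and male reproductive success in
    mapped tree populations from microsatellite paternity of seed arrays. Implements
    maternal-conflict filtering, exclusion- and likelihood-based (LOD) categorical
    paternity assignment with simulation-derived Delta thresholds, per-mother mating
    system statistics (selfing, pollen immigration, within-plot outcrossing), and a
    hierarchical Bayesian mating model combining an exponential-power dispersal
    kernel with log-normally distributed male fecundities, fitted by
    Metropolis-within-Gibbs MCMC. Derived quantities include the mean pollen
    dispersal distance, the observed-to-effective pollen-donor density ratio,
    per-mother pollen-cloud composition and self-pollen share, and global and
    per-mother effective numbers of pollen donors. A synthetic-data generator
    produces mapped populations, genotypes and seed arrays with full ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
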