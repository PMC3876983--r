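# Small in-code fixtures shared across test files.

# Genotype table from a compact list: gt_from(list(id = list(L1 = c(1, 2), ...)))
gt_from <- function(rows, role = "adult", mothers = NULL, adults = NULL) {
  loci <- names(rows[[1]])
  df <- data.frame(individual_id = names(rows), stringsAsFactors = FALSE)
  if (!is.null(mothers)) df$mother_id <- mothers
  for (loc in loci) {
    df[[paste0(loc, "_1")]] <- vapply(rows, function(r) r[[loc]][1], numeric(1))
    df[[paste0(loc, "_2")]] <- vapply(rows, function(r) r[[loc]][2], numeric(1))
  }
  genotype_table(df, role = role, adults = adults)
}

# Frequency table directly from stated per-locus frequencies
freqs_from <- function(freq_list, n_genes = 1000) {
  k <- vapply(freq_list, length, integer(1))
  structure(list(
    freq = lapply(freq_list, function(p) {
      stopifnot(abs(sum(p) - 1) < 1e-9)
      p
    }),
    n_alleles = k,
    H_obs = vapply(freq_list, function(p) 1 - sum(p^2), numeric(1)),
    H_exp = vapply(freq_list, function(p) 1 - sum(p^2), numeric(1)),
    n_genes = stats::setNames(rep(n_genes, length(freq_list)), names(freq_list))
  ), class = "frequency_table")
}

# Tree map from coordinate/flowering vectors
tm_from <- function(ids, x, y, flowering, season = "2005",
                    plot_width = 500, plot_height = 800) {
  df <- data.frame(tree_id = ids, x = x, y = y, stringsAsFactors = FALSE)
  if (is.list(flowering)) {
    for (s in names(flowering)) df[[paste0("flowering_", s)]] <- flowering[[s]]
  } else {
    df[[paste0("flowering_", season)]] <- flowering
  }
  tree_map(df, plot_width = plot_width, plot_height = plot_height)
}

# Exhaustive genotype-trio enumeration of the per-locus second-parent
# (known mother) exclusion probability; independent of the package's
# marginalised closed form.
enum_exclusion <- function(p) {
  k <- length(p)
  Q <- 0
  for (m1 in 1:k) for (m2 in 1:k) {            # ordered mother genotype
    for (tr in c(m1, m2)) {                    # transmitted maternal allele
      for (f in 1:k) {                         # paternal allele (random male)
        w <- p[m1] * p[m2] * 0.5 * p[f]
        off <- c(tr, f)
        # admissible paternal alleles given mother {m1, m2}
        S <- unique(c(if (off[2] %in% c(m1, m2)) off[1],
                      if (off[1] %in% c(m1, m2)) off[2]))
        pS <- sum(p[S])
        Q <- Q + w * (1 - pS)^2                # candidate carries no allele of S
      }
    }
  }
  Q
}

# Mendelian transmission probability P(offspring | mother, father) at one
# locus, by explicit enumeration of transmitted alleles.
enum_transmission <- function(off, mother, father) {
  pr <- 0
  for (i in 1:2) for (j in 1:2) {
    g <- sort(c(mother[i], father[j]))
    if (all(g == sort(off))) pr <- pr + 0.25
  }
  pr
}
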