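#' Exclude seeds that conflict with their putative mother
#'
#' Seeds are usually collected beneath the maternal canopy; overlapping crowns
#' cause occasional contamination by seeds of other mothers. A seed is
#' excluded when, at one or more loci where both seed and mother are fully
#' scored, the seed shares no allele with its putative mother. Loci with
#' missing data are skipped.
#'
#' @param seeds a seed [genotype_table] (with `mother_id`).
#' @param adults an adult [genotype_table] containing every referenced mother.
#' @return List with `retained` (filtered seed table), `excluded_ids` and
#'   `n_excluded`.
#' @export
filter_maternal_conflicts <- function(seeds, adults) {
  stopifnot(inherits(seeds, "genotype_table"), attr(seeds, "role") == "seed",
            inherits(adults, "genotype_table"))
  midx <- match(seeds$mother_id, adults$individual_id)
  if (anyNA(midx)) {
    stop("seed(s) reference unknown mother(s): ",
         paste(unique(seeds$mother_id[is.na(midx)]), collapse = ", "))
  }
  conflict <- rep(FALSE, nrow(seeds))
  for (loc in loci(seeds)) {
    sm <- locus_matrix(seeds, loc)
    mm <- locus_matrix(adults, loc)[midx, , drop = FALSE]
    complete <- !is.na(sm[, 1]) & !is.na(sm[, 2]) & !is.na(mm[, 1]) & !is.na(mm[, 2])
    share <- sm[, 1] == mm[, 1] | sm[, 1] == mm[, 2] |
      sm[, 2] == mm[, 1] | sm[, 2] == mm[, 2]
    conflict <- conflict | (complete & !share)
  }
  retained <- seeds[!conflict, , drop = FALSE]
  attr_keep <- attributes(seeds)
  retained <- structure(as.data.frame(retained),
                        role = "seed", loci = loci(seeds),
                        class = c("genotype_table", "data.frame"))
  list(retained = retained,
       excluded_ids = seeds$individual_id[conflict],
       n_excluded = sum(conflict))
}

#' Categorical paternity assignment for a seed array
#'
#' Combines simple exclusion with LOD likelihood. For every
#' conflict-retained seed, the LOD of each candidate father (all flowering or
#' unknown-status adults in the season, always including the mother herself so
#' that selfing is detectable) is computed with mistyping rate `e`. The best
#' candidate is assigned when it mismatches at no more than
#' `config$max_mismatch` loci and its Delta (best minus second-best LOD)
#' exceeds the simulation-derived critical value at the configured confidence;
#' a best candidate with too many mismatches indicates a father outside the
#' plot (pollen immigration); a sub-critical Delta leaves the seed
#' ambiguous and excluded from the modelling counts. Assignment to the mother
#' is the selfing category.
#'
#' @param seeds seed [genotype_table].
#' @param adults adult [genotype_table].
#' @param tree_map a [tree_map] with flowering status for the season.
#' @param freqs a [frequency_table]; defaults to frequencies of `adults`.
#' @param config an [analysis_config()]; its `season` must name a season in
#'   `tree_map` (or be `NULL` when the map records a single season).
#' @return A `paternity_table`: list with `seeds` (per-seed category,
#'   father, LODs, Delta, mismatches), `mothers` (per-mother statistics, see
#'   [mating_system_table()]), `counts` (mothers x candidates matrix of
#'   within-plot paternities `n_ij`), and attributes `season`,
#'   `critical_delta`, `candidates`, `excluded_conflict`.
#' @export
assign_paternity <- function(seeds, adults, tree_map,
                             freqs = allele_frequencies(adults),
                             config = analysis_config()) {
  season <- config$season
  if (is.null(season)) {
    if (length(seasons(tree_map)) != 1) {
      stop("config$season must be given when the tree map records several seasons")
    }
    season <- seasons(tree_map)
  }
  flt <- filter_maternal_conflicts(seeds, adults)
  kept <- flt$retained

  cand_ids <- candidate_ids(tree_map, season)
  cand_ids <- intersect(cand_ids, adults$individual_id)
  if (!length(cand_ids)) {
    warning("no flowering candidates in season ", season, "; all seeds immigrant")
  }

  n_cand_sim <- if (is.null(config$delta_candidates)) max(length(cand_ids), 2) else config$delta_candidates
  conf <- c(strict = 0.95, relaxed = 0.80)
  crit <- critical_delta(freqs, n_candidates = n_cand_sim,
                         n_sim = config$delta_sim, e = config$mistyping_rate,
                         confidence = conf)
  use_crit <- if (config$confidence >= 0.95) crit[["strict"]] else crit[["relaxed"]]

  res <- data.frame(
    seed_id = kept$individual_id, mother_id = kept$mother_id,
    category = NA_character_, father_id = NA_character_,
    lod_best = NA_real_, lod_second = NA_real_, delta = NA_real_,
    mismatch_best = NA_integer_, stringsAsFactors = FALSE
  )

  cand_cache <- new.env(parent = emptyenv())
  for (s in seq_len(nrow(kept))) {
    mother_id <- kept$mother_id[s]
    ids <- union(cand_ids, mother_id)          # mother always a candidate (selfing)
    if (is.null(cand_cache[[mother_id]])) {
      cand <- adults[match(ids, adults$individual_id), , drop = FALSE]
      cand_cache[[mother_id]] <- structure(
        as.data.frame(cand), role = "adult", loci = loci(adults),
        class = c("genotype_table", "data.frame"))
    }
    cand <- cand_cache[[mother_id]]
    mom <- adults[adults$individual_id == mother_id, , drop = FALSE]
    tl <- trio_lod(kept[s, , drop = FALSE], mom, cand, freqs, config$mistyping_rate)
    o <- order(tl$lod, decreasing = TRUE)
    b1 <- o[1]; b2 <- if (length(o) > 1) o[2] else NA_integer_
    res$lod_best[s] <- tl$lod[b1]
    res$lod_second[s] <- if (is.na(b2)) -Inf else tl$lod[b2]
    res$delta[s] <- res$lod_best[s] - res$lod_second[s]
    res$mismatch_best[s] <- tl$mismatch[b1]
    if (!length(cand_ids)) {
      res$category[s] <- "immigrant"
    } else if (tl$mismatch[b1] > config$max_mismatch) {
      res$category[s] <- "immigrant"
    } else if (!is.finite(res$delta[s]) && is.infinite(res$lod_best[s]) &&
               res$lod_best[s] < 0) {
      # every candidate (incl. mother) impossible at e = 0
      res$category[s] <- "immigrant"
    } else if (res$delta[s] > use_crit) {
      fid <- ids[b1]
      if (fid == mother_id) {
        res$category[s] <- "self"
        res$father_id[s] <- mother_id
      } else {
        res$category[s] <- "within_plot"
        res$father_id[s] <- fid
      }
    } else {
      res$category[s] <- "excluded_ambiguous"
    }
  }

  mothers <- sort(unique(res$mother_id))
  counts <- matrix(0L, length(mothers), length(cand_ids),
                   dimnames = list(mothers, cand_ids))
  wp <- res[res$category %in% "within_plot", ]
  if (nrow(wp)) {
    t_ij <- table(factor(wp$mother_id, mothers), factor(wp$father_id, cand_ids))
    counts <- counts + unclass(t_ij)
  }

  pat <- structure(
    list(seeds = res, counts = counts, mothers = NULL),
    season = season, critical_delta = crit, confidence = config$confidence,
    candidates = cand_ids, excluded_conflict = flt$excluded_ids,
    class = "paternity_table"
  )
  pat$mothers <- mating_system_table(pat)
  pat
}

#' Per-mother mating-system statistics
#'
#' For each mother: the number of seeds retained for modelling `A_i` (seeds
#' neither conflict-excluded nor Delta-ambiguous), the immigration rate `m_i`,
#' the selfing rate `s_i`, the within-plot allogamy rate `1 - m_i - s_i`, and
#' the number of distinct paternal donors identified (the mother herself
#' counts once when selfed seeds occur). The final row holds
#' unweighted means over mothers (for `A_i` and donor counts, the mean; rates
#' are averaged as printed per-mother values).
#'
#' @param paternity a `paternity_table` from [assign_paternity()].
#' @return data.frame with one row per mother plus an `"Average"` row;
#'   columns `mother_id`, `A`, `m`, `s`, `allogamous`, `n_donors`.
#' @export
mating_system_table <- function(paternity) {
  stopifnot(inherits(paternity, "paternity_table"))
  res <- paternity$seeds
  mothers <- sort(unique(res$mother_id))
  rows <- lapply(mothers, function(mid) {
    r <- res[res$mother_id == mid, ]
    analysed <- r[!r$category %in% "excluded_ambiguous", ]
    A <- nrow(analysed)
    s <- if (A) sum(analysed$category == "self") / A else NA_real_
    m <- if (A) sum(analysed$category == "immigrant") / A else NA_real_
    donors <- length(unique(
      analysed$father_id[analysed$category %in% c("self", "within_plot")]))
    data.frame(mother_id = mid, A = A, m = m, s = s,
               allogamous = 1 - m - s, n_donors = donors,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mating_system_summary(tab)
}

#' Append the unweighted-average row to a per-mother mating-system table
#'
#' Accepts any data.frame with per-mother columns `A`, `m`, `s`, `allogamous`
#' and `n_donors` (e.g. one read from a published table) and appends an
#' `"Average"` row of unweighted column means.
#'
#' @param tab per-mother data.frame (no average row).
#' @return The table with an `"Average"` row appended.
#' @export
mating_system_summary <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("mother_id", "A", "m", "s", "allogamous", "n_donors") %in% names(tab)))
  tab <- tab[tab$mother_id != "Average", , drop = FALSE]
  avg <- data.frame(
    mother_id = "Average",
    A = mean(tab$A), m = mean(tab$m), s = mean(tab$s),
    allogamous = mean(tab$allogamous), n_donors = mean(tab$n_donors),
    stringsAsFactors = FALSE
  )
  out <- rbind(tab, avg)
  rownames(out) <- NULL
  out
}

#' @export
print.paternity_table <- function(x, ...) {
  res <- x$seeds
  cat(sprintf("Paternity assignment, season %s: %d seeds (%d conflict-excluded beforehand)\n",
              attr(x, "season"), nrow(res), length(attr(x, "excluded_conflict"))))
  tabs <- table(res$category)
  for (nm in names(tabs)) cat(sprintf("  %-20s %d\n", nm, tabs[[nm]]))
  cd <- attr(x, "critical_delta")
  cat(sprintf("  critical Delta: strict %.3f, relaxed %.3f\n",
              cd[["strict"]], cd[["relaxed"]]))
  invisible(x)
}

#' @export
summary.paternity_table <- function(object, ...) {
  object$mothers
}
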