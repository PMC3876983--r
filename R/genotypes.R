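#' Construct a multilocus genotype table
#'
#' Diploid codominant genotypes (e.g. microsatellites) for adults or seeds.
#' Each locus occupies two integer columns `<locus>_1`, `<locus>_2`; allele
#' codes are positive integers and missing alleles are `NA` (encoded as 0 in
#' files). Allele order within a locus carries no information, so pairs are
#' canonicalised (sorted, `NA` last) on construction. Seed tables carry a
#' `mother_id` column referencing the maternal adult.
#'
#' @param df data.frame with `individual_id`, locus columns, and for seeds a
#'   `mother_id` column.
#' @param role `"adult"` or `"seed"`.
#' @param adults optional adult [genotype_table]; when given for seeds, every
#'   `mother_id` must reference an existing adult.
#' @return An object of class `genotype_table` with attributes `role` and
#'   `loci`.
#' @seealso [read_genotypes()]
#' @export
genotype_table <- function(df, role = c("adult", "seed"), adults = NULL) {
  role <- match.arg(role)
  stopifnot(is.data.frame(df))
  if (!"individual_id" %in% names(df)) stop("genotype table lacks individual_id")
  df$individual_id <- as.character(df$individual_id)
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup)) stop("duplicated individual id(s): ", paste(unique(dup), collapse = ", "))
  meta <- c("individual_id", if (role == "seed") "mother_id")
  if (role == "seed") {
    if (!"mother_id" %in% names(df)) stop("seed table lacks mother_id")
    df$mother_id <- as.character(df$mother_id)
    if (!is.null(adults)) {
      bad <- setdiff(unique(df$mother_id), adults$individual_id)
      if (length(bad)) stop("seed(s) reference unknown mother(s): ",
                            paste(bad, collapse = ", "))
    }
  }
  acols <- setdiff(names(df), c("individual_id", "mother_id"))
  if (length(acols) %% 2 != 0) stop("odd number of allele columns: ", length(acols))
  loci <- unique(sub("_[12]$", "", acols))
  expect <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  if (!all(expect %in% acols)) {
    stop("allele columns must come in <locus>_1/<locus>_2 pairs; missing: ",
         paste(setdiff(expect, acols), collapse = ", "))
  }
  out <- df[, c(meta, expect), drop = FALSE]
  for (col in expect) {
    v <- suppressWarnings(as.integer(out[[col]]))
    v[!is.na(v) & v <= 0] <- NA_integer_   # 0 is the file sentinel for missing
    out[[col]] <- v
  }
  # canonicalise within-locus allele order (sorted, NA last)
  for (loc in loci) {
    a1 <- out[[paste0(loc, "_1")]]; a2 <- out[[paste0(loc, "_2")]]
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    only <- ifelse(is.na(a1), a2, a1)       # one-sided missing: keep known first
    swap <- is.na(lo)
    lo[swap] <- only[swap]; hi[swap] <- NA_integer_
    both_na <- is.na(a1) & is.na(a2)
    lo[both_na] <- NA_integer_
    out[[paste0(loc, "_1")]] <- lo; out[[paste0(loc, "_2")]] <- hi
  }
  rownames(out) <- NULL
  structure(out, role = role, loci = loci,
            class = c("genotype_table", "data.frame"))
}

#' Read a multilocus genotype table from a delimited text file
#'
#' Expects a comma-separated file with a header: `individual_id`, two columns
#' per locus named `<locus>_1` and `<locus>_2`, and for seeds a `mother_id`
#' column. Allele code 0 (or blank) is read as missing.
#'
#' @inheritParams genotype_table
#' @param path file path.
#' @return A [genotype_table] object.
#' @export
read_genotypes <- function(path, role = c("adult", "seed"), adults = NULL) {
  role <- match.arg(role)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  genotype_table(df, role = role, adults = adults)
}

#' Write a genotype table to a delimited text file
#'
#' Missing alleles are written with the conventional 0 sentinel, so a written
#' table reads back identically.
#'
#' @param gt a [genotype_table].
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  df <- as.data.frame(gt)
  for (col in allele_columns(gt)) df[[col]][is.na(df[[col]])] <- 0L
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locus names of a genotype table
#' @param gt a [genotype_table].
#' @return Character vector of locus names.
#' @export
loci <- function(gt) attr(gt, "loci")

allele_columns <- function(gt) {
  as.vector(rbind(paste0(loci(gt), "_1"), paste0(loci(gt), "_2")))
}

# Alleles of one locus as an n x 2 integer matrix
locus_matrix <- function(gt, locus) {
  cbind(gt[[paste0(locus, "_1")]], gt[[paste0(locus, "_2")]])
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table (%s): %d individuals x %d loci\n",
              attr(x, "role"), nrow(x), length(loci(x))))
  miss <- mean(is.na(as.matrix(x[, allele_columns(x)])))
  cat(sprintf("  missing allele calls: %.1f%%\n", 100 * miss))
  invisible(x)
}
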