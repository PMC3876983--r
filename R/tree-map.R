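#' Construct a mapped adult-tree table
#'
#' A tree map records every candidate pollen donor in the study plot: a unique
#' id, metric x/y coordinates (origin at the plot's south-west corner),
#' optional diameter at breast height, and a flowering status per observed
#' season. Flowering status takes one of three states: `"flowering"`,
#' `"not_flowering"` or `"unknown"` (trees whose phenology was not scored
#' cannot be ruled out as pollen donors).
#'
#' @param df data.frame with columns `tree_id`, `x`, `y`, optionally `dbh`,
#'   and one `flowering_<season>` column per season.
#' @param plot_width,plot_height plot dimensions in metres (defaults emulate a
#'   40-ha, 500 x 800 m rainforest plot).
#' @return An object of class `tree_map` (a data.frame with plot-dimension
#'   attributes).
#' @seealso [read_tree_map()]
#' @export
tree_map <- function(df, plot_width = 500, plot_height = 800) {
  stopifnot(is.data.frame(df))
  need <- c("tree_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tree map lacks columns: ", paste(miss, collapse = ", "))
  df$tree_id <- as.character(df$tree_id)
  dup <- df$tree_id[duplicated(df$tree_id)]
  if (length(dup)) stop("duplicated tree id(s): ", paste(unique(dup), collapse = ", "))
  for (col in c("x", "y")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric ", col, " coordinate at row(s): ", paste(bad, collapse = ", "))
    }
  }
  out_x <- which(df$x < 0 | df$x > plot_width)
  out_y <- which(df$y < 0 | df$y > plot_height)
  if (length(c(out_x, out_y))) {
    stop("coordinates outside the ", plot_width, " x ", plot_height,
         " m plot at row(s): ", paste(sort(unique(c(out_x, out_y))), collapse = ", "))
  }
  if (!"dbh" %in% names(df)) df$dbh <- rep(NA_real_, nrow(df))
  fcols <- grep("^flowering_", names(df), value = TRUE)
  for (col in fcols) df[[col]] <- canonical_flowering(df[[col]])
  rownames(df) <- NULL
  structure(df,
            plot_width = plot_width, plot_height = plot_height,
            seasons = sub("^flowering_", "", fcols),
            class = c("tree_map", "data.frame"))
}

# Map the flowering-status spellings found in field sheets onto the three
# canonical states; anything unrecognised (incl. blanks/NA) becomes "unknown".
canonical_flowering <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "y", "yes", "true", "flowering", "f")] <- "flowering"
  out[x %in% c("0", "n", "no", "false", "not_flowering", "nf")] <- "not_flowering"
  out
}

#' Read a mapped adult-tree table from a delimited text file
#'
#' Expects a comma-separated file with header columns `tree_id,x,y` (and
#' optionally `dbh` plus one `flowering_<season>` column per season).
#' Flowering entries `1/yes/flowering` map to flowering, `0/no` to
#' not-flowering, and blanks/`NA`/anything else to unknown status.
#'
#' @inheritParams tree_map
#' @param path file path.
#' @return A [tree_map] object.
#' @export
read_tree_map <- function(path, plot_width = 500, plot_height = 800) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  if (nrow(df)) {
    for (col in intersect(c("x", "y", "dbh"), names(df))) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(num) & !(df[[col]] %in% c("", "NA")) )
      if (col %in% c("x", "y") && length(bad))
        stop("non-numeric ", col, " coordinate at row(s): ", paste(bad, collapse = ", "))
      df[[col]] <- num
    }
  } else {
    df$x <- numeric(0); df$y <- numeric(0)
  }
  tree_map(df, plot_width = plot_width, plot_height = plot_height)
}

#' Write a tree map to a delimited text file
#'
#' @param tm a [tree_map] object.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_tree_map <- function(tm, path) {
  stopifnot(inherits(tm, "tree_map"))
  write.csv(as.data.frame(tm), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Seasons recorded in a tree map
#' @param tm a [tree_map] object.
#' @return Character vector of season labels.
#' @export
seasons <- function(tm) attr(tm, "seasons")

#' Flowering status of every tree in a given season
#' @param tm a [tree_map] object.
#' @param season season label.
#' @return Named character vector over tree ids with values
#'   `flowering` / `not_flowering` / `unknown`.
#' @export
flowering_status <- function(tm, season) {
  col <- paste0("flowering_", season)
  if (!col %in% names(tm)) stop("season ", season, " not recorded in tree map")
  stats::setNames(tm[[col]], tm$tree_id)
}

# Candidate pollen donors in a season: flowering adults plus unknown-status
# adults (they cannot be ruled out); not-flowering adults are excluded.
candidate_ids <- function(tm, season) {
  st <- flowering_status(tm, season)
  names(st)[st != "not_flowering"]
}

# Euclidean distance matrix between two sets of tree ids
tree_distances <- function(tm, ids_from, ids_to) {
  i <- match(ids_from, tm$tree_id)
  j <- match(ids_to, tm$tree_id)
  if (anyNA(i) || anyNA(j)) stop("unknown tree id in distance query")
  dx <- outer(tm$x[i], tm$x[j], "-")
  dy <- outer(tm$y[i], tm$y[j], "-")
  d <- sqrt(dx^2 + dy^2)
  dimnames(d) <- list(ids_from, ids_to)
  d
}

#' @export
print.tree_map <- function(x, ...) {
  cat(sprintf("Tree map: %d adults in a %g x %g m plot (%.2f trees/ha)\n",
              nrow(x), attr(x, "plot_width"), attr(x, "plot_height"),
              nrow(x) / (attr(x, "plot_width") * attr(x, "plot_height") / 1e4)))
  for (s in seasons(x)) {
    st <- flowering_status(x, s)
    cat(sprintf("  season %s: %d flowering, %d not flowering, %d unknown\n",
                s, sum(st == "flowering"), sum(st == "not_flowering"),
                sum(st == "unknown")))
  }
  invisible(x)
}
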