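#' Validate a long-format card-sort table
#'
#' A sorting dataset records how each sorter partitioned the full item set
#' into piles. The table is long format with one row per (sorter, item)
#' assignment; pile labels are local to each sorter (pile "1" of one sorter
#' has nothing to do with pile "1" of another).
#'
#' A sort is complete when every sorter has assigned every item to exactly
#' one pile; incomplete or duplicated assignments are rejected.
#'
#' @param sorts Data frame with columns `sorter_id`, `item_id`, `pile`.
#' @return The input as a tibble with character identifier columns, invisibly
#'   validated.
#' @export
validate_sorts <- function(sorts) {
  if (!is.data.frame(sorts) || nrow(sorts) == 0) {
    stop_input("Sorting dataset is empty.")
  }
  needed <- c("sorter_id", "item_id", "pile")
  missing <- setdiff(needed, names(sorts))
  if (length(missing) > 0) {
    stop_input(paste0("Sorting dataset lacks column(s): ",
                      paste(missing, collapse = ", "), "."))
  }
  sorts <- tibble::as_tibble(sorts)
  sorts <- dplyr::mutate(sorts, dplyr::across(dplyr::all_of(needed), as.character))
  if (anyNA(sorts[needed])) {
    stop_input("Sorting dataset contains missing sorter, item or pile values.")
  }
  dup <- dplyr::count(sorts, .data$sorter_id, .data$item_id)
  if (any(dup$n > 1)) {
    first <- dup[dup$n > 1, ][1, ]
    stop_input(sprintf("Duplicate assignment: sorter '%s' placed item '%s' more than once.",
                       first$sorter_id, first$item_id))
  }
  items <- sort(unique(sorts$item_id))
  if (length(items) < 2) stop_input("Sorting dataset needs at least 2 items.")
  per_sorter <- dplyr::count(sorts, .data$sorter_id)
  incomplete <- per_sorter$sorter_id[per_sorter$n != length(items)]
  if (length(incomplete) > 0) {
    stop_input(sprintf("Sorter '%s' did not sort every item (complete sorts required).",
                       incomplete[1]))
  }
  sorts
}

#' Flag sorters who executed the sorting task incorrectly
#'
#' A sort carries no information about item similarity when all items are
#' lumped in a single pile or every item sits alone; such sorts are flagged
#' invalid and, by default, excluded from the similarity matrix and the
#' reliability analysis.
#'
#' @inheritParams validate_sorts
#' @return A tibble with one row per sorter: `sorter_id`, `n_piles`,
#'   `n_items`, `valid`.
#' @export
sorter_validity <- function(sorts) {
  sorts <- validate_sorts(sorts)
  dplyr::summarise(
    dplyr::group_by(sorts, .data$sorter_id),
    n_piles = dplyr::n_distinct(.data$pile),
    n_items = dplyr::n(),
    .groups = "drop"
  ) |>
    dplyr::mutate(valid = .data$n_piles > 1 & .data$n_piles < .data$n_items)
}

#' Build the co-sort similarity matrix
#'
#' Entry (i, j) counts the sorters who placed items i and j in the same pile.
#' The diagonal equals the number of retained sorters. This co-occurrence
#' matrix is the starting point of the concept-mapping analysis: more often
#' co-piled means more similar.
#'
#' @inheritParams validate_sorts
#' @param exclude_invalid Drop sorters flagged by [sorter_validity()]
#'   (all-in-one-pile or all-singleton sorts). Default `TRUE`.
#' @return An object of class `dtpd_similarity`: a list with `counts`
#'   (named symmetric integer matrix), `n_sorters` (retained sorters),
#'   `items`, and `excluded` (ids of dropped sorters). Use [tidy()] for a
#'   long tibble of item pairs.
#' @export
build_similarity <- function(sorts, exclude_invalid = TRUE) {
  sorts <- validate_sorts(sorts)
  if (isTRUE(exclude_invalid)) {
    validity <- sorter_validity(sorts)
    excluded <- validity$sorter_id[!validity$valid]
    sorts <- dplyr::filter(sorts, !.data$sorter_id %in% excluded)
    if (nrow(sorts) == 0) {
      stop_input(paste0(
        "All sorters are invalid (each sort is all-in-one-pile or ",
        "all-singletons); nothing left after exclusion."
      ))
    }
  } else {
    excluded <- character(0)
  }
  items <- sort(unique(sorts$item_id))
  sorters <- unique(sorts$sorter_id)
  n <- length(items)
  counts <- matrix(0L, n, n, dimnames = list(items, items))
  for (s in sorters) {
    one <- sorts[sorts$sorter_id == s, ]
    # indicator matrix items x piles; crossprod counts co-piled pairs
    ind <- table(factor(one$item_id, levels = items), one$pile)
    counts <- counts + tcrossprod(unclass(ind))
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, n_sorters = length(sorters), items = items,
         excluded = excluded),
    class = "dtpd_similarity"
  )
}

#' @export
print.dtpd_similarity <- function(x, ...) {
  cat(sprintf("<dtpd_similarity> %d items, %d sorters", length(x$items), x$n_sorters))
  if (length(x$excluded) > 0) {
    cat(sprintf(" (%d invalid sorter(s) excluded)", length(x$excluded)))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dtpd_similarity <- function(x, ...) {
  pairs <- upper_pairs(length(x$items))
  tibble::tibble(
    item_i = x$items[pairs[, 1]],
    item_j = x$items[pairs[, 2]],
    count = x$counts[pairs]
  )
}

#' Dissimilarities implied by a similarity matrix
#'
#' Converts co-sort counts into dissimilarities
#' \eqn{\delta_{ij} = (S - c_{ij})/S} where S is the number of retained
#' sorters: items never co-piled are maximally dissimilar (1), items always
#' co-piled maximally similar (0).
#'
#' @param sim A `dtpd_similarity` object.
#' @return A symmetric numeric matrix in \[0, 1\] with zero diagonal.
#' @export
sort_dissimilarity <- function(sim) {
  stopifnot(inherits(sim, "dtpd_similarity"))
  (sim$n_sorters - sim$counts) / sim$n_sorters
}

#' Average number of piles per sorter
#'
#' Diagnostic used when choosing the number of clusters: the mean (and range)
#' of piles the participants themselves created.
#'
#' @inheritParams validate_sorts
#' @return A one-row tibble: `mean_piles`, `min_piles`, `max_piles`,
#'   `n_sorters`.
#' @export
pile_count_summary <- function(sorts) {
  v <- sorter_validity(sorts)
  tibble::tibble(
    mean_piles = mean(v$n_piles),
    min_piles = min(v$n_piles),
    max_piles = max(v$n_piles),
    n_sorters = nrow(v)
  )
}
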