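#' Hierarchical cluster ladder over the concept map
#'
#' Agglomerative (Ward) clustering of the 2-D map coordinates, reported as a
#' ladder of solutions from `k_max` clusters down to `k_min`: at each step
#' exactly two clusters are merged, so every coarser partition is a
#' coarsening of the finer one. Choosing the working number of clusters is a
#' judgement call informed by diagnostics (average participant pile count,
#' bridging values); the ladder only supplies the candidate solutions.
#'
#' @param map A `dtpd_map` from [embed_map()].
#' @param k_max,k_min Range of cluster counts (defaults 15 and 2).
#' @return An object of class `dtpd_ladder`: `assignments` (tibble with
#'   columns `k`, `item_id`, `cluster`), the underlying `hclust` tree, and
#'   the k range. Use [ladder_solution()] to extract one solution.
#' @export
cluster_ladder <- function(map, k_max = 15, k_min = 2) {
  stopifnot(inherits(map, "dtpd_map"))
  n <- length(map$items)
  if (k_min > k_max) stop_input("k_min must not exceed k_max.")
  if (k_min < 1) stop_input("k_min must be at least 1.")
  if (k_max > n) stop_input("k_max cannot exceed the number of items.")
  tree <- hclust(dist(map$coords), method = "ward.D2")
  ks <- seq(k_max, k_min)
  cuts <- cutree(tree, k = ks)
  if (length(ks) == 1) cuts <- matrix(cuts, ncol = 1)
  assignments <- purrr::map_dfr(seq_along(ks), function(j) {
    tibble::tibble(k = ks[j], item_id = map$items,
                   cluster = unname(cuts[, j]))
  })
  structure(
    list(assignments = assignments, tree = tree,
         k_max = k_max, k_min = k_min, items = map$items),
    class = "dtpd_ladder"
  )
}

#' @export
print.dtpd_ladder <- function(x, ...) {
  cat(sprintf("<dtpd_ladder> %d items, solutions for k = %d..%d (Ward)\n",
              length(x$items), x$k_max, x$k_min))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dtpd_ladder <- function(x, ...) x$assignments

#' Extract one cluster solution from a ladder
#'
#' @param ladder A `dtpd_ladder`.
#' @param k Number of clusters.
#' @return Tibble `item_id`, `cluster`.
#' @export
ladder_solution <- function(ladder, k) {
  stopifnot(inherits(ladder, "dtpd_ladder"))
  if (!k %in% unique(ladder$assignments$k)) {
    stop_input(sprintf("No solution for k = %d in this ladder (range %d..%d).",
                       k, ladder$k_min, ladder$k_max))
  }
  dplyr::select(dplyr::filter(ladder$assignments, .data$k == !!k),
                "item_id", "cluster")
}

#' Bridging values: coherence of each item's map position
#'
#' For item i the raw bridging value is the co-sort-weighted mean map
#' distance \eqn{b_i = \sum_{j\ne i} c_{ij} d_{ij} / \sum_{j\ne i} c_{ij}}:
#' small when the sorters who grouped item i did so with items that ended up
#' nearby on the map, large when the item "bridges" distant regions. Raw
#' values are min-max normalised to \[0, 1\] across items; low values
#' indicate cluster coherence. If every raw value is identical the
#' normalisation is degenerate and all items are reported as 0. An item never
#' co-piled with any other has an undefined value (`defined = FALSE`, value
#' `NA`), never a silent 0.
#'
#' @param map A `dtpd_map`.
#' @param sim The `dtpd_similarity` the map was built from.
#' @return Tibble `item_id`, `raw`, `bridging`, `defined`.
#' @export
bridging_values <- function(map, sim) {
  stopifnot(inherits(map, "dtpd_map"), inherits(sim, "dtpd_similarity"))
  if (!identical(map$items, sim$items)) {
    stop_input("Map and similarity matrix cover different item sets.")
  }
  n <- length(map$items)
  if (n < 2) stop_input("At least 2 items are required for bridging values.")
  d <- as.matrix(dist(map$coords))
  counts <- sim$counts
  diag(counts) <- 0L
  wsum <- rowSums(counts)
  raw <- ifelse(wsum > 0, rowSums(counts * d) / wsum, NA_real_)
  defined <- wsum > 0
  if (any(!defined)) {
    warn(sprintf("%d item(s) were never co-piled with any other item; their bridging values are undefined.",
                 sum(!defined)))
  }
  rng <- range(raw[defined])
  bridging <- if (diff(rng) < 1e-12) {
    ifelse(defined, 0, NA_real_)        # degenerate normalisation
  } else {
    (raw - rng[1]) / (rng[2] - rng[1])
  }
  tibble::tibble(item_id = map$items, raw = unname(raw),
                 bridging = unname(bridging), defined = unname(defined))
}

#' Per-cluster bridging summary
#'
#' Cluster-level bridging is the arithmetic mean of the member items'
#' normalised bridging values; low cluster bridging indicates a homogeneous
#' cluster.
#'
#' @param bridging Output of [bridging_values()].
#' @param solution Tibble `item_id`, `cluster` (e.g. [ladder_solution()]).
#' @return Tibble `cluster`, `n_items`, `cluster_bridging`.
#' @export
cluster_bridging <- function(bridging, solution) {
  dplyr::inner_join(bridging, solution, by = "item_id") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_items = dplyr::n(),
                     cluster_bridging = mean(.data$bridging),
                     .groups = "drop")
}
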