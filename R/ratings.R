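#' Validate a long-format rating table
#'
#' Each rater scores items for perceived importance on a 1-6 integer scale;
#' not every rater needs to rate every item.
#'
#' @param ratings Data frame with columns `rater_id`, `item_id`, `rating`.
#' @return The input as a tibble, validated.
#' @export
validate_ratings <- function(ratings) {
  if (!is.data.frame(ratings) || nrow(ratings) == 0) {
    stop_input("Rating dataset is empty.")
  }
  needed <- c("rater_id", "item_id", "rating")
  missing <- setdiff(needed, names(ratings))
  if (length(missing) > 0) {
    stop_input(paste0("Rating dataset lacks column(s): ",
                      paste(missing, collapse = ", "), "."))
  }
  ratings <- tibble::as_tibble(ratings)
  ratings$rater_id <- as.character(ratings$rater_id)
  ratings$item_id <- as.character(ratings$item_id)
  r <- ratings$rating
  ok <- !is.na(r) & r == as.integer(r) & r >= 1 & r <= 6
  if (!all(ok)) {
    stop_input(sprintf("Rating '%s' at row %d is not an integer in 1-6.",
                       as.character(r[which(!ok)[1]]), which(!ok)[1]))
  }
  ratings$rating <- as.integer(r)
  ratings
}

#' Item-level mean importance ratings
#'
#' @inheritParams validate_ratings
#' @return Tibble `item_id`, `mean_rating`, `n_ratings`.
#' @export
item_ratings <- function(ratings) {
  ratings <- validate_ratings(ratings)
  dplyr::summarise(dplyr::group_by(ratings, .data$item_id),
                   mean_rating = mean(.data$rating),
                   n_ratings = dplyr::n(), .groups = "drop")
}

#' Cluster rating means with Bonferroni-corrected pairwise tests
#'
#' Summarises importance ratings at the cluster level (mean of the member
#' items' mean ratings) and tests every pair of clusters with a two-sample
#' t-test on the item-level means. Because all k(k-1)/2 pairs are tested, the
#' significance threshold is Bonferroni-corrected to `alpha / (k(k-1)/2)` -
#' for 6 clusters that is 0.05/15 = 0.00333. Near-equal cluster ratings are
#' the basis for weighting the clusters evenly in the final instrument.
#'
#' @inheritParams validate_ratings
#' @param solution Tibble `item_id`, `cluster` (e.g. [ladder_solution()]).
#' @param alpha Familywise significance level, default 0.05.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return An object of class `dtpd_rating_summary`: `cluster_means` tibble,
#'   `tests` tibble (one row per cluster pair: `t`, `df`, `p_value`,
#'   `computable`, `significant`), `threshold`, `n_tests`, `alpha`.
#' @export
rating_summary <- function(ratings, solution, alpha = 0.05, var_equal = FALSE) {
  per_item <- item_ratings(ratings)
  solution <- tibble::as_tibble(solution)
  joined <- dplyr::inner_join(per_item, solution, by = "item_id")
  missing_items <- setdiff(solution$item_id, per_item$item_id)
  if (length(missing_items) > 0) {
    stop_input(sprintf("Item '%s' has no ratings.", missing_items[1]))
  }
  clusters <- sort(unique(joined$cluster))
  k <- length(clusters)
  if (k < 2) stop_input("At least 2 clusters are required for pairwise tests.")
  n_tests <- k * (k - 1) / 2
  threshold <- alpha / n_tests

  cluster_means <- dplyr::summarise(
    dplyr::group_by(joined, .data$cluster),
    n_items = dplyr::n(),
    sd_rating = sd(.data$mean_rating),
    mean_rating = mean(.data$mean_rating),
    .groups = "drop"
  )

  pair_idx <- utils::combn(clusters, 2)
  tests <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(p) {
    a <- pair_idx[1, p]; b <- pair_idx[2, p]
    xa <- joined$mean_rating[joined$cluster == a]
    xb <- joined$mean_rating[joined$cluster == b]
    computable <- length(xa) >= 2 && length(xb) >= 2 &&
      (sd(xa) > 0 || sd(xb) > 0)
    if (computable) {
      tt <- stats::t.test(xa, xb, var.equal = var_equal)
      tibble::tibble(cluster_a = a, cluster_b = b,
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value, computable = TRUE)
    } else if (length(xa) >= 2 && length(xb) >= 2) {
      # both samples constant: no variance, t defined as 0 when means equal
      eq <- isTRUE(all.equal(mean(xa), mean(xb)))
      tibble::tibble(cluster_a = a, cluster_b = b,
                     t = if (eq) 0 else NA_real_, df = NA_real_,
                     p_value = if (eq) 1 else NA_real_, computable = eq)
    } else {
      tibble::tibble(cluster_a = a, cluster_b = b, t = NA_real_,
                     df = NA_real_, p_value = NA_real_, computable = FALSE)
    }
  })
  tests$significant <- !is.na(tests$p_value) & tests$p_value < threshold

  structure(
    list(cluster_means = cluster_means, tests = tests, threshold = threshold,
         n_tests = n_tests, alpha = alpha, k = k, var_equal = var_equal),
    class = "dtpd_rating_summary"
  )
}

#' @export
print.dtpd_rating_summary <- function(x, ...) {
  cat(sprintf("<dtpd_rating_summary> %d clusters, %d pairwise tests, Bonferroni threshold p < %.5f\n",
              x$k, x$n_tests, x$threshold))
  print(x$cluster_means)
  sig <- x$tests[x$tests$significant, ]
  if (nrow(sig) > 0) {
    cat("Significant pairs:\n")
    print(sig)
  } else {
    cat("No significant cluster pairs.\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dtpd_rating_summary <- function(x, ...) x$tests

#' @exportS3Method generics::glance
glance.dtpd_rating_summary <- function(x, ...) {
  tibble::tibble(k = x$k, n_tests = x$n_tests, alpha = x$alpha,
                 threshold = x$threshold,
                 n_significant = sum(x$tests$significant))
}
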