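#' Sorter reliability: individual versus group co-pile agreement
#'
#' For each sorter, the binary co-pile matrix (1 if the sorter put a pair of
#' items in the same pile) is vectorised over its upper triangle and
#' correlated (Pearson; with a binary variable this is the point-biserial
#' correlation) with the corresponding vector of group co-pile counts. By
#' default the group matrix is computed leave-one-out - from all sorters
#' except the one being scored - so a sorter is never correlated with their
#' own contribution; set `include_self = TRUE` to correlate against the full
#' total matrix instead. The per-sorter correlations are averaged, and a
#' Spearman-Brown step-up \eqn{k r / (1 + (k-1) r)} extrapolates the average
#' to the reliability of the whole panel of k sorters.
#'
#' Sorters whose binary matrix is constant (after exclusion of invalid sorts
#' this can still happen in principle) have an undefined correlation and are
#' dropped from the average with a warning.
#'
#' @inheritParams validate_sorts
#' @param spearman_brown Also report the Spearman-Brown corrected value.
#' @param include_self Correlate each sorter against the total matrix
#'   including themselves rather than leave-one-out.
#' @param exclude_invalid Drop invalid sorters first (see [sorter_validity()]).
#' @return An object of class `dtpd_reliability`: `per_sorter` tibble
#'   (`sorter_id`, `r`), `mean_r`, `sb_corrected` (or `NA`),
#'   `correction_applied`, `k`.
#' @export
sorter_reliability <- function(sorts, spearman_brown = TRUE,
                               include_self = FALSE, exclude_invalid = TRUE) {
  sorts <- validate_sorts(sorts)
  if (isTRUE(exclude_invalid)) {
    validity <- sorter_validity(sorts)
    sorts <- dplyr::filter(sorts, .data$sorter_id %in%
                             validity$sorter_id[validity$valid])
  }
  sorters <- unique(sorts$sorter_id)
  if (length(sorters) < 2) {
    stop_input("At least 2 valid sorters are required for reliability.")
  }
  items <- sort(unique(sorts$item_id))
  n <- length(items)
  pairs <- upper_pairs(n)

  copile <- function(one) {
    ind <- table(factor(one$item_id, levels = items), one$pile)
    m <- tcrossprod(unclass(ind))
    m[pairs]
  }
  indiv <- vapply(sorters, function(s) copile(sorts[sorts$sorter_id == s, ]),
                  numeric(nrow(pairs)))
  total <- rowSums(indiv)

  r <- vapply(seq_along(sorters), function(j) {
    ref <- if (include_self) total else total - indiv[, j]
    if (sd(indiv[, j]) == 0 || sd(ref) == 0) return(NA_real_)
    cor(indiv[, j], ref)
  }, numeric(1))

  dropped <- is.na(r)
  if (any(dropped)) {
    warn(sprintf("Correlation undefined for sorter(s) %s (constant co-pile matrix); excluded from the average.",
                 paste(sorters[dropped], collapse = ", ")))
  }
  per_sorter <- tibble::tibble(sorter_id = sorters, r = r)
  mean_r <- mean(r[!dropped])
  k <- length(sorters)
  sb <- if (isTRUE(spearman_brown)) k * mean_r / (1 + (k - 1) * mean_r) else NA_real_

  structure(
    list(per_sorter = per_sorter, mean_r = mean_r, sb_corrected = sb,
         correction_applied = isTRUE(spearman_brown), k = k,
         include_self = include_self),
    class = "dtpd_reliability"
  )
}

#' @export
print.dtpd_reliability <- function(x, ...) {
  cat(sprintf("<dtpd_reliability> %d sorters, mean r = %.3f", x$k, x$mean_r))
  if (x$correction_applied) {
    cat(sprintf(", Spearman-Brown corrected = %.3f", x$sb_corrected))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dtpd_reliability <- function(x, ...) x$per_sorter

#' @exportS3Method generics::glance
glance.dtpd_reliability <- function(x, ...) {
  tibble::tibble(k = x$k, mean_r = x$mean_r, sb_corrected = x$sb_corrected,
                 correction_applied = x$correction_applied)
}
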