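#' Plot a concept map
#'
#' Items on the 2-D plane, optionally coloured by a cluster solution and
#' sized by bridging value.
#'
#' @param object A `dtpd_map`.
#' @param solution Optional tibble `item_id`, `cluster`.
#' @param bridging Optional output of [bridging_values()].
#' @param label Draw item labels, default `FALSE`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dtpd_map <- function(object, solution = NULL, bridging = NULL,
                              label = FALSE, ...) {
  df <- tidy(object)
  if (!is.null(solution)) {
    df <- dplyr::left_join(df, tibble::as_tibble(solution), by = "item_id") |>
      dplyr::mutate(cluster = factor(.data$cluster))
  }
  if (!is.null(bridging)) {
    df <- dplyr::left_join(df, dplyr::select(bridging, "item_id", "bridging"),
                           by = "item_id")
  }
  aes <- ggplot2::aes(x = .data$x, y = .data$y)
  p <- ggplot2::ggplot(df, aes)
  p <- if (!is.null(solution) && !is.null(bridging)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster,
                                         size = .data$bridging), alpha = 0.8)
  } else if (!is.null(solution)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$item_id),
                                vjust = -0.7, size = 2.5)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Concept map (stress-1 = %.3f)", object$stress),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `dtpd_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dtpd_roc <- function(object, ...) {
  df <- dplyr::arrange(object$points, .data$one_minus_specificity, .data$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$one_minus_specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("ROC curve, AUC = %.3f (%.3f-%.3f)",
                      object$auc, object$ci_lower, object$ci_upper),
      x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a cut-off sensitivity/specificity table
#'
#' @param object A `dtpd_cutoff_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dtpd_cutoff_table <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("sensitivity", "specificity"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(title = "Sensitivity and specificity by sum-score cut-off",
                  x = "Cut-off (criteria positively scored)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
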