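#' Pilot-study agreement between each criterion and clinical judgement
#'
#' For each of the seven criteria, the percentage of records on which the
#' criterion answer agrees with the clinician's referral judgement
#' (yes-with-yes or no-with-no; NA counts as no). The alternative
#' `"joint_positive"` definition reports the percentage of records where the
#' criterion is positive and the clinician judged referral at the same time.
#'
#' @param records Patient record tibble.
#' @param definition `"agreement"` (default) or `"joint_positive"`.
#' @param config A [tool_config()].
#' @return Tibble `criterion`, `label`, `percent`, `computable` (`FALSE`
#'   when a criterion is NA on every record).
#' @export
pilot_agreement <- function(records,
                            definition = c("agreement", "joint_positive"),
                            config = tool_config()) {
  definition <- match.arg(definition)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop_input("Patient record table is empty.")
  norm <- normalize_answers(records, config)
  judged <- parse_judgement(records)
  purrr::map_dfr(1:7, function(j) {
    a <- norm$ans[, j]
    computable <- any(a != "na")
    pct <- if (!computable) {
      NA_real_
    } else if (definition == "agreement") {
      100 * mean((a == "yes") == judged)
    } else {
      100 * mean(a == "yes" & judged)
    }
    tibble::tibble(criterion = j, label = config$criterion_names[j],
                   percent = pct, computable = computable)
  })
}

#' ROC curve and AUC with confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance (ties
#' count one half), with a 95% DeLong confidence interval by default or a
#' seeded stratified bootstrap. In the validation analysis the scores are
#' the linear predictors of the marginal logistic model
#' ([fit_marginal_logistic()]) and the labels the clinical judgement.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome: logical, 0/1 or yes/no tokens.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level, default 0.95.
#' @param seed Seed for the bootstrap (required for `ci_method =
#'   "bootstrap"`).
#' @param boot_n Bootstrap replicates, default 2000.
#' @return Object of class `dtpd_roc`: `auc`, `ci_lower`, `ci_upper`,
#'   `ci_method`, `n_pos`, `n_neg`, and a `points` tibble
#'   (`threshold`, `sensitivity`, `one_minus_specificity`).
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    conf_level = 0.95, seed = 1, boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  if (is.character(labels) || is.factor(labels)) {
    labels <- normalize_token(labels, c("yes", "no"), "outcome label") == "yes"
  }
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_input("scores and labels differ in length.")
  if (anyNA(scores) || anyNA(labels)) stop_input("scores/labels must not contain NA.")
  if (!any(labels) || all(labels)) {
    stop_input("Both outcome classes must be present to compute a ROC curve.")
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(roc, conf.level = conf_level, method = "delong"))
  } else {
    with_seed(seed,
              as.numeric(pROC::ci.auc(roc, conf.level = conf_level,
                                      method = "bootstrap", boot.n = boot_n)))
  }
  points <- tibble::tibble(
    threshold = roc$thresholds,
    sensitivity = roc$sensitivities,
    one_minus_specificity = 1 - roc$specificities
  )
  structure(
    list(auc = auc, ci_lower = ci[1], ci_upper = ci[3],
         conf_level = conf_level, ci_method = ci_method,
         n_pos = sum(labels), n_neg = sum(!labels), points = points),
    class = "dtpd_roc"
  )
}

#' @export
print.dtpd_roc <- function(x, ...) {
  cat(sprintf("<dtpd_roc> AUC = %.3f (%d%% CI %.3f-%.3f, %s), %d pos / %d neg\n",
              x$auc, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dtpd_roc <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.dtpd_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 conf_level = x$conf_level, ci_method = x$ci_method,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Sensitivity and specificity at every sum-score cut-off
#'
#' For each candidate cut-off k = 1..7: sensitivity is the share of patients
#' clinically judged to need highly specialized care whose criterion score
#' reaches k, specificity the share of the remaining patients whose score
#' stays below k. Raising k trades sensitivity for specificity, which is the
#' basis on which the working cut-off (4) was chosen.
#'
#' @param records Patient record tibble with `clinical_judgement`.
#' @param config A [tool_config()].
#' @return Tibble of class `dtpd_cutoff_table`: `cutoff`, `sensitivity`,
#'   `specificity`, `n_pos`, `n_neg`.
#' @export
cutoff_table <- function(records, config = tool_config()) {
  decisions <- score_patients(records, config)
  judged <- parse_judgement(decisions)
  if (!any(judged) || all(judged)) {
    stop_input("Both judgement classes must be present for a cut-off table.")
  }
  s <- decisions$score
  out <- purrr::map_dfr(1:7, function(k) {
    tibble::tibble(
      cutoff = k,
      sensitivity = mean(s[judged] >= k),
      specificity = mean(s[!judged] < k),
      n_pos = sum(judged),
      n_neg = sum(!judged)
    )
  })
  class(out) <- c("dtpd_cutoff_table", class(out))
  out
}

#' Cronbach's alpha for the criterion set
#'
#' Internal consistency of the k items:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' with sample variances (n-1 divisor) used for both the item variances
#' \eqn{s_i^2} and the variance of the total score \eqn{s_T^2}. For the
#' decision tool the items are the seven criteria coded 0/1.
#'
#' @param item_matrix Numeric matrix or data frame, respondents in rows,
#'   items in columns.
#' @return Alpha (a number, at most 1; can be negative). `NA` with a warning
#'   when the total score has zero variance.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop_input("Cronbach's alpha needs at least 2 respondents and 2 items.")
  }
  if (anyNA(m)) stop_input("Item matrix must not contain NA; recode first.")
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var < .Machine$double.eps) {
    warn("Total score has zero variance; Cronbach's alpha is undefined.")
    return(NA_real_)
  }
  (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Criterion answers as a 0/1 item matrix
#'
#' Helper turning patient records into the binary item matrix used for
#' Cronbach's alpha and the model design (yes = 1, no/NA = 0).
#'
#' @param records Patient record tibble.
#' @param config A [tool_config()].
#' @return Integer matrix, one column per criterion.
#' @export
criterion_matrix <- function(records, config = tool_config()) {
  norm <- normalize_answers(tibble::as_tibble(records), config)
  m <- (norm$ans == "yes") * 1L
  colnames(m) <- paste0("c", 1:7)
  m
}

#' Welch two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, computed from group means, standard deviations and sizes (the
#' form in which published group comparisons are reported).
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return One-row tibble `t`, `df`, `p_value` (two-sided).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_input("Both groups need at least 2 observations.")
  if (sd1 <= 0 || sd2 <= 0) stop_input("Standard deviations must be positive.")
  se2_1 <- sd1^2 / n1
  se2_2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2_1 + se2_2)
  df <- (se2_1 + se2_2)^2 /
    (se2_1^2 / (n1 - 1) + se2_2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Full validation report for a scored cohort
#'
#' Bundles the Phase-3 analytics: the marginal logistic model, the ROC/AUC
#' of its linear predictor against clinical judgement, the cut-off table of
#' the sum score, Cronbach's alpha of the criterion set, and the pilot
#' agreement percentages.
#'
#' @param records Patient record tibble.
#' @param config A [tool_config()].
#' @param cluster_by Cluster column for the model, default `"centre_id"`.
#' @param ci_method Confidence-interval method for the AUC.
#' @param seed Seed for any bootstrap.
#' @return Object of class `dtpd_validation`: components `gee`, `roc`,
#'   `cutoffs`, `cronbach_alpha`, `pilot_agreement`, `n`.
#' @export
validate_tool <- function(records, config = tool_config(),
                          cluster_by = "centre_id",
                          ci_method = c("delong", "bootstrap"), seed = 1) {
  ci_method <- match.arg(ci_method)
  records <- tibble::as_tibble(records)
  gee <- fit_marginal_logistic(records, cluster_by = cluster_by, config = config)
  judged <- parse_judgement(records)
  roc <- roc_auc(gee$linear_predictors, judged, ci_method = ci_method, seed = seed)
  cutoffs <- cutoff_table(records, config)
  alpha <- cronbach_alpha(criterion_matrix(records, config))
  agreement <- pilot_agreement(records, config = config)
  structure(
    list(gee = gee, roc = roc, cutoffs = cutoffs, cronbach_alpha = alpha,
         pilot_agreement = agreement, n = nrow(records)),
    class = "dtpd_validation"
  )
}

#' @export
print.dtpd_validation <- function(x, ...) {
  cat(sprintf("<dtpd_validation> n = %d\n", x$n))
  print(x$gee)
  print(x$roc)
  cat(sprintf("Cronbach's alpha: %.3f\n", x$cronbach_alpha))
  cat("Cut-off table:\n")
  print(tibble::as_tibble(x$cutoffs))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dtpd_validation <- function(x, ...) {
  tibble::tibble(n = x$n, auc = x$roc$auc, auc_ci_lower = x$roc$ci_lower,
                 auc_ci_upper = x$roc$ci_upper,
                 cronbach_alpha = x$cronbach_alpha,
                 working_alpha = x$gee$alpha)
}
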