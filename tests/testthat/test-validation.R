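mini_cohort <- function(n = 40, seed = 3) {
  simulate_patients(n_patients = n, seed = seed)$records
}

test_that("pilot agreement counts agreement and joint-positive shares correctly", {
  rec <- mini_cohort(20, seed = 12)
  ag <- pilot_agreement(rec)
  judged <- rec$clinical_judgement == "yes"
  for (j in 1:7) {
    manual <- 100 * mean((rec[[paste0("c", j)]] == "yes") == judged)
    expect_equal(ag$percent[ag$criterion == j], manual)
  }
  jp <- pilot_agreement(rec, definition = "joint_positive")
  for (j in 1:7) {
    manual <- 100 * mean(rec[[paste0("c", j)]] == "yes" & judged)
    expect_equal(jp$percent[jp$criterion == j], manual)
  }
})

test_that("a criterion identical (or opposite) to judgement scores 100% (0%)", {
  judged <- rep(c("yes", "no"), 10)
  rec <- tibble::tibble(
    c1 = judged, c2 = ifelse(judged == "yes", "no", "yes"),
    c3 = "no", c4 = "no", c5 = "no", c6 = "no", c7 = "no",
    q8 = "yes", clinical_judgement = judged
  )
  ag <- pilot_agreement(rec)
  expect_equal(ag$percent[ag$criterion == 1], 100)
  expect_equal(ag$percent[ag$criterion == 2], 0)
})

test_that("an all-NA criterion is flagged not computable", {
  rec <- mini_cohort(15, seed = 4)
  rec$c6 <- "na"
  ag <- pilot_agreement(rec)
  expect_false(ag$computable[ag$criterion == 6])
  expect_true(is.na(ag$percent[ag$criterion == 6]))
})

test_that("AUC equals the exhaustive concordance on hand-listed pairs", {
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.55, 0.5, 0.5, 0.4, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
              TRUE, FALSE, FALSE)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  expect_true(r$ci_lower <= r$auc && r$auc <= r$ci_upper)
})

test_that("perfect separation gives AUC 1 and one-class input errors out", {
  r1 <- suppressWarnings(roc_auc(c(1, 2, 3, 10, 11, 12),
                                 c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)))
  expect_equal(r1$auc, 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "dtpd_input_error")
})

test_that("bootstrap CI is reproducible under a fixed seed", {
  rec <- mini_cohort(60, seed = 7)
  fit <- fit_marginal_logistic(rec)
  labels <- rec$clinical_judgement == "yes"
  b1 <- roc_auc(fit$linear_predictors, labels, ci_method = "bootstrap",
                seed = 5, boot_n = 200)
  b2 <- roc_auc(fit$linear_predictors, labels, ci_method = "bootstrap",
                seed = 5, boot_n = 200)
  expect_equal(b1$ci_lower, b2$ci_lower)
  expect_equal(b1$ci_upper, b2$ci_upper)
})

test_that("cut-off table cells equal brute-force counting and bound rows correctly", {
  rec <- mini_cohort(80, seed = 21)
  ct <- cutoff_table(rec)
  s <- score_patients(rec)$score
  judged <- rec$clinical_judgement == "yes"
  for (k in 1:7) {
    expect_equal(ct$sensitivity[k], sum(s >= k & judged) / sum(judged))
    expect_equal(ct$specificity[k], sum(s < k & !judged) / sum(!judged))
  }
  expect_equal(max(ct$sensitivity), ct$sensitivity[1])
  expect_equal(max(ct$specificity), ct$specificity[7])
  # conservation: counts recoverable from the score distribution
  expect_equal(ct$n_pos[1] + ct$n_neg[1], 80)
})

test_that("an ideally separated cohort has perfect sensitivity and specificity", {
  yes7 <- tibble::tibble(c1 = "yes", c2 = "yes", c3 = "yes", c4 = "yes",
                         c5 = "yes", c6 = "yes", c7 = "yes", q8 = "yes",
                         clinical_judgement = "yes")
  no0 <- tibble::tibble(c1 = "no", c2 = "no", c3 = "no", c4 = "no",
                        c5 = "no", c6 = "no", c7 = "no", q8 = "yes",
                        clinical_judgement = "no")
  rec <- dplyr::bind_rows(yes7[rep(1, 5), ], no0[rep(1, 5), ])
  ct <- cutoff_table(rec)
  expect_true(all(ct$sensitivity == 1))
  expect_true(all(ct$specificity == 1))
})

test_that("Cronbach's alpha reproduces closed-form and boundary cases", {
  # two standardized items with correlation exactly 0.5 -> alpha = 2/3
  a <- c(0, 1, 2)
  b <- c(1, 0, 2)
  expect_equal(cor(a, b), 0.5)
  expect_equal(cronbach_alpha(cbind(a, b)), 2 / 3, tolerance = 1e-12)
  # identical non-constant items -> alpha = 1
  x <- c(0, 1, 1, 0, 1)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  # direct variance-formula recomputation on a seeded binary matrix
  m <- withr::with_seed(31, matrix(rbinom(7 * 25, 1, 0.45), 25, 7))
  k <- ncol(m)
  manual <- (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), manual, tolerance = 1e-12)
})

test_that("alpha is invariant to adding a constant to every item and flags zero variance", {
  m <- withr::with_seed(9, matrix(rbinom(40, 1, 0.5), 10, 4))
  expect_equal(cronbach_alpha(m), cronbach_alpha(m + 3), tolerance = 1e-12)
  expect_warning(a <- cronbach_alpha(matrix(1, 5, 3)), "zero variance")
  expect_true(is.na(a))
})

test_that("Welch t from summaries matches the pooled test at equal variance and n", {
  expect_equal(welch_t(5, 1, 10, 5, 1, 10)$t, 0)
  w <- welch_t(6.2, 1.3, 12, 5.1, 1.3, 12)
  sp <- sqrt((1.3^2 + 1.3^2) / 2)
  t_pooled <- (6.2 - 5.1) / (sp * sqrt(2 / 12))
  expect_equal(w$t, t_pooled, tolerance = 1e-12)
  expect_equal(w$df, 22, tolerance = 1e-9)
  expect_error(welch_t(1, 0, 5, 2, 1, 5), class = "dtpd_input_error")
})

test_that("published-style group summaries give the direct-formula Welch result", {
  # therapist experience comparison: 16.3 (8.7), n=29 vs 8.7 (7.1), n=59
  w <- welch_t(16.3, 8.7, 29, 8.7, 7.1, 59)
  se <- sqrt(8.7^2 / 29 + 7.1^2 / 59)
  expect_equal(w$t, (16.3 - 8.7) / se, tolerance = 1e-12)
  expect_equal(w$t, 4.083, tolerance = 1e-3)
  expect_equal(w$df, 46.89, tolerance = 1e-2)
  expect_lt(w$p_value, 0.001)
})

test_that("validate_tool bundles a coherent report", {
  rec <- mini_cohort(120, seed = 14)
  v <- validate_tool(rec)
  expect_s3_class(v$gee, "dtpd_gee")
  expect_true(v$roc$auc >= 0 && v$roc$auc <= 1)
  expect_true(v$roc$ci_lower <= v$roc$auc && v$roc$auc <= v$roc$ci_upper)
  expect_lte(v$cronbach_alpha, 1)
  expect_equal(nrow(v$cutoffs), 7)
  g <- glance(v)
  expect_equal(g$auc, v$roc$auc)
})
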