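all_combinations <- function() {
  tidyr::expand_grid(
    c1 = c("yes", "no"), c2 = c("yes", "no"), c3 = c("yes", "no"),
    c4 = c("yes", "no"), c5 = c("yes", "no"),
    c6 = c("yes", "no", "na"), c7 = c("yes", "no", "na"),
    q8 = c("yes", "no", "na")
  )
}

test_that("the canonical rule paths behave as the instrument specifies", {
  expect_true(score_patient(rep("yes", 7), "yes")$referral)
  expect_equal(score_patient(rep("yes", 7), "yes")$score, 7L)

  three <- c("yes", "yes", "yes", "no", "no", "no", "no")
  expect_equal(score_patient(three, "yes")$score, 3L)
  expect_false(score_patient(three, "yes")$referral)

  four <- c("yes", "yes", "yes", "yes", "no", "no", "no")
  expect_true(score_patient(four, "na")$referral)    # gate NA -> refer
  expect_false(score_patient(four, "no")$referral)   # gate no -> do not refer
  expect_true(score_patient(four, "yes")$referral)
})

test_that("all 864 answer combinations match the independent rule table", {
  grid <- all_combinations()
  expect_equal(nrow(grid), 2^5 * 3^2 * 3)
  scored <- score_patients(grid)
  oracle <- purrr::map_lgl(seq_len(nrow(grid)), function(i) {
    oracle_decide(unlist(grid[i, paste0("c", 1:7)]), grid$q8[i], cutoff = 4)
  })
  expect_equal(scored$referral, oracle)
  expect_equal(scored$score,
               as.integer(rowSums(as.matrix(grid[paste0("c", 1:7)]) == "yes")))
  expect_true(all(scored$passed_cutoff[scored$referral]))
})

test_that("NA is rejected on criteria that do not admit it", {
  rec <- tibble::tibble(c1 = "na", c2 = "no", c3 = "no", c4 = "no",
                        c5 = "no", c6 = "no", c7 = "no", q8 = "yes")
  expect_error(score_patients(rec), "Criterion 1", class = "dtpd_input_error")
})

test_that("flipping any single answer to yes never revokes a referral", {
  grid <- all_combinations()
  scored <- score_patients(grid)
  for (j in paste0("c", 1:7)) {
    flipped <- grid
    flipped[[j]] <- "yes"
    rescored <- score_patients(flipped)
    expect_true(all(rescored$referral >= scored$referral))
  }
})

test_that("raising the cutoff never increases the number of referrals", {
  cohort <- simulate_patients(n_patients = 120, seed = 5)$records
  n_ref <- purrr::map_int(1:7, function(k) {
    sum(score_patients(cohort, tool_config(cutoff = k))$referral)
  })
  expect_true(all(diff(n_ref) <= 0))
})

test_that("recoding NA to no on criteria 6-7 leaves every decision unchanged", {
  grid <- all_combinations()
  recoded <- dplyr::mutate(grid,
                           c6 = ifelse(c6 == "na", "no", c6),
                           c7 = ifelse(c7 == "na", "no", c7))
  expect_equal(score_patients(grid)$referral, score_patients(recoded)$referral)
  expect_equal(score_patients(grid)$score, score_patients(recoded)$score)
})

test_that("the score distribution is a faithful recount of the cohort", {
  cohort <- simulate_patients(n_patients = 150, seed = 8)$records
  decisions <- score_patients(cohort)
  distr <- score_distribution(decisions)
  expect_equal(sum(distr$n), 150)
  judged <- cohort$clinical_judgement == "yes"
  for (s in 0:7) {
    expect_equal(distr$n[distr$score == s], sum(decisions$score == s))
    expect_equal(distr$n_judged_yes[distr$score == s],
                 sum(decisions$score == s & judged))
  }
  # degenerate cohorts
  zeros <- tibble::tibble(c1 = "no", c2 = "no", c3 = "no", c4 = "no",
                          c5 = "no", c6 = "no", c7 = "no", q8 = "yes")[rep(1, 10), ]
  expect_equal(sum(score_patients(zeros)$referral), 0)
  sevens <- dplyr::mutate(zeros, dplyr::across(dplyr::starts_with("c"), ~"yes"))
  expect_equal(mean(score_patients(sevens)$referral), 1)
})

test_that("GAF dichotomization uses at-or-below the revised threshold", {
  expect_equal(gaf_criterion(c(45, 50, 51, NA)), c("yes", "yes", "no", NA))
  expect_equal(gaf_criterion(44, threshold = 45), "yes")
  expect_equal(gaf_criterion(46, threshold = 45), "no")
})

test_that("tool configuration is validated", {
  expect_error(tool_config(cutoff = 0), class = "dtpd_input_error")
  expect_error(tool_config(cutoff = 8), class = "dtpd_input_error")
  expect_error(tool_config(criterion_names = letters[1:5]),
               class = "dtpd_input_error")
})
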