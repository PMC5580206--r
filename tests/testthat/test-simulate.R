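test_that("simulators are pure functions of their seed", {
  s1 <- simulate_sorting(n_items = 10, n_sorters = 4, n_true_clusters = 3, seed = 7)
  s2 <- simulate_sorting(n_items = 10, n_sorters = 4, n_true_clusters = 3, seed = 7)
  expect_identical(s1, s2)
  p1 <- simulate_patients(n_patients = 50, seed = 9)
  p2 <- simulate_patients(n_patients = 50, seed = 9)
  expect_identical(p1, p2)
  # byte-identical CSV round of the cohort
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  readr::write_csv(p1$records, f1); readr::write_csv(p2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the seed does not leak into the session RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_patients(n_patients = 20, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("noise-free sorting reproduces the truth and unit reliability", {
  sim <- simulate_sorting(n_items = 12, n_sorters = 5, n_true_clusters = 3,
                          noise = 0, split_prob = 0, merge_prob = 0, seed = 2)
  per_sorter <- split(sim$sorts, sim$sorts$sorter_id)
  for (one in per_sorter) {
    lab <- one$pile[match(sim$truth$item_id, one$item_id)]
    expect_true(same_partition(lab, sim$truth$cluster))
  }
  expect_equal(sorter_reliability(sim$sorts)$mean_r, 1)
})

test_that("ratings are clipped integers around the cluster means", {
  solution <- tibble::tibble(item_id = sprintf("it%02d", 1:9),
                             cluster = rep(1:3, each = 3))
  exact <- simulate_ratings(solution, c(2.4, 3.6, 5.9), sd = 0, seed = 1)
  expect_true(all(exact$rating == rep(rep(c(2L, 4L, 6L), each = 3), 22)))
  noisy <- simulate_ratings(solution, c(1.2, 3.5, 5.8), sd = 3, seed = 4)
  expect_true(all(noisy$rating >= 1 & noisy$rating <= 6))
  expect_error(simulate_ratings(solution, c(2, 3, 7)), class = "dtpd_input_error")
  expect_error(simulate_ratings(solution, c(2, 3, 4), sd = -1),
               class = "dtpd_input_error")
})

test_that("empirical cluster rating means concentrate on the truth", {
  solution <- tibble::tibble(item_id = sprintf("it%02d", 1:12),
                             cluster = rep(1:3, each = 4))
  means <- c(2.5, 3.5, 4.5)
  emp <- purrr::map(1:50, function(r) {
    ratings <- simulate_ratings(solution, means, sd = 0.5, n_raters = 10,
                                seed = 600 + r)
    joined <- dplyr::inner_join(ratings, solution, by = "item_id")
    tapply(joined$rating, joined$cluster, mean)
  })
  avg <- colMeans(do.call(rbind, emp))
  expect_true(all(abs(avg - means) < 0.1))
})

test_that("a flat null cohort has 50% judgement prevalence", {
  sim <- simulate_patients(
    n_patients = 10000, true_coefficients = setNames(rep(0, 7), paste0("c", 1:7)),
    intercept = 0, centre_effect_sd = 0, seed = 17)
  expect_lt(abs(mean(sim$records$clinical_judgement == "yes") - 0.5), 0.03)
})

test_that("uncorrelated criteria come out pairwise uncorrelated", {
  sim <- simulate_patients(n_patients = 10000, criterion_correlation = 0,
                           na_rate_items = 0, seed = 23)
  m <- criterion_matrix(sim$records)
  cm <- cor(m)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 0.05))
})

test_that("marginal criterion prevalences honour the configuration", {
  prev <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  sim <- simulate_patients(n_patients = 10000, criterion_prevalences = prev,
                           na_rate_items = 0, seed = 29)
  m <- criterion_matrix(sim$records)
  expect_true(all(abs(colMeans(m) - prev) < 0.03))
})

test_that("the calibrated intercept hits the target referral prevalence", {
  b0 <- calibrate_intercept()
  sim <- simulate_patients(n_patients = 20000, intercept = b0, seed = 41)
  expect_lt(abs(mean(sim$records$clinical_judgement == "yes") - 110 / 378), 0.02)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_patients(criterion_correlation = 1.2, n_patients = 10),
               class = "dtpd_input_error")
  expect_error(simulate_patients(criterion_prevalences = c(0, rep(0.5, 6)),
                                 n_patients = 10), class = "dtpd_input_error")
  expect_error(simulate_patients(n_centres = 1, n_patients = 10),
               class = "dtpd_input_error")
  expect_warning(simulate_sorting(n_items = 5, n_sorters = 2,
                                  n_true_clusters = 5, noise = 1),
                 "unrecoverable")
})

test_that("low-noise sorting studies are recovered by the cluster ladder", {
  ari <- purrr::map_dbl(1:20, function(r) {
    sim <- simulate_sorting(n_items = 24, n_sorters = 12, n_true_clusters = 4,
                            noise = 0.2, split_prob = 0, merge_prob = 0,
                            seed = 700 + r)
    map <- embed_map(build_similarity(sim$sorts), seed = r, n_starts = 4)
    sol <- ladder_solution(cluster_ladder(map, k_max = 8, k_min = 2), 4)
    mclust::adjustedRandIndex(sol$cluster,
                              sim$truth$cluster[match(sol$item_id, sim$truth$item_id)])
  })
  expect_gte(mean(ari), 0.9)
})

test_that("map stress grows with sorting noise", {
  mean_stress <- purrr::map_dbl(c(0, 0.1, 0.3, 0.5), function(noise) {
    mean(purrr::map_dbl(1:20, function(r) {
      sim <- simulate_sorting(n_items = 15, n_sorters = 8, n_true_clusters = 3,
                              noise = noise, split_prob = 0, merge_prob = 0,
                              seed = 800 + r)
      embed_map(build_similarity(sim$sorts, exclude_invalid = FALSE),
                seed = r, n_starts = 2)$stress
    }))
  })
  expect_true(all(diff(mean_stress) > 0))
})
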