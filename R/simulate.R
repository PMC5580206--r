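#' Table-of-coefficients defaults for the cohort simulator
#'
#' The seven marginal log-odds ratios of the validation study's multilevel
#' model, in criterion order, used as the default ground truth of
#' [simulate_patients()].
#'
#' @return Named numeric vector of length 7.
#' @export
dtpd_true_coefficients <- function() {
  setNames(
    c(2.530693, 0.917365, 1.737646, 0.825936, 0.214238, -0.004092, 1.208202),
    paste0("c", 1:7)
  )
}

#' Simulate a card-sorting study with a latent cluster structure
#'
#' Emulates a panel of experts sorting a set of items: all sorters perceive
#' the same latent partition of the items into `n_true_clusters` thematic
#' groups, but each applies it imperfectly. Per sorter, with probability
#' `split_prob` a random pile is split in two and with probability
#' `merge_prob` two random piles are merged (granularity disagreements),
#' after which each item independently moves to a uniformly chosen other
#' pile with probability `noise`. Defaults mirror the scale of a real
#' concept-mapping exercise: 95 items, 22 sorters, 6 latent clusters.
#'
#' @param n_items,n_sorters,n_true_clusters Study size (defaults 95/22/6).
#' @param noise Per-item probability of reassignment to a random other pile.
#' @param split_prob,merge_prob Per-sorter structural perturbation
#'   probabilities.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return List with `sorts` (long tibble `sorter_id`, `item_id`, `pile`)
#'   and `truth` (tibble `item_id`, `cluster` - the generating partition).
#' @export
simulate_sorting <- function(n_items = 95, n_sorters = 22,
                             n_true_clusters = 6, noise = 0.25,
                             split_prob = 0.3, merge_prob = 0.3, seed = 1) {
  stopifnot(n_items >= 2, n_sorters >= 1)
  if (n_true_clusters > n_items) stop_input("n_true_clusters cannot exceed n_items.")
  for (p in c(noise, split_prob, merge_prob)) {
    if (p < 0 || p > 1) stop_input("noise/split_prob/merge_prob must lie in [0, 1].")
  }
  if (noise == 1 && n_true_clusters == n_items) {
    warn("noise = 1 with one item per latent cluster: the structure is unrecoverable by design.")
  }
  items <- sprintf("item_%03d", seq_len(n_items))
  with_seed(seed, {
    truth_lab <- sort(rep_len(seq_len(n_true_clusters), n_items))
    truth_lab <- truth_lab[sample.int(n_items)]      # random, roughly balanced
    sorts <- purrr::map_dfr(seq_len(n_sorters), function(s) {
      piles <- truth_lab
      if (runif(1) < split_prob && dplyr::n_distinct(piles) < n_items) {
        big <- names(which(table(piles) >= 2))
        victim <- sample(big, 1)
        members <- which(piles == victim)
        moved <- sample(members, ceiling(length(members) / 2))
        piles[moved] <- max(as.integer(factor(piles))) + 1L
        piles <- as.integer(factor(piles))
      }
      if (runif(1) < merge_prob && dplyr::n_distinct(piles) >= 3) {
        two <- sample(unique(piles), 2)
        piles[piles == two[2]] <- two[1]
        piles <- as.integer(factor(piles))
      }
      piles <- as.integer(factor(piles))
      n_piles <- max(piles)
      if (n_piles >= 2) {
        move <- runif(n_items) < noise
        for (i in which(move)) {
          others <- setdiff(seq_len(n_piles), piles[i])
          piles[i] <- others[sample.int(length(others), 1)]
        }
      }
      tibble::tibble(sorter_id = sprintf("sorter_%02d", s),
                     item_id = items, pile = paste0("p", piles))
    })
    list(sorts = sorts,
         truth = tibble::tibble(item_id = items, cluster = truth_lab))
  })
}

#' Simulate an importance-rating task
#'
#' Each rater rates each item on the 1-6 scale; ratings are Gaussian around
#' the item's cluster mean, rounded to integers and clipped into \[1, 6\].
#'
#' @param solution Tibble `item_id`, `cluster` giving each item's cluster.
#' @param cluster_means Named or positional numeric vector of cluster mean
#'   ratings, each in \[1, 6\].
#' @param sd Rating noise standard deviation (>= 0).
#' @param n_raters Number of raters, default 22.
#' @param seed Integer seed.
#' @return Long tibble `rater_id`, `item_id`, `rating`.
#' @export
simulate_ratings <- function(solution, cluster_means, sd = 0.75,
                             n_raters = 22, seed = 1) {
  solution <- tibble::as_tibble(solution)
  if (sd < 0) stop_input("sd must be non-negative.")
  if (any(cluster_means < 1 | cluster_means > 6)) {
    stop_input("cluster_means must lie in [1, 6].")
  }
  clusters <- sort(unique(solution$cluster))
  if (is.null(names(cluster_means))) {
    if (length(cluster_means) != length(clusters)) {
      stop_input("cluster_means must have one value per cluster.")
    }
    names(cluster_means) <- as.character(clusters)
  }
  mu <- cluster_means[as.character(solution$cluster)]
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_raters), function(r) {
      raw <- round(rnorm(nrow(solution), mean = mu, sd = sd))
      tibble::tibble(rater_id = sprintf("rater_%02d", r),
                     item_id = solution$item_id,
                     rating = as.integer(pmin(6, pmax(1, raw))))
    })
  })
}

# Expected referral prevalence under the simulator's model, by deterministic
# Monte Carlo (own fixed RNG stream; independent of the cohort seed).
expected_prevalence <- function(intercept, beta, prevalences, rho,
                                centre_effect_sd, n_mc = 20000,
                                mc_seed = 20260101) {
  with_seed(mc_seed, {
    x <- copula_binary(n_mc, prevalences, rho)
    u <- rnorm(n_mc, 0, centre_effect_sd)
    mean(plogis(intercept + drop(x %*% beta) + u))
  })
}

#' Calibrate the simulator intercept to a target referral prevalence
#'
#' Bisection on the intercept of the judgement model so that the expected
#' share of patients judged to need highly specialized care matches
#' `target_prevalence` (default 110/378, the observed split of the
#' validation cohort). The expectation is evaluated by a fixed-seed Monte
#' Carlo integral over the criterion copula and centre effects, so the
#' result is deterministic.
#'
#' @param true_coefficients Criterion log-odds ratios.
#' @param criterion_prevalences Marginal criterion prevalences.
#' @param criterion_correlation Exchangeable copula correlation.
#' @param centre_effect_sd SD of centre-level intercept shifts.
#' @param target_prevalence Target P(judgement = yes).
#' @return The calibrated intercept.
#' @export
calibrate_intercept <- function(true_coefficients = dtpd_true_coefficients(),
                                criterion_prevalences = default_prevalences(),
                                criterion_correlation = 0.2,
                                centre_effect_sd = 0.3,
                                target_prevalence = 110 / 378) {
  f <- function(b0) {
    expected_prevalence(b0, true_coefficients, criterion_prevalences,
                        criterion_correlation, centre_effect_sd) -
      target_prevalence
  }
  lo <- -20; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-7) break
  }
  (lo + hi) / 2
}

#' Default marginal criterion prevalences of the cohort simulator
#'
#' Chosen once as plausible intake prevalences of the seven criteria in a
#' personality-disorder population referred for assessment (no raw cohort
#' data exist to estimate them from).
#'
#' @return Numeric vector of length 7.
#' @export
default_prevalences <- function() {
  c(0.50, 0.45, 0.35, 0.50, 0.40, 0.45, 0.40)
}

# n draws of 7 correlated 0/1 criteria via a Gaussian copula with
# exchangeable correlation rho, thresholded at the marginal prevalences.
copula_binary <- function(n, prevalences, rho) {
  k <- length(prevalences)
  if (rho < 0 || rho >= 1) {
    stop_input("criterion_correlation must lie in [0, 1) for an exchangeable Gaussian copula.")
  }
  common <- rnorm(n)
  z <- sqrt(rho) * common +
    sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  x <- sweep(z, 2, qnorm(1 - prevalences), `>`) * 1L
  colnames(x) <- paste0("c", seq_len(k))
  x
}

#' Simulate a multi-centre validation cohort
#'
#' Generates patient records with the statistical structure the validation
#' analysis assumes. The seven criterion answers are correlated binaries
#' (Gaussian copula, exchangeable correlation, thresholded at the marginal
#' prevalences). The clinician's referral judgement is Bernoulli with
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + u_{centre} + \beta^\top x)}, where the
#' centre shifts \eqn{u} induce within-centre correlation and the default
#' \eqn{\beta} are the validation study's model coefficients. NA answers are
#' injected on criteria 6-7 and the gate question at the stated rates; the
#' gate answer itself is yes with probability `q8_yes_prob` when observed.
#' Therapists are nested in centres but the analysis clusters by centre.
#'
#' @param n_patients,n_centres,n_therapists Cohort size (defaults 368/7/88).
#' @param true_coefficients Criterion log-odds ratios (default
#'   [dtpd_true_coefficients()]).
#' @param intercept Intercept of the judgement model; `NULL` (default)
#'   calibrates it to `target_prevalence` via [calibrate_intercept()].
#' @param centre_effect_sd SD of centre-level intercept shifts, default 0.3.
#' @param criterion_prevalences Marginal prevalences, default
#'   [default_prevalences()].
#' @param criterion_correlation Exchangeable copula correlation, default 0.2.
#' @param na_rate_items NA rate on criteria 6 and 7, default 0.05.
#' @param na_rate_q8 NA rate on the gate question, default 0.05.
#' @param q8_yes_prob P(gate = yes | observed), default 0.8.
#' @param target_prevalence Referral prevalence used for intercept
#'   calibration, default 110/378.
#' @param seed Integer seed.
#' @return List with `records` (tibble `centre_id`, `therapist_id`,
#'   `c1`..`c7`, `q8`, `clinical_judgement`) and `truth` (the generating
#'   parameters, including the calibrated intercept and centre effects).
#' @export
simulate_patients <- function(n_patients = 368, n_centres = 7,
                              n_therapists = 88,
                              true_coefficients = dtpd_true_coefficients(),
                              intercept = NULL, centre_effect_sd = 0.3,
                              criterion_prevalences = default_prevalences(),
                              criterion_correlation = 0.2,
                              na_rate_items = 0.05, na_rate_q8 = 0.05,
                              q8_yes_prob = 0.8,
                              target_prevalence = 110 / 378, seed = 1) {
  if (n_centres < 2) stop_input("At least 2 centres are required.")
  if (any(criterion_prevalences <= 0 | criterion_prevalences >= 1)) {
    stop_input("criterion_prevalences must lie strictly in (0, 1).")
  }
  if (length(true_coefficients) != 7 || length(criterion_prevalences) != 7) {
    stop_input("true_coefficients and criterion_prevalences must have length 7.")
  }
  if (is.null(intercept)) {
    intercept <- calibrate_intercept(true_coefficients, criterion_prevalences,
                                     criterion_correlation, centre_effect_sd,
                                     target_prevalence)
  }
  with_seed(seed, {
    centre <- sample.int(n_centres, n_patients, replace = TRUE)
    ther_per_centre <- rep_len(seq_len(n_centres), n_therapists)
    therapist <- vapply(centre, function(cc) {
      pool <- which(ther_per_centre == cc)
      if (length(pool) == 1) pool else sample(pool, 1)
    }, integer(1))
    u <- rnorm(n_centres, 0, centre_effect_sd)
    x <- copula_binary(n_patients, criterion_prevalences, criterion_correlation)
    eta <- intercept + u[centre] + drop(x %*% true_coefficients)
    judged <- rbinom(n_patients, 1, plogis(eta)) == 1

    ans <- matrix(ifelse(x == 1, "yes", "no"), n_patients, 7)
    for (j in 6:7) {
      ans[runif(n_patients) < na_rate_items, j] <- "na"
    }
    q8 <- ifelse(runif(n_patients) < q8_yes_prob, "yes", "no")
    q8[runif(n_patients) < na_rate_q8] <- "na"

    records <- tibble::as_tibble(as.data.frame(ans, stringsAsFactors = FALSE))
    names(records) <- paste0("c", 1:7)
    records <- dplyr::bind_cols(
      tibble::tibble(centre_id = sprintf("centre_%d", centre),
                     therapist_id = sprintf("therapist_%02d", therapist)),
      records,
      tibble::tibble(q8 = q8,
                     clinical_judgement = ifelse(judged, "yes", "no"))
    )
    list(records = records,
         truth = list(intercept = intercept,
                      coefficients = true_coefficients,
                      centre_effects = u,
                      criterion_prevalences = criterion_prevalences,
                      criterion_correlation = criterion_correlation,
                      centre_effect_sd = centre_effect_sd,
                      seed = seed))
  })
}
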