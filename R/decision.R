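#' Default criterion labels of the referral decision tool
#'
#' The seven criteria of the DTPD (Decision Tool Personality Disorder), in
#' instrument order. Criteria 1-5 are answered yes/no; criteria 6 and 7 also
#' admit "not applicable".
#'
#' @return Character vector of length 7.
#' @export
dtpd_criteria <- function() {
  c("Severe negative affect with disadaptive coping",
    "Severe destructive behavior to oneself or others",
    "Multiple comorbid disorders on axis I and/or axis II due to severe psychiatric problems",
    "Severe social and societal dysfunction: GAF <= 50",
    "Severe chronic traumatisation in childhood",
    "Difficulties in developing a therapeutic relationship",
    "Treatment in specialized care was not successful")
}

#' Configuration of the referral decision rule
#'
#' The rule: count the YES answers over the seven criteria; if the count
#' reaches `cutoff` (default 4) the gate question - possibility and
#' motivation to conform to minimal treatment conditions for intensive
#' psychotherapy - decides: yes or not-applicable leads to referral to
#' highly specialized care, no does not. Below the cutoff the patient is not
#' referred and the gate is never consulted.
#'
#' "Not applicable" is allowed only on the criteria listed in `na_allowed`
#' (6 and 7 by default) and, under the default `na_policy = "as_no"`,
#' contributes 0 to the score - the score counts positive answers only.
#'
#' @param criterion_names Labels of the seven criteria.
#' @param cutoff Minimum score that opens the gate question (1-7, default 4).
#' @param gaf_threshold GAF value at or below which criterion 4 is positive
#'   (default 50; the pilot study revised the original 45).
#' @param na_allowed Indices of criteria that admit NA (default 6 and 7).
#' @param na_policy How NA counts toward the score; only `"as_no"` is
#'   currently implemented (named so alternatives can be added).
#' @return A list of class `dtpd_tool_config`.
#' @export
tool_config <- function(criterion_names = dtpd_criteria(), cutoff = 4,
                        gaf_threshold = 50, na_allowed = c(6, 7),
                        na_policy = "as_no") {
  if (length(criterion_names) != 7) stop_input("Exactly 7 criterion names are required.")
  if (!(cutoff >= 1 && cutoff <= 7)) stop_input("cutoff must lie in 1..7.")
  if (!(gaf_threshold > 0)) stop_input("gaf_threshold must be positive.")
  if (!all(na_allowed %in% 1:7)) stop_input("na_allowed must be criterion indices in 1..7.")
  na_policy <- match.arg(na_policy, "as_no")
  structure(list(criterion_names = criterion_names, cutoff = as.integer(cutoff),
                 gaf_threshold = as.integer(gaf_threshold),
                 na_allowed = as.integer(na_allowed), na_policy = na_policy),
            class = "dtpd_tool_config")
}

#' Dichotomize a raw GAF value for criterion 4
#'
#' Global Assessment of Functioning at or below the threshold counts as
#' severe social and societal dysfunction (answer "yes").
#'
#' @param gaf Integer GAF values (0-100).
#' @param threshold Defaults to 50 (pilot-revised from below-45).
#' @return Character vector `"yes"`/`"no"` (`NA` stays `NA`).
#' @export
gaf_criterion <- function(gaf, threshold = 50) {
  ifelse(is.na(gaf), NA_character_, ifelse(gaf <= threshold, "yes", "no"))
}

# Validate and normalise the criterion answer columns of a record table.
# Returns a list: ans (n x 7 character matrix of yes/no/na), q8 (character).
normalize_answers <- function(records, config) {
  cols <- paste0("c", 1:7)
  missing <- setdiff(c(cols, "q8"), names(records))
  if (length(missing) > 0) {
    stop_input(paste0("Patient records lack column(s): ",
                      paste(missing, collapse = ", "), "."))
  }
  rows <- seq_len(nrow(records))
  ans <- sapply(cols, function(cc) {
    normalize_token(records[[cc]], c("yes", "no", "na"), paste0("criterion ", cc), rows)
  })
  if (nrow(records) == 1) ans <- matrix(ans, nrow = 1, dimnames = list(NULL, cols))
  for (j in setdiff(1:7, config$na_allowed)) {
    bad <- ans[, j] == "na"
    if (any(bad)) {
      stop_input(sprintf(
        "Criterion %d ('%s') does not admit NA (row %d); only criteria %s may be NA.",
        j, config$criterion_names[j], which(bad)[1],
        paste(config$na_allowed, collapse = " and ")))
    }
  }
  q8 <- normalize_token(records[["q8"]], c("yes", "no", "na"), "gate question q8", rows)
  list(ans = ans, q8 = q8)
}

#' Apply the decision rule to a cohort of patient records
#'
#' Scores every record (count of YES answers over the seven criteria, NA
#' counting as no under the default policy) and applies the cutoff-plus-gate
#' rule. The returned `rationale` spells out which branch of the rule fired.
#'
#' @param records Data frame with columns `c1`..`c7` and `q8` holding
#'   `yes`/`no`/`na` tokens (case-insensitive); other columns are carried
#'   through.
#' @param config A [tool_config()].
#' @return The input tibble plus columns `score` (0-7), `passed_cutoff`,
#'   `referral` (logical) and `rationale`.
#' @export
score_patients <- function(records, config = tool_config()) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_input("Patient record table is empty.")
  }
  records <- tibble::as_tibble(records)
  norm <- normalize_answers(records, config)
  score <- as.integer(rowSums(norm$ans == "yes"))
  passed <- score >= config$cutoff
  referral <- passed & norm$q8 != "no"
  rationale <- ifelse(
    !passed,
    sprintf("score %d < cutoff %d: not referred", score, config$cutoff),
    ifelse(norm$q8 == "yes",
           sprintf("score %d >= cutoff %d and gate yes: referred", score, config$cutoff),
           ifelse(norm$q8 == "na",
                  sprintf("score %d >= cutoff %d and gate NA: referred", score, config$cutoff),
                  sprintf("score %d >= cutoff %d but gate no: not referred", score, config$cutoff)))
  )
  dplyr::mutate(records, score = score, passed_cutoff = passed,
                referral = referral, rationale = rationale)
}

#' Score a single patient
#'
#' Convenience wrapper around [score_patients()] for one record.
#'
#' @param answers Character vector of 7 `yes`/`no`/`na` answers.
#' @param q8 Gate-question answer (`yes`/`no`/`na`).
#' @param config A [tool_config()].
#' @return One-row tibble with `score`, `passed_cutoff`, `referral`,
#'   `rationale`.
#' @export
score_patient <- function(answers, q8, config = tool_config()) {
  if (length(answers) != 7) stop_input("Exactly 7 criterion answers are required.")
  rec <- tibble::as_tibble(setNames(as.list(as.character(answers)), paste0("c", 1:7)))
  rec$q8 <- as.character(q8)
  out <- score_patients(rec, config)
  dplyr::select(out, "score", "passed_cutoff", "referral", "rationale")
}

#' Score distribution cross-tabulated with clinical judgement
#'
#' @param decisions Output of [score_patients()]; must carry a
#'   `clinical_judgement` column (`yes`/`no` tokens or logical).
#' @return Tibble with one row per score 0-7: counts of clinically judged
#'   yes/no records and referrals at that score.
#' @export
score_distribution <- function(decisions) {
  cj <- parse_judgement(decisions)
  tibble::tibble(score = decisions$score, judged_yes = cj,
                 referral = decisions$referral) |>
    dplyr::mutate(score = factor(.data$score, levels = 0:7)) |>
    dplyr::group_by(.data$score, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     n_judged_yes = sum(.data$judged_yes),
                     n_judged_no = sum(!.data$judged_yes),
                     n_referred = sum(.data$referral), .groups = "drop") |>
    dplyr::mutate(score = as.integer(as.character(.data$score)))
}

# clinical_judgement column -> logical vector
parse_judgement <- function(records) {
  if (!"clinical_judgement" %in% names(records)) {
    stop_input("Records lack the clinical_judgement column.")
  }
  x <- records$clinical_judgement
  if (is.logical(x)) return(x)
  normalize_token(x, c("yes", "no"), "clinical_judgement",
                  seq_len(nrow(records))) == "yes"
}
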