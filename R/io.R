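#' Read a card-sort CSV
#'
#' Long format, comma-separated, UTF-8, header `sorter_id,item_id,pile`.
#'
#' @param path File path.
#' @return Validated sort tibble (see [validate_sorts()]).
#' @export
read_sorts <- function(path) {
  df <- read_strict(path, c("sorter_id", "item_id", "pile"))
  validate_sorts(df)
}

#' Read a rating CSV
#'
#' Header `rater_id,item_id,rating`; ratings must be integers 1-6.
#'
#' @param path File path.
#' @return Validated rating tibble (see [validate_ratings()]).
#' @export
read_ratings <- function(path) {
  df <- read_strict(path, c("rater_id", "item_id", "rating"))
  validate_ratings(df)
}

#' Read a patient-record CSV
#'
#' Header `centre_id,therapist_id,c1,...,c7,q8,clinical_judgement`; answer
#' tokens `yes`/`no`/`na` (case-insensitive).
#'
#' @param path File path.
#' @param config A [tool_config()] governing where NA is admissible.
#' @return Validated patient tibble with normalised lower-case tokens.
#' @export
read_patients <- function(path, config = tool_config()) {
  cols <- c("centre_id", "therapist_id", paste0("c", 1:7), "q8",
            "clinical_judgement")
  df <- read_strict(path, cols)
  norm <- normalize_answers(df, config)
  for (j in 1:7) df[[paste0("c", j)]] <- norm$ans[, j]
  df$q8 <- norm$q8
  df$clinical_judgement <- ifelse(parse_judgement(df), "yes", "no")
  df
}

read_strict <- function(path, cols) {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input(sprintf("%s lacks column(s): %s.", path,
                       paste(missing, collapse = ", ")))
  }
  if ("rating" %in% cols) {
    r <- suppressWarnings(as.numeric(df$rating))
    bad <- is.na(r) | r != round(r)
    if (any(bad)) {
      stop_input(sprintf("Rating '%s' at row %d is not an integer.",
                         df$rating[which(bad)[1]], which(bad)[1]))
    }
    df$rating <- as.integer(r)
  }
  tibble::as_tibble(df[cols])
}

#' Write a similarity matrix as CSV
#'
#' Items appear as both header row and first column.
#'
#' @param sim A `dtpd_similarity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "dtpd_similarity"))
  df <- tibble::as_tibble(sim$counts, rownames = "item_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Write map coordinates as CSV
#'
#' Columns `item_id,x,y`; the stress value and seeds travel in the JSON run
#' report, not the CSV.
#'
#' @param map A `dtpd_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  readr::write_csv(tidy(map), path)
  invisible(path)
}

#' Write a generic tibble as CSV
#'
#' Convenience used by the pipeline for cluster solutions, bridging values,
#' decisions, cut-off tables and ROC points.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Write a run report as JSON
#'
#' @param report A list (e.g. a `dtpd_run_report`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
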