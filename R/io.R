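#' Write and read study datasets
#'
#' Trials and glucose traces are exchanged as plain CSV in the documented
#' schemas; cohort ground truth as JSON. `write_cohort()` emits all three
#' into a directory; `read_trials_csv()` validates the trial schema on
#' ingest.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the directory invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$trials, file.path(dir, "trials.csv"))
  readr::write_csv(cohort$glucose, file.path(dir, "glucose.csv"))
  readr::write_csv(cohort$scores, file.path(dir, "scores.csv"))
  gt <- as.list(cohort$ground_truth)
  jsonlite::write_json(
    list(ground_truth = gt, planted = cohort$planted, seed = cohort$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @param path CSV path of trial records.
#' @return `read_trials_csv()` returns a validated trials tibble.
#' @export
read_trials_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          participant_id = readr::col_character(),
                          phase = readr::col_character(),
                          chosen_symbol = readr::col_character()
                        ))
  req <- c("participant_id", "phase", "trial", "left_symbol",
           "right_symbol", "chosen_symbol", "outcome")
  missing <- setdiff(req, names(df))
  assert_that(length(missing) == 0,
              paste("trials file missing columns:",
                    paste(missing, collapse = ", ")))
  bad_phase <- setdiff(unique(df$phase), c("training", "test"))
  assert_that(length(bad_phase) == 0,
              paste("unknown phase values:", paste(bad_phase, collapse = ", ")))
  tibble::as_tibble(df)
}
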