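#' Read and write episode tables
#'
#' Episode tables are flat CSV (RFC 4180, UTF-8, ISO-8601 dates).
#' Additional diagnoses are packed as `"CODE=POA|CODE=ADE"` (see
#' [pack_diagnoses()]); procedure codes as a `;`-separated list.
#'
#' @param episodes episode table.
#' @param path CSV file path.
#' @return `read_episodes()` returns the episode tibble.
#' @export
write_episodes <- function(episodes, path) {
  readr::write_csv(episodes, path, na = "")
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    admission_date = readr::col_date(),
    discharge_date = readr::col_date(),
    age_at_admission = readr::col_integer(),
    .default = readr::col_character()
  ), na = character())
}

#' Read and write ground truth
#'
#' Serialises a `cohort_truth` as four CSV files
#' (`truth_episodes.csv`, `truth_persons.csv`, `truth_events.csv`,
#' `truth_transfers.csv`) in a directory.
#'
#' @param truth a `cohort_truth`.
#' @param dir directory path (created if needed).
#' @return `read_truth()` returns the `cohort_truth`.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(truth$episodes, file.path(dir, "truth_episodes.csv"), na = "")
  readr::write_csv(truth$persons, file.path(dir, "truth_persons.csv"), na = "")
  readr::write_csv(truth$events, file.path(dir, "truth_events.csv"), na = "")
  readr::write_csv(truth$transfers, file.path(dir, "truth_transfers.csv"),
                   na = "")
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  chr <- function(...) readr::cols(..., .default = readr::col_character())
  structure(list(
    episodes = readr::read_csv(
      file.path(dir, "truth_episodes.csv"),
      col_types = chr(true_incident = readr::col_logical()), na = ""),
    persons = readr::read_csv(
      file.path(dir, "truth_persons.csv"),
      col_types = chr(age_at_start = readr::col_integer(),
                      dob = readr::col_date()), na = ""),
    events = readr::read_csv(
      file.path(dir, "truth_events.csv"),
      col_types = chr(event_no = readr::col_integer(),
                      admission_date = readr::col_date(),
                      is_second = readr::col_logical(),
                      community = readr::col_logical(),
                      inhospital_death = readr::col_logical(),
                      in_window = readr::col_logical()), na = ""),
    transfers = readr::read_csv(file.path(dir, "truth_transfers.csv"),
                                col_types = chr(), na = "")
  ), class = "cohort_truth")
}
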