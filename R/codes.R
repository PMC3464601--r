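#' ICD-10-AM code helpers
#'
#' Small string utilities for working with ICD-10-AM diagnosis and
#' external-cause codes.  Codes are matched structurally: the dot is
#' ignored, comparison is by character prefix, and three-character
#' category ranges (e.g. S00--T75) are compared as letter + two-digit
#' number.
#'
#' @param code character vector of ICD-10-AM codes (dotted or not).
#' @return `icd_strip()` returns the upper-cased, dot-free code;
#'   the predicates return logical vectors (malformed codes give `FALSE`).
#' @examples
#' icd_strip("s72.04")           # "S7204"
#' is_hip_fracture_dx(c("S72.1", "S72.3", "S71.9"))
#' is_fall_mechanism("W05")
#' is_fall_injury_dx(c("S72.0", "T79.0", "T80"))
#' @name icd_codes
NULL

#' @rdname icd_codes
#' @export
icd_strip <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

icd_valid <- function(stripped) grepl("^[A-Z][0-9]{2}", stripped)

#' @rdname icd_codes
#' @export
is_hip_fracture_dx <- function(code) {
  s <- icd_strip(code)
  icd_valid(s) & grepl("^S72[0-2]", s)
}

#' @rdname icd_codes
#' @export
is_fall_mechanism <- function(code) {
  s <- icd_strip(code)
  ok <- icd_valid(s) & substr(s, 1, 1) == "W"
  num <- suppressWarnings(as.integer(substr(s, 2, 3)))
  ok & !is.na(num) & num >= 0 & num <= 19
}

#' @rdname icd_codes
#' @export
is_fall_injury_dx <- function(code) {
  # principal diagnosis in S00-T75 or T79 (excludes complications of
  # medical care, T80+)
  s <- icd_strip(code)
  ok <- icd_valid(s)
  letter <- substr(s, 1, 1)
  num <- suppressWarnings(as.integer(substr(s, 2, 3)))
  res <- ok & !is.na(num) &
    ((letter == "S") | (letter == "T" & (num <= 75 | num == 79)))
  res[is.na(res)] <- FALSE
  res
}

#' Prefix match of an ICD code against a code-list prefix
#'
#' @param code,prefix character vectors (recycled); dots are ignored.
#' @return logical vector.
#' @export
icd_has_prefix <- function(code, prefix) {
  startsWith(icd_strip(code), icd_strip(prefix))
}

#' Australian fiscal year of a date
#'
#' Fiscal years run 1 July to 30 June and are labelled "2005/06" style.
#'
#' @param date a `Date` vector.
#' @return character vector of fiscal-year labels.
#' @examples
#' fiscal_year(as.Date(c("2005-07-01", "2006-06-30")))  # both "2005/06"
#' @export
fiscal_year <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  start <- ifelse(m >= 7, y, y - 1L)
  sprintf("%d/%02d", start, (start + 1L) %% 100L)
}

#' Assign ages to 5-year bands
#'
#' @param age numeric vector of ages in years.
#' @param breaks increasing integer vector of band lower bounds
#'   (default `c(65, 70, 75, 80, 85)`); the last band is open-ended.
#' @return factor of band labels ("65-69", ..., "85+").
#' @export
age_band <- function(age, breaks = c(65, 70, 75, 80, 85)) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks))
  labs <- c(paste0(utils::head(breaks, -1), "-",
                   utils::tail(breaks, -1) - 1),
            paste0(utils::tail(breaks, 1), "+"))
  cut(age, breaks = c(breaks, Inf), labels = labs, right = FALSE)
}

#' @rdname age_band
#' @export
age_band_levels <- function(breaks = c(65, 70, 75, 80, 85)) {
  levels(age_band(breaks[1], breaks))
}

# ---- packed list columns -----------------------------------------------
# Episode tables are flat (CSV-friendly); additional diagnoses and
# procedure codes are packed into single strings.

ONSET_POA <- "present_on_admission"
ONSET_ADE <- "arose_during_episode"

#' Pack / parse additional-diagnosis strings
#'
#' Additional diagnoses with condition-onset flags are stored in episode
#' tables as a single string, e.g. `"I50.0=POA|F05.9=ADE"` (`POA` =
#' present on admission, `ADE` = arose during episode).
#'
#' @param codes character vector of diagnosis codes.
#' @param onset character vector, `"present_on_admission"` or
#'   `"arose_during_episode"`.
#' @param x packed string (length-1 for `parse_diagnoses()`).
#' @return `pack_diagnoses()`: a length-1 string; `parse_diagnoses()`:
#'   a data frame with columns `code` and `onset`.
#' @export
pack_diagnoses <- function(codes, onset) {
  if (length(codes) == 0) return("")
  stopifnot(length(codes) == length(onset),
            all(onset %in% c(ONSET_POA, ONSET_ADE)))
  flag <- ifelse(onset == ONSET_POA, "POA", "ADE")
  paste(paste0(codes, "=", flag), collapse = "|")
}

#' @rdname pack_diagnoses
#' @export
parse_diagnoses <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(code = character(), onset = character()))
  }
  parts <- strsplit(strsplit(x, "|", fixed = TRUE)[[1]], "=", fixed = TRUE)
  data.frame(
    code = vapply(parts, `[`, "", 1),
    onset = ifelse(vapply(parts, `[`, "", 2) == "POA", ONSET_POA, ONSET_ADE)
  )
}

pack_codes <- function(codes) paste(codes, collapse = ";")

parse_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}
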