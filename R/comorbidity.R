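#' Load a comorbidity code map
#'
#' The code map drives comorbidity ascertainment: one row per
#' (condition, ICD-10-AM code prefix) with a Charlson flag and the Deyo
#' weight used for the comorbidity index.  The shipped asset covers the
#' seventeen Deyo-Charlson conditions plus five fall/fracture risk
#' factors (osteoporosis, Parkinson's disease, visual impairment,
#' deafness, delirium).  It is a replaceable, editable asset — the
#' ascertainment engine is code-list-agnostic — and the shipped prefixes
#' are a published-style ICD-10 mapping, not a reproduction of any
#' jurisdiction's exact list.
#'
#' @param path CSV file with columns `condition`, `icd10_prefix`,
#'   `charlson` (logical), `weight` (integer).
#' @return tibble of class `code_map`.
#' @export
load_code_map <- function(path = system.file("extdata", "comorbidity_codes.csv",
                                             package = "hipfraclink")) {
  map <- readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(),
    icd10_prefix = readr::col_character(),
    charlson = readr::col_logical(),
    weight = readr::col_integer()
  ))
  if (nrow(map) == 0) stop("empty code map", call. = FALSE)
  validate_code_map(map)
  class(map) <- c("code_map", class(map))
  map
}

# Prefix overlap across conditions is forbidden except for the documented
# severity hierarchies, where the severer level wins in the index.
code_map_hierarchies <- function() {
  list(c("diabetes", "diabetes_complications"),
       c("liver_mild", "liver_severe"),
       c("cancer", "metastatic"))
}

validate_code_map <- function(map) {
  s <- icd_strip(map$icd10_prefix)
  for (i in seq_along(s)) {
    hit <- startsWith(s, s[i]) & map$condition != map$condition[i]
    if (any(hit)) {
      pairs <- vapply(code_map_hierarchies(), function(h) {
        all(c(map$condition[i], map$condition[hit][1]) %in% h)
      }, TRUE)
      if (!any(pairs)) {
        stop("code map prefix overlap outside documented hierarchies: ",
             map$icd10_prefix[i], " (", map$condition[i], ") vs ",
             map$condition[hit][1], call. = FALSE)
      }
    }
  }
  w <- tapply(map$weight, map$condition, function(x) length(unique(x)))
  if (any(w != 1)) {
    stop("code map gives a condition more than one weight: ",
         paste(names(w)[w != 1], collapse = ", "), call. = FALSE)
  }
  invisible(map)
}

code_map_env <- new.env(parent = emptyenv())

#' @rdname load_code_map
#' @export
default_code_map <- function() {
  if (is.null(code_map_env$map)) code_map_env$map <- load_code_map()
  code_map_env$map
}

# One representative, emittable code per condition (first prefix row,
# completed to a plausible full code).  Used by the generator.
condition_example_codes <- function(code_map = default_code_map()) {
  first <- code_map[!duplicated(code_map$condition), ]
  code <- first$icd10_prefix
  short <- nchar(icd_strip(code)) <= 3
  code[short] <- paste0(code[short],
                        ifelse(nchar(icd_strip(code[short])) == 3, ".0", "4.0"))
  stats::setNames(code, first$condition)
}

condition_weights <- function(code_map = default_code_map()) {
  first <- code_map[!duplicated(code_map$condition), ]
  stats::setNames(as.integer(first$weight), first$condition)
}

condition_charlson_flags <- function(code_map = default_code_map()) {
  first <- code_map[!duplicated(code_map$condition), ]
  stats::setNames(first$charlson, first$condition)
}

#' Deyo-Charlson comorbidity index
#'
#' Weighted sum of present Charlson conditions after resolving the
#' severity hierarchies (uncomplicated diabetes yields to diabetes with
#' complications, mild liver disease to moderate/severe liver disease,
#' and non-metastatic cancer to metastatic disease).  Non-Charlson risk
#' factors carry weight 0 and never contribute.
#'
#' @param present_conditions character vector of condition names.
#' @param code_map a [load_code_map()] table.
#' @return a single non-negative integer.
#' @examples
#' charlson_index(c("dementia", "chf"))            # 2
#' charlson_index(c("diabetes", "diabetes_complications"))  # 2, hierarchy
#' @export
charlson_index <- function(present_conditions, code_map = default_code_map()) {
  w <- condition_weights(code_map)
  unknown <- setdiff(present_conditions, names(w))
  if (length(unknown)) {
    stop("unknown condition name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  present <- unique(present_conditions)
  for (h in code_map_hierarchies()) {
    if (all(h %in% present)) present <- setdiff(present, h[1])
  }
  sum(w[present])
}

# Episode x condition logical matrix of conditions coded with onset flag
# present_on_admission.  Parsed once; reused by every ascertainment call.
episode_condition_matrix <- function(episodes, code_map) {
  conds <- unique(code_map$condition)
  mat <- matrix(FALSE, nrow = nrow(episodes), ncol = length(conds),
                dimnames = list(episodes$episode_id, conds))
  parsed <- lapply(episodes$additional_diagnoses, parse_diagnoses)
  n_codes <- vapply(parsed, nrow, 0L)
  if (sum(n_codes) == 0) return(mat)
  long <- data.frame(
    row = rep(seq_len(nrow(episodes)), n_codes),
    code = unlist(lapply(parsed, `[[`, "code")),
    onset = unlist(lapply(parsed, `[[`, "onset"))
  )
  long <- long[long$onset == ONSET_POA, , drop = FALSE]
  if (nrow(long) == 0) return(mat)
  stripped <- icd_strip(long$code)
  for (i in seq_len(nrow(code_map))) {
    hit <- startsWith(stripped, icd_strip(code_map$icd10_prefix[i]))
    if (any(hit)) {
      mat[cbind(long$row[hit], match(code_map$condition[i], conds))] <- TRUE
    }
  }
  mat
}

#' Ascertain comorbidities for one incident case
#'
#' A condition is deemed present if at least one qualifying diagnosis
#' code with onset flag `present_on_admission` appears on the index
#' record or, when `lookback_enabled`, on any earlier record of the
#' person available in the dataset.  Codes flagged
#' `arose_during_episode` (hospital-acquired) never count.  The index
#' record is the first multiday episode of the incident's chain
#' (discharge after admission); if the chain has none, the index episode
#' itself.
#'
#' @param incident one row of an incident-case table (needs
#'   `index_episode_id`, `person_id`).
#' @param person_episodes the person's episodes at or before the index
#'   admission that exist in the dataset (include the index episode).
#' @param code_map a [load_code_map()] table.
#' @param lookback_enabled search records earlier than the index record?
#' @return one-row tibble: `incident_id`, `person_id`, one logical
#'   column per condition, `charlson_index`, `lookback_days_available`.
#' @seealso [comorbidity_records()] for the vectorised pathway.
#' @export
ascertain_comorbidities <- function(incident, person_episodes,
                                    code_map = default_code_map(),
                                    lookback_enabled = TRUE) {
  if (nrow(code_map) == 0) stop("empty code map", call. = FALSE)
  mat <- episode_condition_matrix(person_episodes, code_map)
  ascertain_one(incident$index_episode_id, incident$person_id,
                person_episodes, mat, code_map, lookback_enabled)
}

ascertain_one <- function(index_episode_id, person_id, person_episodes, mat,
                          code_map, lookback_enabled) {
  idx_row <- match(index_episode_id, person_episodes$episode_id)
  if (is.na(idx_row)) {
    stop("index episode ", index_episode_id, " not among person_episodes",
         call. = FALSE)
  }
  # index record: first multiday episode of the chain starting at the
  # index admission; fall back to the index episode itself
  chain <- person_episodes[
    person_episodes$admission_date >= person_episodes$admission_date[idx_row] &
      is_hip_fracture_dx(person_episodes$principal_diagnosis), , drop = FALSE]
  chain <- chain[order(chain$admission_date, chain$discharge_date,
                       chain$episode_id), , drop = FALSE]
  multiday <- chain[chain$discharge_date > chain$admission_date, , drop = FALSE]
  index_record <- if (nrow(multiday)) multiday$episode_id[1] else index_episode_id
  ir_row <- match(index_record, person_episodes$episode_id)

  search <- ir_row
  lookback_days <- 0
  if (lookback_enabled) {
    earlier <- which(person_episodes$admission_date <
                       person_episodes$admission_date[ir_row])
    search <- c(search, earlier)
    if (length(earlier)) {
      lookback_days <- as.numeric(person_episodes$admission_date[ir_row] -
                                    min(person_episodes$admission_date[earlier]))
    }
  }
  present <- apply(mat[search, , drop = FALSE], 2, any)
  out <- tibble::tibble(incident_id = index_episode_id, person_id = person_id)
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(present)))
  out$charlson_index <- charlson_index(names(present)[present], code_map)
  out$lookback_days_available <- lookback_days
  out
}

#' Comorbidity records for a set of incident cases
#'
#' Vectorised ascertainment.  With `person_assignment` (the linked
#' pathway) each incident searches its index record plus, under
#' lookback, all of the person's earlier records in `episodes`.
#' Without it (the unlinked pathway) no person identity exists: each
#' incident is ascertained from its identified episode alone and
#' `lookback` is ignored.
#'
#' @param incidents incident-case table (`index_episode_id`,
#'   `person_id`).
#' @param episodes episode table the records are drawn from.
#' @param person_assignment optional tibble (`episode_id`, `person_id`)
#'   partitioning the episodes, e.g. from [link_records()] or truth.
#' @param code_map a [load_code_map()] table.
#' @param lookback search earlier records (linked pathway only)?
#' @return tibble, one row per incident (see
#'   [ascertain_comorbidities()]).
#' @export
comorbidity_records <- function(incidents, episodes, person_assignment = NULL,
                                code_map = default_code_map(),
                                lookback = TRUE) {
  if (nrow(code_map) == 0) stop("empty code map", call. = FALSE)
  if (nrow(incidents) == 0) stop("no incident cases supplied", call. = FALSE)
  mat <- episode_condition_matrix(episodes, code_map)

  if (is.null(person_assignment)) {
    idx <- match(incidents$index_episode_id, episodes$episode_id)
    rows <- lapply(seq_len(nrow(incidents)), function(i) {
      sub <- episodes[idx[i], , drop = FALSE]
      ascertain_one(incidents$index_episode_id[i], incidents$person_id[i],
                    sub, mat[idx[i], , drop = FALSE], code_map, FALSE)
    })
    return(dplyr::bind_rows(rows))
  }

  person_of <- stats::setNames(person_assignment$person_id,
                               person_assignment$episode_id)
  rows_by_person <- split(seq_len(nrow(episodes)),
                          person_of[episodes$episode_id])
  rows <- lapply(seq_len(nrow(incidents)), function(i) {
    pid <- incidents$person_id[i]
    r <- rows_by_person[[pid]]
    ascertain_one(incidents$index_episode_id[i], pid,
                  episodes[r, , drop = FALSE],
                  mat[r, , drop = FALSE], code_map, lookback)
  })
  dplyr::bind_rows(rows)
}

#' Comorbidity prevalence table
#'
#' Prevalence (per cent, with confidence interval) of each condition
#' among the supplied comorbidity records, plus `any_charlson` and
#' `any_comorbidity` summary rows.  Conditions are rank-ordered by
#' descending prevalence with deterministic alphabetical tie-break.
#'
#' @param records output of [comorbidity_records()].
#' @param code_map a [load_code_map()] table.
#' @param ci_method,conf_level confidence-interval method (see
#'   [prop_ci()]) and level.
#' @return tibble with columns `condition`, `numerator`, `denominator`,
#'   `prevalence`, `ci_lower`, `ci_upper`, `rank` (NA for the summary
#'   rows, which come first).
#' @export
prevalence_table <- function(records, code_map = default_code_map(),
                             ci_method = "wilson", conf_level = 0.95) {
  if (is.null(records) || nrow(records) == 0) {
    stop("empty comorbidity record list", call. = FALSE)
  }
  conds <- intersect(unique(code_map$condition), names(records))
  n <- nrow(records)
  flags <- condition_charlson_flags(code_map)
  as_mat <- as.matrix(records[conds])
  num <- colSums(as_mat)
  any_ch <- sum(apply(as_mat[, flags[conds], drop = FALSE], 1, any))
  any_cm <- sum(apply(as_mat, 1, any))

  make_rows <- function(condition, x) {
    x <- unname(x)
    ci <- t(vapply(x, function(k) prop_ci(k, n, ci_method, conf_level),
                   c(0, 0)))
    tibble::tibble(condition = condition, numerator = as.numeric(x),
                   denominator = n, prevalence = 100 * x / n,
                   ci_lower = 100 * ci[, 1], ci_upper = 100 * ci[, 2])
  }
  summary_rows <- make_rows(c("any_comorbidity", "any_charlson"),
                            c(any_cm, any_ch))
  summary_rows$rank <- NA_integer_
  cond_rows <- make_rows(conds, num)
  ord <- order(-cond_rows$prevalence, cond_rows$condition)
  cond_rows <- cond_rows[ord, ]
  cond_rows$rank <- seq_len(nrow(cond_rows))
  out <- dplyr::bind_rows(summary_rows, cond_rows)
  class(out) <- c("prevalence_table", class(out))
  out
}

#' Share of comorbidity occurrences carried by the top-ranked conditions
#'
#' @param ptab a [prevalence_table()].
#' @param k number of top-ranked conditions.
#' @return percentage of all condition occurrences (summary rows
#'   excluded) accounted for by the `k` most prevalent conditions.
#' @export
top_share <- function(ptab, k = 3) {
  conds <- ptab[!is.na(ptab$rank), ]
  100 * sum(conds$numerator[conds$rank <= k]) / sum(conds$numerator)
}
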