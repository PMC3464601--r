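#' Confidence interval for a binomial proportion
#'
#' Wilson score interval by default (never leaves \[0,1\] and always
#' contains the point estimate); Clopper-Pearson exact and Wald
#' intervals are available for sensitivity of reporting.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param method `"wilson"`, `"exact"` or `"wald"`.
#' @param conf_level confidence level.
#' @return numeric vector `c(lower, upper)` on the proportion scale.
#' @export
prop_ci <- function(x, n, method = c("wilson", "exact", "wald"),
                    conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(n > 0, x >= 0, x <= n)
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- switch(method,
    wilson = {
      den <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / den
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      c(centre - half, centre + half)
    },
    exact = as.numeric(stats::binom.test(x, n,
                                         conf.level = conf_level)$conf.int),
    wald = pmin(pmax(p + c(-1, 1) * z * sqrt(p * (1 - p) / n), 0), 1)
  )
  ci <- pmin(pmax(ci, 0), 1)
  # containment of the point estimate is exact, not just up to rounding
  c(min(ci[1], p), max(ci[2], p))
}

#' Cross-classify scenario labels against the reference standard
#'
#' Counts extracted episodes by reference-standard label x scenario
#' label.  Both label tables must cover exactly the same episode set.
#'
#' @param ref_labels,scenario_labels tibbles (`episode_id`, `incident`).
#' @return an object of class `confusion_matrix` with fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion <- function(ref_labels, scenario_labels) {
  sym <- length(setdiff(ref_labels$episode_id, scenario_labels$episode_id)) +
    length(setdiff(scenario_labels$episode_id, ref_labels$episode_id))
  if (sym > 0) {
    stop("label tables cover different episode sets (symmetric difference ",
         sym, ")", call. = FALSE)
  }
  j <- dplyr::inner_join(ref_labels, scenario_labels, by = "episode_id",
                         suffix = c("_ref", "_scen"))
  structure(list(
    tp = sum(j$incident_ref & j$incident_scen),
    fp = sum(!j$incident_ref & j$incident_scen),
    fn = sum(j$incident_ref & !j$incident_scen),
    tn = sum(!j$incident_ref & !j$incident_scen)
  ), class = "confusion_matrix")
}

#' Overestimation of the incident count
#'
#' `(n_scenario - n_ref) / n_ref * 100`: the multiple-counting bias of a
#' scenario relative to the reference standard, as a percentage.
#'
#' @param n_scenario,n_ref incident counts.
#' @return percentage (can be negative when a scenario undercounts).
#' @examples
#' overestimation(11110, 10110)  # 9.9 (to one decimal)
#' @export
overestimation <- function(n_scenario, n_ref) {
  if (any(n_ref <= 0)) stop("reference count must be positive", call. = FALSE)
  (n_scenario - n_ref) / n_ref * 100
}

#' Accuracy of a scenario against the reference standard
#'
#' Standard definitions: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)`, negative
#' predictive value `TN/(TN+FN)`; each reported as a percentage with a
#' two-sided confidence interval, together with the overestimation of
#' the incident count.  A zero denominator yields `NA` with a warning.
#'
#' @param cm a [confusion()] matrix.
#' @param scenario scenario name for the report row.
#' @param ci_method,conf_level see [prop_ci()].
#' @return one-row tibble with counts, the four measures, their CIs and
#'   `overestimation`.
#' @export
accuracy_measures <- function(cm, scenario = NA_character_,
                              ci_method = "wilson", conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  measure <- function(x, n, what) {
    if (n == 0) {
      warning("zero denominator for ", what, call. = FALSE)
      return(c(NA_real_, NA_real_, NA_real_))
    }
    c(100 * x / n, 100 * prop_ci(x, n, ci_method, conf_level))
  }
  sens_v <- measure(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec_v <- measure(cm$tn, cm$tn + cm$fp, "specificity")
  ppv_v <- measure(cm$tp, cm$tp + cm$fp, "PPV")
  npv_v <- measure(cm$tn, cm$tn + cm$fn, "NPV")
  n_ref <- cm$tp + cm$fn
  n_scen <- cm$tp + cm$fp
  tibble::tibble(
    scenario = scenario,
    n_ref = n_ref, n_scenario = n_scen,
    overestimation = if (n_ref > 0) overestimation(n_scen, n_ref) else NA_real_,
    sensitivity = sens_v[1], sens_lower = sens_v[2], sens_upper = sens_v[3],
    specificity = spec_v[1], spec_lower = spec_v[2], spec_upper = spec_v[3],
    ppv = ppv_v[1], ppv_lower = ppv_v[2], ppv_upper = ppv_v[3],
    npv = npv_v[1], npv_lower = npv_v[2], npv_upper = npv_v[3]
  )
}

#' Two-sample test of proportions
#'
#' Chi-square test of two proportions (without continuity correction) by
#' default; when any expected cell count is below 5, Fisher's exact test
#' is used instead.  Two-tailed.
#'
#' @param x1,n1,x2,n2 successes and trials in the two samples.
#' @return list with `statistic` (chi-square; `NA` for the exact test),
#'   `p_value` and `method`.
#' @export
compare_proportions <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("both sample sizes must be positive",
                               call. = FALSE)
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                method = "fisher_exact"))
  }
  if (x1 / n1 == x2 / n2) {
    # degenerate equal proportions: chi-square statistic exactly 0
    return(list(statistic = 0, p_value = 1, method = "chi_square"))
  }
  pt <- stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)
  list(statistic = unname(pt$statistic), p_value = pt$p.value,
       method = "chi_square")
}

#' Age-specific hospital admission rates
#'
#' Rates per 100,000 community-dwelling population by (fiscal year,
#' sex, age band).  Strata with no cases are reported with rate 0; an
#' incident falling in a stratum missing from the population table is
#' an error naming the stratum.
#'
#' @param incidents incident-case table (needs `fiscal_year`, `sex`,
#'   `age_band`).
#' @param population a [population_table()].
#' @return tibble: population columns plus `cases` and `rate_per_100k`.
#' @export
age_specific_rates <- function(incidents, population) {
  counts <- dplyr::count(incidents, .data$fiscal_year, .data$sex,
                         .data$age_band, name = "cases")
  missing <- dplyr::anti_join(counts, population,
                              by = c("fiscal_year", "sex", "age_band"))
  if (nrow(missing) > 0) {
    stop("no population row for stratum ",
         paste(missing$fiscal_year[1], missing$sex[1], missing$age_band[1],
               collapse = " "), call. = FALSE)
  }
  out <- dplyr::left_join(population, counts,
                          by = c("fiscal_year", "sex", "age_band"))
  out$cases[is.na(out$cases)] <- 0L
  out$rate_per_100k <- 100000 * out$cases / out$community_denominator
  out
}

#' Directly standardised admission rates
#'
#' Weights each year's age-specific rates (sexes combined: cases and
#' denominators summed within age band) by a fixed standard population's
#' age structure.
#'
#' @param rate_table an [age_specific_rates()] table.
#' @param standard_population tibble (`age_band`, `weight` or
#'   `population`); weights are normalised to sum to 1 and must cover
#'   exactly the rate table's age bands.
#' @return tibble (`fiscal_year`, `std_rate_per_100k`).
#' @export
direct_standardise <- function(rate_table, standard_population) {
  if (!"weight" %in% names(standard_population)) {
    standard_population$weight <- standard_population$population /
      sum(standard_population$population)
  }
  standard_population$weight <- standard_population$weight /
    sum(standard_population$weight)
  if (!setequal(standard_population$age_band, rate_table$age_band)) {
    stop("standard population age bands do not match the rate table",
         call. = FALSE)
  }
  combined <- rate_table |>
    dplyr::group_by(.data$fiscal_year, .data$age_band) |>
    dplyr::summarise(cases = sum(.data$cases),
                     community_denominator = sum(.data$community_denominator),
                     .groups = "drop") |>
    dplyr::mutate(rate = 100000 * .data$cases / .data$community_denominator)
  w <- stats::setNames(standard_population$weight,
                       standard_population$age_band)
  combined |>
    dplyr::group_by(.data$fiscal_year) |>
    dplyr::summarise(
      std_rate_per_100k = sum(w[as.character(.data$age_band)] * .data$rate),
      .groups = "drop"
    )
}

#' Compare prevalence estimates between data sources
#'
#' Pairwise comparison of each condition's prevalence in a scenario's
#' records against the linked reference estimate, in absolute terms and
#' with a two-sample proportion test (see [compare_proportions()]).
#'
#' @param ref_table,scenario_table [prevalence_table()] objects.
#' @return tibble with both estimates, their absolute difference
#'   (scenario minus reference, percentage points) and the test.
#' @export
compare_prevalence <- function(ref_table, scenario_table) {
  j <- dplyr::inner_join(
    ref_table[c("condition", "numerator", "denominator", "prevalence")],
    scenario_table[c("condition", "numerator", "denominator", "prevalence")],
    by = "condition", suffix = c("_ref", "_scen")
  )
  tests <- lapply(seq_len(nrow(j)), function(i) {
    compare_proportions(j$numerator_scen[i], j$denominator_scen[i],
                        j$numerator_ref[i], j$denominator_ref[i])
  })
  j$difference <- j$prevalence_scen - j$prevalence_ref
  j$p_value <- vapply(tests, `[[`, 0, "p_value")
  j$method <- vapply(tests, `[[`, "", "method")
  j
}
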