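#' Key-corruption specification
#'
#' Per-episode, independent corruption probabilities for the linkage
#' keys recorded on each episode.  These drive the error regime of the
#' deterministic linkage: missing or perturbed keys fragment a person's
#' episodes (false negatives), while Medicare numbers shared within a
#' family can merge distinct persons (false positives).  The defaults
#' are calibrated so that, with the default linkage passes, the
#' transfer-pair false-negative rate is about 0.15 and the matched-pair
#' false-positive rate lies in \[0.01, 0.02\].
#'
#' @param dob_error probability that the recorded date of birth on an
#'   episode is perturbed (wrong day, possibly an impossible date, or a
#'   one-year shift).
#' @param postcode_error probability that the recorded postcode differs
#'   from the person's usual postcode.
#' @param medicare_missing probability that the Medicare surrogate is
#'   missing on an episode.
#' @param medicare_error probability that one digit of the Medicare
#'   surrogate is mis-keyed.
#' @return an object of class `corruption_spec`.
#' @export
corruption_spec <- function(dob_error = 0.13,
                            postcode_error = 0.12,
                            medicare_missing = 0.22,
                            medicare_error = 0.04) {
  spec <- list(dob_error = dob_error, postcode_error = postcode_error,
               medicare_missing = medicare_missing,
               medicare_error = medicare_error)
  for (nm in names(spec)) check_prob(spec[[nm]], nm)
  structure(spec, class = "corruption_spec")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("configuration error: `", name, "` must be a probability in [0, 1]",
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
    stop("configuration error: `", name, "` must be a positive integer",
         call. = FALSE)
  }
  invisible(x)
}

#' Default true comorbidity prevalences
#'
#' Person-level prevalences of Deyo-Charlson conditions and of five
#' additional fall/fracture risk factors (osteoporosis, Parkinson's
#' disease, visual impairment, deafness, delirium) used by the
#' synthetic-data generator.  Values emulate the comorbidity profile of
#' community-dwelling older hip-fracture patients as estimated from
#' linked discharge data; conditions are drawn independently per person.
#'
#' @return named numeric vector of probabilities.
#' @export
default_comorbidity_prevalences <- function() {
  c(
    renal                  = 0.076,
    dementia               = 0.071,
    chf                    = 0.057,
    diabetes               = 0.054,
    diabetes_complications = 0.053,
    pulmonary              = 0.043,
    osteoporosis           = 0.039,
    parkinsons             = 0.030,
    delirium               = 0.026,
    cerebrovascular        = 0.022,
    mi                     = 0.020,
    cancer                 = 0.018,
    vision_impairment      = 0.017,
    deafness               = 0.014,
    paraplegia             = 0.013,
    pvd                    = 0.010,
    rheumatic              = 0.005,
    metastatic             = 0.004,
    peptic_ulcer           = 0.002,
    liver_mild             = 0.002,
    liver_severe           = 0.0005,
    hiv                    = 0.0
  )
}

#' Simulation configuration for the synthetic discharge-data cohort
#'
#' Bundles every parameter of the synthetic episode-of-care generator.
#' The defaults define the study conditions the analysis emulates: a
#' three-fiscal-year observation window (1 July 2005 to 30 June 2008),
#' a 65+ cohort with median age ~81 (IQR 72-86), 2.3% of fractured
#' persons sustaining a second fall-related hip fracture a median of
#' 335 days after the first (never sooner than the 120-day clearance
#' period), and hospital reuse such that about 64.7% of repeat
#' admissions return to the same public hospital.
#'
#' @param n_persons number of persons in the cohort.
#' @param study_start,study_end observation window (`Date`).
#' @param age_median,age_q1,age_q3 target quantiles of the age
#'   distribution (years); ages follow a lognormal truncated to
#'   `[age_min, age_max]` fitted to these quantiles.
#' @param age_min,age_max support of the age distribution.
#' @param female_fraction probability a person is female.
#' @param nursing_home_fraction probability a person resides in a
#'   nursing home (admission source `nursing_home`; such persons are
#'   outside the community-dwelling incidence scope).
#' @param fracture_hazard probability that a person aged 80 sustains a
#'   first fall-related hip fracture during the window; the hazard
#'   doubles every `fracture_age_doubling` years of age (capped at 0.9).
#' @param fracture_age_doubling years of age per doubling of fracture
#'   risk.
#' @param second_fracture_prob probability that a fractured (surviving)
#'   person sustains a second fall-related hip fracture inside the
#'   window.
#' @param second_gap_median,second_gap_sdlog lognormal parameters of the
#'   admission-to-admission gap between first and second fracture
#'   (days); the gap is truncated below at `second_gap_min`.
#' @param second_gap_min minimum first-to-second gap (days); must be at
#'   least the 120-day clearance period.
#' @param second_triple_differs probability that the second fracture's
#'   external-cause triple (mechanism, place, activity) differs from the
#'   first's in all three components.  The default 1 is the assumption
#'   the reference-standard selector relies on; lower it to study the
#'   rule's failure mode.
#' @param transfer_prob probability an index admission ends in an
#'   inter-hospital transfer (two episodes: sender discharged with
#'   status `transfer`, receiver admitted from source `transfer`).
#' @param readmission_30d_prob probability of a readmission within 30
#'   days of discharge belonging to the same fracture event.
#' @param readmission_120d_prob probability of a readmission 31-120 days
#'   after discharge belonging to the same event.
#' @param revision_readmission_prob probability a readmission episode
#'   carries hip revision procedure codes only.
#' @param nonacute_episode_prob probability a readmission episode has
#'   care type `non_acute`.
#' @param nonemergency_readmission_prob probability a readmission
#'   episode has admission category `non_emergency`.
#' @param inhospital_death_prob probability a fracture event ends in
#'   in-hospital death during the index acute admission (the event then
#'   has no transfer or readmission episodes).
#' @param nonfracture_fall_rate expected number (Poisson) of
#'   non-fracture fall-injury episodes per person over the window
#'   (principal diagnosis in S00-T75/T79 but outside S72.0-S72.2);
#'   these populate the specificity denominator and the lookback pool.
#' @param public_hospital_fraction probability a person's usual hospital
#'   is public.
#' @param same_hospital_prob probability a readmission returns to the
#'   same hospital as the previous episode (0.809 x 0.80 public share
#'   gives ~64.7% same-public-hospital reuse).
#' @param n_hospitals_public,n_hospitals_private hospital pool sizes.
#' @param n_postcodes number of distinct residential postcodes.
#' @param medicare_shared_prob probability a person shares a (family)
#'   Medicare surrogate with another cohort member.
#' @param prestart_event_fraction fraction of first fracture events
#'   whose index admission is placed before `study_start` (their index
#'   episode falls outside the dataset, emulating left-censoring of the
#'   lookback window).  Default 0.
#' @param comorbidity_prevalences named vector of true person-level
#'   condition probabilities (see [default_comorbidity_prevalences()]).
#' @param per_episode_coding_prob probability a truly present condition
#'   is coded on any given episode (under-coding of discharge data).
#' @param hospital_acquired_prob probability a coded condition carries
#'   the onset flag `arose_during_episode` rather than
#'   `present_on_admission`.
#' @param population_total synthetic resident population aged 65+ behind
#'   the cohort, used for rate denominators.
#' @param key_corruption a [corruption_spec()].
#' @param age_bands lower bounds of the reporting age bands.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_persons = 20000,
                              study_start = as.Date("2005-07-01"),
                              study_end = as.Date("2008-06-30"),
                              age_median = 81, age_q1 = 72, age_q3 = 86,
                              age_min = 65, age_max = 105,
                              female_fraction = 0.72,
                              nursing_home_fraction = 0.25,
                              fracture_hazard = 0.12,
                              fracture_age_doubling = 6,
                              second_fracture_prob = 0.023,
                              second_gap_median = 335,
                              second_gap_sdlog = 0.69,
                              second_gap_min = 120,
                              second_triple_differs = 1,
                              transfer_prob = 0.25,
                              readmission_30d_prob = 0.40,
                              readmission_120d_prob = 0.02,
                              revision_readmission_prob = 0.15,
                              nonacute_episode_prob = 0.20,
                              nonemergency_readmission_prob = 0.5,
                              inhospital_death_prob = 0.055,
                              nonfracture_fall_rate = 0.5,
                              public_hospital_fraction = 0.80,
                              same_hospital_prob = 0.809,
                              n_hospitals_public = 60,
                              n_hospitals_private = 40,
                              n_postcodes = 80,
                              medicare_shared_prob = 0.016,
                              prestart_event_fraction = 0,
                              comorbidity_prevalences = default_comorbidity_prevalences(),
                              per_episode_coding_prob = 0.70,
                              hospital_acquired_prob = 0.05,
                              population_total = 268000,
                              key_corruption = corruption_spec(),
                              age_bands = c(65, 70, 75, 80, 85)) {
  cfg <- as.list(environment())
  check_count(cfg$n_persons, "n_persons")
  cfg$study_start <- as.Date(study_start)
  cfg$study_end <- as.Date(study_end)
  if (!cfg$study_start < cfg$study_end) {
    stop("configuration error: `study_start` must precede `study_end`",
         call. = FALSE)
  }
  probs <- c("female_fraction", "nursing_home_fraction", "fracture_hazard",
             "second_fracture_prob", "second_triple_differs",
             "transfer_prob", "readmission_30d_prob", "readmission_120d_prob",
             "revision_readmission_prob", "nonacute_episode_prob",
             "nonemergency_readmission_prob", "inhospital_death_prob",
             "public_hospital_fraction", "same_hospital_prob",
             "medicare_shared_prob", "prestart_event_fraction",
             "per_episode_coding_prob", "hospital_acquired_prob")
  for (nm in probs) check_prob(cfg[[nm]], nm)
  if (cfg$second_gap_min < 120) {
    stop("configuration error: `second_gap_min` must be >= 120 days ",
         "(the clearance period)", call. = FALSE)
  }
  if (any(cfg$comorbidity_prevalences < 0 | cfg$comorbidity_prevalences > 1) ||
      is.null(names(cfg$comorbidity_prevalences))) {
    stop("configuration error: `comorbidity_prevalences` must be a named ",
         "vector of probabilities in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(names(cfg$comorbidity_prevalences),
                 unique(default_code_map()$condition))
  if (length(bad)) {
    stop("configuration error: `comorbidity_prevalences` names unknown to ",
         "the code map: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$nonfracture_fall_rate < 0) {
    stop("configuration error: `nonfracture_fall_rate` must be >= 0",
         call. = FALSE)
  }
  if (!inherits(cfg$key_corruption, "corruption_spec")) {
    cfg$key_corruption <- do.call(corruption_spec, as.list(cfg$key_corruption))
  }
  structure(cfg, class = "simulation_config")
}

# Fit a lognormal truncated to [lo, hi] to target quantiles (q25, q50, q75).
fit_truncated_lognormal <- function(q25, q50, q75, lo, hi) {
  obj <- function(par) {
    ml <- par[1]; sl <- exp(par[2])
    plo <- stats::plnorm(lo, ml, sl); phi <- stats::plnorm(hi, ml, sl)
    q <- stats::qlnorm(plo + c(0.25, 0.5, 0.75) * (phi - plo), ml, sl)
    sum((q - c(q25, q50, q75))^2)
  }
  fit <- stats::optim(c(log(q50), log(0.12)), obj)
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

# Inverse-CDF sampler for the truncated lognormal.
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# Expected age-band probabilities under the configured age distribution.
age_band_probs <- function(config) {
  fit <- fit_truncated_lognormal(config$age_q1, config$age_median,
                                 config$age_q3, config$age_min, config$age_max)
  breaks <- c(config$age_bands, Inf)
  lo <- stats::plnorm(config$age_min, fit$meanlog, fit$sdlog)
  hi <- stats::plnorm(config$age_max, fit$meanlog, fit$sdlog)
  cdf <- function(x) {
    (pmin(pmax(stats::plnorm(x, fit$meanlog, fit$sdlog), lo), hi) - lo) /
      (hi - lo)
  }
  upper <- pmin(breaks[-1], config$age_max)
  p <- cdf(upper) - cdf(breaks[-length(breaks)])
  names(p) <- age_band_levels(config$age_bands)
  p / sum(p)
}

#' Experiment configuration
#'
#' A full experiment bundles the simulation configuration, the linkage
#' pass set, the unlinked scenarios to evaluate, the confidence-interval
#' method and a single seed governing every stochastic stage.
#'
#' @param simulation a [simulation_config()].
#' @param passes list of linkage passes (see [linkage_pass()]).
#' @param scenarios character vector of unlinked scenario names.
#' @param ci_method `"wilson"`, `"exact"` or `"wald"`.
#' @param seed integer master seed.
#' @return an object of class `experiment_config`.
#' @seealso [run_experiment()], [write_experiment_config()]
#' @export
experiment_config <- function(simulation = simulation_config(),
                              passes = default_linkage_passes(),
                              scenarios = c("base", "S1", "S2", "S3", "S4"),
                              ci_method = c("wilson", "exact", "wald"),
                              seed = 1L) {
  stopifnot(inherits(simulation, "simulation_config"))
  ci_method <- match.arg(ci_method)
  unknown <- setdiff(scenarios, setdiff(shipped_scenarios(), "reference"))
  if (length(unknown)) {
    stop("unknown scenario(s): ", paste(unknown, collapse = ", "),
         "; shipped scenarios are: ",
         paste(shipped_scenarios(), collapse = ", "), call. = FALSE)
  }
  structure(list(simulation = simulation, passes = passes,
                 scenarios = scenarios, ci_method = ci_method,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' Round-trips losslessly: `read_experiment_config(write_experiment_config(x))`
#' reproduces `x`.
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `read_experiment_config()` returns an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- unclass(config$simulation)
  sim$study_start <- format(sim$study_start)
  sim$study_end <- format(sim$study_end)
  sim$key_corruption <- unclass(sim$key_corruption)
  sim$comorbidity_prevalences <- as.list(sim$comorbidity_prevalences)
  out <- list(
    simulation = sim,
    passes = lapply(config$passes, function(p) as.list(p$keys)),
    scenarios = as.list(config$scenarios),
    ci_method = config$ci_method,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  sim$study_start <- as.Date(sim$study_start)
  sim$study_end <- as.Date(sim$study_end)
  sim$key_corruption <- do.call(corruption_spec, sim$key_corruption)
  sim$comorbidity_prevalences <- unlist(sim$comorbidity_prevalences)
  sim$age_bands <- unlist(sim$age_bands)
  sim <- do.call(simulation_config, sim)
  experiment_config(
    simulation = sim,
    passes = lapply(raw$passes, function(k) linkage_pass(unlist(k))),
    scenarios = unlist(raw$scenarios),
    ci_method = raw$ci_method,
    seed = raw$seed
  )
}
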