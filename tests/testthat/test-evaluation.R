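labels_tbl <- function(ids, x) tibble::tibble(episode_id = ids,
                                              incident = as.logical(x))

test_that("confusion counts match hand enumeration and a brute-force tally", {
  ids <- sprintf("E%03d", 1:4)
  cm <- confusion(labels_tbl(ids, c(1, 1, 0, 0)),
                  labels_tbl(ids, c(1, 0, 1, 0)))
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 1, fn = 1, fp = 1, tn = 1))

  # identical labels: no errors
  cm2 <- confusion(labels_tbl(ids, c(1, 1, 0, 0)),
                   labels_tbl(ids, c(1, 1, 0, 0)))
  expect_equal(cm2$fp + cm2$fn, 0)

  # brute-force oracle on random labels at n = 1000
  set.seed(101)
  ids <- sprintf("E%04d", 1:1000)
  ref <- stats::runif(1000) < 0.3
  scen <- stats::runif(1000) < 0.35
  cm4 <- confusion(labels_tbl(ids, ref), labels_tbl(ids, scen))
  # row order of the label tables must not matter
  shuffle <- sample(1000)
  cm3 <- confusion(labels_tbl(ids, ref),
                   labels_tbl(ids[shuffle], scen[shuffle]))
  expect_equal(unclass(cm3), unclass(cm4))
  tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in 1:1000) {
    k <- if (ref[i] && scen[i]) "tp" else if (!ref[i] && scen[i]) "fp"
    else if (ref[i] && !scen[i]) "fn" else "tn"
    tally[k] <- tally[k] + 1
  }
  expect_equal(unlist(unclass(cm4)), tally[c("tp", "fp", "fn", "tn")])
  # marginal invariants
  expect_equal(cm4$tp + cm4$fn, sum(ref))
  expect_equal(cm4$tp + cm4$fp, sum(scen))

  expect_error(confusion(labels_tbl(ids, ref), labels_tbl(ids[-1], scen[-1])),
               "symmetric difference")
})

test_that("accuracy measures equal hand-computed ratios", {
  cm <- structure(list(tp = 8, fp = 2, fn = 1, tn = 9),
                  class = "confusion_matrix")
  acc <- accuracy_measures(cm, "toy")
  expect_equal(acc$sensitivity, 100 * 8 / 9)
  expect_equal(acc$specificity, 100 * 9 / 11)
  expect_equal(acc$ppv, 100 * 8 / 10)
  expect_equal(acc$npv, 100 * 9 / 10)
  expect_equal(acc$overestimation, 100 * (10 - 9) / 9)

  perfect <- structure(list(tp = 5, fp = 0, fn = 0, tn = 5),
                       class = "confusion_matrix")
  accp <- accuracy_measures(perfect)
  expect_equal(c(accp$sensitivity, accp$specificity, accp$ppv, accp$npv),
               rep(100, 4))
  expect_equal(accp$overestimation, 0)

  degenerate <- structure(list(tp = 0, fp = 0, fn = 3, tn = 7),
                          class = "confusion_matrix")
  expect_warning(accd <- accuracy_measures(degenerate), "PPV")
  expect_true(is.na(accd$ppv))
})

test_that("published accuracy figures are internally consistent", {
  # PPV reconstructed from sensitivity and the two counts:
  # 94.4% of 10,110 reference cases over 11,110 identified cases
  expect_equal(round(100 * (0.944 * 10110) / 11110, 1), 85.9)
  # overestimation row reproduced from the count row
  expect_equal(round(overestimation(11110, 10110), 1), 9.9)
  expect_equal(round(overestimation(11746, 10110), 1), 16.2)
  expect_equal(round(overestimation(11056, 10110), 1), 9.4)
  expect_equal(round(overestimation(10173, 10110), 1), 0.6)
  expect_equal(round(overestimation(10765, 10110), 1), 6.5)
  expect_equal(overestimation(10110, 10110), 0)
  expect_error(overestimation(10, 0), "positive")
})

test_that("PPV identity links sensitivity, counts and the confusion matrix", {
  set.seed(7)
  for (i in 1:20) {
    tp <- sample(50:500, 1); fp <- sample(0:200, 1)
    fn <- sample(0:100, 1); tn <- sample(100:2000, 1)
    cm <- structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
                    class = "confusion_matrix")
    acc <- accuracy_measures(cm)
    reconstructed <- (acc$sensitivity / 100 * acc$n_ref) / acc$n_scenario * 100
    expect_equal(reconstructed, acc$ppv, tolerance = 1e-12)
  }
})

test_that("Wilson intervals stay in range and contain the estimate", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    x <- sample(0:n, 1)
    ci <- prop_ci(x, n, "wilson")
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    expect_true(ci[1] <= x / n && x / n <= ci[2])
  }
  # frozen hand computation for 3/10
  expect_equal(prop_ci(3, 10, "wilson"), c(0.1077913, 0.6032219),
               tolerance = 1e-6)
  # alternative methods also bracket the estimate
  expect_true(all(prop_ci(3, 10, "exact") - c(0, 0.3) <= c(0.3, 1)))
  ciw <- prop_ci(3, 10, "wald")
  expect_true(ciw[1] <= 0.3 && ciw[2] >= 0.3)
})

test_that("proportion tests match enumeration and normal-approximation oracles", {
  # identical proportions: statistic 0, p 1
  same <- compare_proportions(30, 100, 30, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$method, "chi_square")

  # small samples: exact test equals full hypergeometric enumeration
  small <- compare_proportions(3, 10, 1, 10)
  expect_equal(small$method, "fisher_exact")
  m <- 3 + 1
  d <- stats::dhyper(0:m, m, 20 - m, 10)
  enumerated <- sum(d[d <= d[3 + 1] * (1 + 1e-7)])
  expect_equal(small$p_value, enumerated, tolerance = 1e-10)

  # large samples: chi-square equals the squared two-proportion z statistic
  big <- compare_proportions(300, 1000, 250, 1000)
  p_pool <- 550 / 2000
  z <- (0.3 - 0.25) / sqrt(p_pool * (1 - p_pool) * (1 / 1000 + 1 / 1000))
  expect_equal(big$statistic, z^2, tolerance = 1e-10)
  expect_equal(big$p_value, 2 * stats::pnorm(-abs(z)), tolerance = 1e-10)
  expect_equal(big$method, "chi_square")

  expect_error(compare_proportions(0, 0, 1, 10), "positive")
})

test_that("age-specific rates are cases per 100,000 community denominator", {
  pop <- tibble::tibble(
    fiscal_year = "2005/06", sex = c("F", "F"), age_band = c("65-69", "70-74"),
    population_estimate = c(12000, 11000),
    nursing_home_residents = c(2000, 1000),
    community_denominator = c(10000, 10000)
  )
  inc <- tibble::tibble(fiscal_year = rep("2005/06", 50), sex = "F",
                        age_band = "65-69")
  rt <- age_specific_rates(inc, pop)
  expect_equal(rt$rate_per_100k[rt$age_band == "65-69"], 500)
  expect_equal(rt$rate_per_100k[rt$age_band == "70-74"], 0)  # no cases

  bad <- tibble::tibble(fiscal_year = "2005/06", sex = "M",
                        age_band = "65-69")
  expect_error(age_specific_rates(bad, pop), "no population row")
})

test_that("direct standardisation equals the brute-force weighted sum", {
  # constant rates are invariant under any weights
  rt <- tidyr::expand_grid(fiscal_year = "2006/07", sex = c("F", "M"),
                           age_band = c("65-69", "70-74"))
  rt$community_denominator <- 10000
  rt$cases <- 30  # rate 300 everywhere
  std <- direct_standardise(rt, tibble::tibble(age_band = c("65-69", "70-74"),
                                               weight = c(0.9, 0.1)))
  expect_equal(std$std_rate_per_100k, 300)

  # two-band toy: 0.25 x 100 + 0.75 x 300 = 250
  rt2 <- tibble::tibble(fiscal_year = "2006/07", sex = "F",
                        age_band = c("65-69", "70-74"),
                        community_denominator = c(10000, 10000),
                        cases = c(10, 30))
  std2 <- direct_standardise(rt2, tibble::tibble(
    age_band = c("65-69", "70-74"), weight = c(0.25, 0.75)))
  expect_equal(std2$std_rate_per_100k, 250)

  # arbitrary table against an independently coded weighted sum
  set.seed(13)
  grid <- tidyr::expand_grid(fiscal_year = c("2005/06", "2006/07"),
                             sex = c("F", "M"),
                             age_band = age_band_levels())
  grid$community_denominator <- sample(5000:20000, nrow(grid))
  grid$cases <- stats::rpois(nrow(grid), 40)
  wts <- tibble::tibble(age_band = age_band_levels(),
                        population = sample(1000:9000, 5))
  std3 <- direct_standardise(grid, wts)
  w <- wts$population / sum(wts$population)
  names(w) <- wts$age_band
  for (fy in unique(grid$fiscal_year)) {
    manual <- 0
    for (b in names(w)) {
      sub <- grid[grid$fiscal_year == fy & grid$age_band == b, ]
      manual <- manual + w[[b]] * 1e5 * sum(sub$cases) /
        sum(sub$community_denominator)
    }
    expect_equal(std3$std_rate_per_100k[std3$fiscal_year == fy], manual)
  }
  # standardised rate lies between the min and max age-specific rates
  rates_by_band <- grid |>
    dplyr::group_by(fiscal_year, age_band) |>
    dplyr::summarise(rate = 1e5 * sum(cases) / sum(community_denominator),
                     .groups = "drop")
  for (fy in unique(grid$fiscal_year)) {
    r <- rates_by_band$rate[rates_by_band$fiscal_year == fy]
    s <- std3$std_rate_per_100k[std3$fiscal_year == fy]
    expect_true(s >= min(r) && s <= max(r))
  }

  expect_error(direct_standardise(rt2, tibble::tibble(
    age_band = "85+", weight = 1)), "age bands")
})

test_that("prevalence comparison reports differences and pairwise tests", {
  ref <- tibble::tibble(condition = c("dementia", "renal"),
                        numerator = c(71, 76), denominator = 1000,
                        prevalence = c(7.1, 7.6))
  scen <- tibble::tibble(condition = c("dementia", "renal"),
                         numerator = c(56, 58), denominator = 1000,
                         prevalence = c(5.6, 5.8))
  cmp <- compare_prevalence(ref, scen)
  expect_equal(cmp$difference, c(-1.5, -1.8))
  manual <- compare_proportions(56, 1000, 71, 1000)
  expect_equal(cmp$p_value[1], manual$p_value)
})
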