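test_that("month conversion follows the 30.4375-day convention", {
  d0 <- as.Date("2013-01-01")
  expect_equal(months_between(d0, d0), 0)
  expect_equal(months_between(d0, d0 + 70), 70 / 30.4375)
  expect_equal(round(months_between(d0, d0 + 70), 2), 2.30)
  expect_equal(round(months_between(d0, d0 + 183), 2), 6.01)
  expect_error(months_between(d0 + 1, d0), "d1 <= d2")
  expect_error(month_convention(0), "positive")
})

test_that("treatment duration spans first to last claim and ignores interior claims", {
  line <- tibble::tibble(start_date = as.Date("2013-01-01"),
                         end_date = as.Date("2013-01-01") + 71)
  expect_equal(round(treatment_duration(line), 2), 2.33)
  single <- tibble::tibble(start_date = as.Date("2013-01-01"),
                           end_date = as.Date("2013-01-01"))
  expect_equal(treatment_duration(single), 0)
})

test_that("time to next treatment is the start-to-start span in months", {
  l1 <- tibble::tibble(start_date = as.Date("2013-01-01"))
  l2 <- tibble::tibble(start_date = as.Date("2013-01-01") + 28)
  expect_equal(round(ttnt(l1, l2), 2), 0.92)
  expect_error(ttnt(l1, l1), "must start after")
})

test_that("summaries use sample SD and interpolated quartiles", {
  s <- summarize_values(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$iqi_low, 1.75)
  expect_equal(s$iqi_high, 3.25)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  one <- summarize_values(5)
  expect_equal(one$mean, 5)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
  expect_equal(one$iqi_low, 5)
  const <- summarize_values(rep(2.5, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$iqi_high, 2.5)
  expect_error(summarize_values(numeric(0)), "at least one")
})

test_that("treatment-period restriction drops between-line claims and keeps boundaries", {
  base <- as.Date("2014-01-01")
  lines <- tibble::tibble(start_date = c(base, base + 200),
                          end_date = c(base + 63, base + 263))
  claims <- tibble::tibble(
    patient_id = "X",
    service_date = base + c(0, 63, 100, 200, 964),
    category = "er_visit", code = "", setting = "outpatient",
    cost_brl_nominal = 1, admission_days = 0L)
  res <- restrict_to_treatment_periods(claims, lines)
  expect_equal(res$claims$service_date, base + c(0, 63, 200))
  expect_equal(res$exposure_months, (63 + 63) / 30.4375)
})

test_that("a single-day line contributes the exposure floor and keeps its claims", {
  base <- as.Date("2014-01-01")
  lines <- tibble::tibble(start_date = base, end_date = base)
  claims <- tibble::tibble(patient_id = "X", service_date = base,
                           category = "procedure", code = "P", setting = "outpatient",
                           cost_brl_nominal = 5, admission_days = 0L)
  res <- restrict_to_treatment_periods(claims, lines)
  expect_equal(res$exposure_months, 0.25)
  expect_equal(nrow(res$claims), 1)
})

test_that("pooled PPPM rate carries the exact Poisson interval", {
  est <- pppm_count(100, 400, 50)
  expect_equal(est$point, 0.25)
  # chi-square quantile oracle for the Garwood bounds on a count of 100
  expect_equal(est$ci_low * 400, qchisq(0.025, 200) / 2)
  expect_equal(est$ci_high * 400, qchisq(0.975, 202) / 2)
  expect_equal(round(est$ci_low, 4), 0.2034)
  expect_equal(round(est$ci_high, 4), 0.3041)
})

test_that("zero events give a zero rate with a zero lower bound", {
  est <- pppm_count(0, 50)
  expect_equal(est$point, 0)
  expect_equal(est$ci_low, 0)
  expect_gt(est$ci_high, 0)
})

test_that("doubling events and exposure keeps the rate and narrows the interval", {
  a <- pppm_count(50, 200)
  b <- pppm_count(100, 400)
  expect_equal(a$point, b$point)
  expect_lt(b$ci_high - b$ci_low, a$ci_high - a$ci_low)
  expect_error(pppm_count(10, 0), "positive")
})

test_that("gamma cost interval brackets the mean and collapses for constants", {
  set.seed(9)
  x <- rgamma(200, shape = 2, scale = 500)
  est <- pppm_cost(x)
  expect_equal(est$point, mean(x))
  expect_lt(est$ci_low, est$point)
  expect_gt(est$ci_high, est$point)
  const <- pppm_cost(rep(100, 50))
  expect_equal(c(const$ci_low, const$ci_high), c(100, 100))
  two <- pppm_cost(c(10, 30))
  expect_true(two$ci_low < 20 && 20 < two$ci_high)
  expect_warning(zero <- pppm_cost(rep(0, 10)), "zero")
  expect_equal(zero$ci_high, 0)
  expect_error(pppm_cost(5), "at least 2")
  expect_error(pppm_cost(c(-1, 2)), "non-negative")
})

test_that("gamma interval width shrinks toward the constant as n grows", {
  w <- sapply(c(50, 500, 5000), function(n) {
    est <- pppm_cost(rep(c(399, 401), length.out = n))
    est$ci_high - est$ci_low
  })
  expect_true(all(diff(w) < 0))
})

test_that("currency adjustment applies inflation then the exchange rate", {
  res <- adjust_and_convert(1000)
  expect_equal(res$brl_adjusted, 1576.9934)
  expect_equal(res$usd, 1576.9934 * 0.1968581)
  adj <- adjust_and_convert(37345.27, already_adjusted = TRUE)
  expect_equal(adj$brl_adjusted, 37345.27)
  expect_equal(round(adj$usd, 2), 7351.72)
  expect_equal(adjust_and_convert(0)$usd, 0)
  expect_error(adjust_and_convert(-1), "non-negative")
})

test_that("currency chain is linear to currency precision", {
  set.seed(11)
  a <- runif(20, 0, 1e5); b <- runif(20, 0, 1e5)
  expect_equal(adjust_and_convert(a + b)$usd,
               adjust_and_convert(a)$usd + adjust_and_convert(b)$usd)
})

test_that("cost aggregation assigns categories to settings and excludes medication", {
  claims <- tibble::tibble(
    patient_id = "X", service_date = as.Date("2014-01-01") + 0:4,
    category = c("drug", "surgery", "inpatient_admission", "procedure", "er_visit"),
    code = c("paclitaxel", "S", "", "P", ""),
    setting = c("outpatient", "inpatient", "inpatient", "outpatient", "outpatient"),
    cost_brl_nominal = c(9999, 1000, 500, 200, 100), admission_days = c(0L, 0L, 3L, 0L, 0L))
  costs <- aggregate_costs(claims)
  expect_equal(costs$inpatient_brl, 1500 * 1.5769934)
  expect_equal(costs$outpatient_brl, 300 * 1.5769934)
  expect_equal(costs$total_brl, costs$inpatient_brl + costs$outpatient_brl)
  expect_true(costs$medication_excluded)
  drug_only <- claims[claims$category == "drug", ]
  expect_equal(aggregate_costs(drug_only)$total_brl, 0)
})

test_that("total cost equals inpatient plus outpatient on random claim sets", {
  set.seed(12)
  for (k in 1:25) {
    costs <- aggregate_costs(random_cost_claims())
    expect_equal(costs$total_brl, costs$inpatient_brl + costs$outpatient_brl)
    expect_equal(costs$total_usd, costs$inpatient_usd + costs$outpatient_usd)
  }
})

test_that("patient-level period metrics feed a consistent cohort PPPM table", {
  sim <- simulate_claims(simulation_config(n_patients = 60, seed = 33))
  lines <- build_cohort_lines(sim$claims)
  pm <- patient_period_metrics(sim$claims, lines)
  expect_equal(sort(unique(pm$patient_id)), sort(unique(lines$patient_id)))
  expect_true(all(pm$exposure_months > 0))
  expect_equal(pm$total_brl, pm$inpatient_brl + pm$outpatient_brl)
  tab <- cohort_pppm_table(pm)
  rate_rows <- tab[tab$family == "poisson", ]
  expect_true(all(rate_rows$ci_low <= rate_rows$point &
                    rate_rows$point <= rate_rows$ci_high))
  er <- tab[tab$measure == "er_visit", ]
  expect_equal(er$point, sum(pm$er_visit) / sum(pm$exposure_months))
})
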