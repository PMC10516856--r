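#' Month convention
#'
#' All day spans are converted to months with a single constant,
#' 365.25/12 = 30.4375 days per month.
#'
#' @param days_per_month Days in one month.
#' @return A `month_convention` list.
#' @export
month_convention <- function(days_per_month = 30.4375) {
  if (!is.numeric(days_per_month) || days_per_month <= 0) {
    stop("days_per_month must be strictly positive", call. = FALSE)
  }
  structure(list(days_per_month = days_per_month), class = "month_convention")
}

#' Months between two dates
#'
#' @param d1,d2 Dates with `d1 <= d2` (vectorised).
#' @param conv A [month_convention()].
#' @return Numeric months: `(d2 - d1) / days_per_month`.
#' @examples
#' months_between(as.Date("2013-01-01"), as.Date("2013-03-12"))
#' @export
months_between <- function(d1, d2, conv = month_convention()) {
  d1 <- as.Date(d1); d2 <- as.Date(d2)
  if (any(d1 > d2, na.rm = TRUE)) {
    stop("months_between requires d1 <= d2", call. = FALSE)
  }
  as.numeric(d2 - d1) / conv$days_per_month
}

#' Treatment duration of a line in months
#'
#' First to last constituent claim; a single-claim line has duration 0.
#'
#' @param line One row of a lines tibble (or a tibble; vectorised over
#'   rows).
#' @param conv A [month_convention()].
#' @return Numeric months.
#' @export
treatment_duration <- function(line, conv = month_convention()) {
  months_between(line$start_date, line$end_date, conv)
}

#' Time to next treatment (TTNT) in months
#'
#' Months from one line's first claim to the next line's first claim.
#'
#' @param line_n,line_next Two consecutive lines of one patient;
#'   `line_next` must start strictly after `line_n`.
#' @param conv A [month_convention()].
#' @return Numeric months.
#' @export
ttnt <- function(line_n, line_next, conv = month_convention()) {
  if (any(as.Date(line_next$start_date) <= as.Date(line_n$start_date))) {
    stop("ttnt: next line must start after the current line", call. = FALSE)
  }
  months_between(line_n$start_date, line_next$start_date, conv)
}

#' Summary statistics in the duration-table layout
#'
#' Mean, sample SD (n - 1 denominator; reported as 0 for a single value,
#' with `sd_defined = FALSE`), median and the interquartile interval (25th
#' and 75th percentiles, linear interpolation between order statistics).
#'
#' @param values Numeric vector, length at least 1.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `iqi_low`,
#'   `iqi_high`, `sd_defined`.
#' @examples
#' summarize_values(c(1, 2, 3, 4))
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(is.na(values))) {
    stop("summarize_values requires at least one non-missing value", call. = FALSE)
  }
  n <- length(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = n, mean = mean(values),
                 sd = if (n > 1) stats::sd(values) else 0,
                 median = q[2], iqi_low = q[1], iqi_high = q[3],
                 sd_defined = n > 1)
}

#' Restrict claims to treatment periods and measure exposure
#'
#' Utilization and costs are assessed only while the patient is on therapy:
#' claims dated inside any line's `[start_date, end_date]` interval (closed
#' on both ends) are kept, and exposure is the sum of line durations in
#' months. A line whose start and end coincide contributes the exposure
#' floor (0.25 month by default) so single-visit lines do not produce a
#' zero denominator; the floor is applied per line as
#' `max(duration, floor)`.
#'
#' @param claims Claims of one patient.
#' @param lines The patient's lines ([build_lines()] output).
#' @param conv A [month_convention()].
#' @param exposure_floor_months Minimum exposure a line contributes.
#' @return A list with `claims` (filtered tibble) and `exposure_months`.
#' @export
restrict_to_treatment_periods <- function(claims, lines,
                                          conv = month_convention(),
                                          exposure_floor_months = 0.25) {
  if (nrow(lines) == 0) {
    return(list(claims = claims[0, ], exposure_months = 0))
  }
  keep <- rep(FALSE, nrow(claims))
  for (i in seq_len(nrow(lines))) {
    keep <- keep | (claims$service_date >= lines$start_date[i] &
                      claims$service_date <= lines$end_date[i])
  }
  exposure <- sum(pmax(months_between(lines$start_date, lines$end_date, conv),
                       exposure_floor_months))
  list(claims = claims[keep, , drop = FALSE], exposure_months = exposure)
}

#' Pooled per-patient-per-month event rate with an exact Poisson CI
#'
#' The point estimate is the pooled rate, total events over total
#' patient-months. The 95% interval is the exact (Garwood) Poisson interval
#' for the total count — lower bound `qchisq(0.025, 2k)/2`, upper bound
#' `qchisq(0.975, 2k + 2)/2`, zero lower bound for `k = 0` — divided by the
#' exposure.
#'
#' @param total_events Non-negative integer count of events.
#' @param exposure_months Total patient-months at risk; must be positive.
#' @param n_patients Number of patients contributing (carried through for
#'   reporting).
#' @param conf_level Confidence level.
#' @return A `pppm_estimate` tibble row: `point`, `ci_low`, `ci_high`,
#'   `family = "poisson"`, `n_patients`, `total_exposure_months`.
#' @examples
#' pppm_count(100, 400, 50)
#' @export
pppm_count <- function(total_events, exposure_months, n_patients = NA_integer_,
                       conf_level = 0.95) {
  if (exposure_months <= 0) stop("exposure must be positive", call. = FALSE)
  if (total_events < 0) stop("event count must be non-negative", call. = FALSE)
  k <- total_events
  alpha <- 1 - conf_level
  lower <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  tibble::tibble(point = k / exposure_months,
                 ci_low = lower / exposure_months,
                 ci_high = upper / exposure_months,
                 family = "poisson", n_patients = as.integer(n_patients),
                 total_exposure_months = exposure_months)
}

#' Mean per-patient-per-month cost with a moment-matched gamma CI
#'
#' The point estimate is the mean of the per-patient PPPM costs. For the
#' interval, a gamma distribution is moment-matched to the patient values
#' (shape `k = m^2/v`, scale `theta = v/m`); the mean of `n` such gammas is
#' gamma with shape `n k` and scale `theta/n`, and the 2.5% and 97.5%
#' quantiles of that distribution bound the mean. Degenerate inputs
#' (all-zero values, or zero variance) collapse the interval to the point,
#' with a warning in the all-zero case.
#'
#' @param per_patient_pppm Numeric vector of per-patient PPPM costs,
#'   length at least 2, all non-negative.
#' @param conf_level Confidence level.
#' @return A `pppm_estimate` tibble row with `family = "gamma"`.
#' @examples
#' set.seed(1)
#' pppm_cost(rgamma(100, shape = 2, scale = 500))
#' @export
pppm_cost <- function(per_patient_pppm, conf_level = 0.95) {
  x <- as.numeric(per_patient_pppm)
  if (length(x) < 2) stop("pppm_cost requires at least 2 patients", call. = FALSE)
  if (any(is.na(x)) || any(x < 0)) {
    stop("pppm_cost requires non-negative, non-missing values", call. = FALSE)
  }
  n <- length(x)
  m <- mean(x)
  v <- stats::var(x)
  alpha <- 1 - conf_level
  if (m == 0) {
    warning("all per-patient costs are zero; degenerate CI")
    ci <- c(0, 0)
  } else if (v == 0) {
    ci <- c(m, m)
  } else {
    shape <- m^2 / v
    scale <- v / m
    ci <- stats::qgamma(c(alpha / 2, 1 - alpha / 2), shape = n * shape,
                        scale = scale / n)
  }
  tibble::tibble(point = m, ci_low = ci[1], ci_high = ci[2],
                 family = "gamma", n_patients = n,
                 total_exposure_months = NA_real_)
}

#' Currency parameters: inflation adjustment and USD conversion
#'
#' Nominal 2012--2017 BRL amounts are brought to March-2023 price levels
#' with a single average inflation factor and then converted to USD at the
#' March-2023 exchange rate.
#'
#' @param inflation_factor Multiplicative price-adjustment factor.
#' @param brl_to_usd USD per adjusted BRL.
#' @return A `currency_parameters` list.
#' @export
currency_parameters <- function(inflation_factor = 1.5769934,
                                brl_to_usd = 0.1968581) {
  if (inflation_factor <= 0 || brl_to_usd <= 0) {
    stop("currency parameters must be strictly positive", call. = FALSE)
  }
  structure(list(inflation_factor = inflation_factor, brl_to_usd = brl_to_usd),
            class = "currency_parameters")
}

#' Adjust a nominal BRL amount and convert to USD
#'
#' @param nominal Non-negative BRL amount(s). When `already_adjusted` is
#'   `TRUE` the inflation step is skipped and only the exchange-rate step
#'   applies.
#' @param params A [currency_parameters()].
#' @param already_adjusted Is the input already at adjusted price levels?
#' @return A tibble with `brl_adjusted` and `usd`.
#' @examples
#' adjust_and_convert(1000)
#' adjust_and_convert(37345.27, already_adjusted = TRUE)
#' @export
adjust_and_convert <- function(nominal, params = currency_parameters(),
                               already_adjusted = FALSE) {
  nominal <- as.numeric(nominal)
  if (any(is.na(nominal)) || any(nominal < 0)) {
    stop("amounts must be non-negative and non-missing", call. = FALSE)
  }
  adjusted <- if (already_adjusted) nominal else nominal * params$inflation_factor
  tibble::tibble(brl_adjusted = adjusted, usd = adjusted * params$brl_to_usd)
}

#' Aggregate treatment-period claim costs by care setting
#'
#' Inpatient costs are the sum over admission and breast-surgery claims
#' (surgery is billed to the inpatient setting by definition); outpatient
#' costs sum outpatient visits, procedures and ER visits. Drug-claim costs
#' are excluded throughout — medication costs cannot be attributed reliably
#' in the source data — and total = inpatient + outpatient. Amounts are
#' returned in adjusted BRL and USD.
#'
#' @param claims Claims already restricted to treatment periods.
#' @param params A [currency_parameters()].
#' @return A one-row tibble: `inpatient_brl`, `outpatient_brl`, `total_brl`
#'   (adjusted BRL), the `_usd` counterparts, and `medication_excluded =
#'   TRUE`.
#' @export
aggregate_costs <- function(claims, params = currency_parameters()) {
  inpatient_nominal <- sum(claims$cost_brl_nominal[
    claims$category %in% c("inpatient_admission", "surgery")])
  outpatient_nominal <- sum(claims$cost_brl_nominal[
    claims$category %in% c("outpatient_visit", "procedure", "er_visit")])
  inp <- adjust_and_convert(inpatient_nominal, params)
  out <- adjust_and_convert(outpatient_nominal, params)
  tibble::tibble(
    inpatient_brl = inp$brl_adjusted, outpatient_brl = out$brl_adjusted,
    total_brl = inp$brl_adjusted + out$brl_adjusted,
    inpatient_usd = inp$usd, outpatient_usd = out$usd,
    total_usd = inp$usd + out$usd,
    medication_excluded = TRUE)
}

#' Per-patient treatment-period utilization and costs
#'
#' Convenience layer: for each patient, restricts claims to treatment
#' periods, counts events by category, aggregates costs and computes the
#' patient's exposure months. This is the patient-level table the PPPM
#' estimators consume.
#'
#' @param claims Cohort claims tibble.
#' @param lines Cohort lines ([build_cohort_lines()] output).
#' @param conv A [month_convention()].
#' @param params A [currency_parameters()].
#' @param exposure_floor_months Per-line exposure floor.
#' @return A tibble with one row per patient having at least one line:
#'   `patient_id`, `exposure_months`, `er_visit`, `outpatient_visit`,
#'   `procedure`, `inpatient_admission` (event counts), `admission_days`,
#'   cost columns as in [aggregate_costs()], and `total_pppm_brl`/`_usd`.
#' @export
patient_period_metrics <- function(claims, lines, conv = month_convention(),
                                   params = currency_parameters(),
                                   exposure_floor_months = 0.25) {
  count_cats <- c("er_visit", "outpatient_visit", "procedure",
                  "inpatient_admission")
  ids <- unique(lines$patient_id)
  by_patient <- split(claims, claims$patient_id)
  by_lines <- split(tibble::as_tibble(lines), lines$patient_id)
  rows <- lapply(ids, function(pid) {
    pl <- by_lines[[pid]]
    pc <- by_patient[[pid]] %||% claims[0, ]
    res <- restrict_to_treatment_periods(pc, pl, conv, exposure_floor_months)
    counts <- vapply(count_cats,
                     function(cat) sum(res$claims$category == cat), numeric(1))
    costs <- aggregate_costs(res$claims, params)
    tibble::tibble(
      patient_id = pid, exposure_months = res$exposure_months,
      !!!as.list(counts),
      admission_days = sum(res$claims$admission_days),
      costs,
      total_pppm_brl = costs$total_brl / res$exposure_months,
      total_pppm_usd = costs$total_usd / res$exposure_months,
      inpatient_pppm_brl = costs$inpatient_brl / res$exposure_months,
      inpatient_pppm_usd = costs$inpatient_usd / res$exposure_months,
      outpatient_pppm_brl = costs$outpatient_brl / res$exposure_months,
      outpatient_pppm_usd = costs$outpatient_usd / res$exposure_months)
  })
  dplyr::bind_rows(rows)
}

#' Cohort PPPM table for utilization and costs
#'
#' Computes, over a set of patients, the pooled PPPM rate with exact
#' Poisson CI for each event category and the mean per-patient PPPM cost
#' with moment-matched gamma CI for total, inpatient and outpatient costs.
#'
#' @param period_metrics Output of [patient_period_metrics()], optionally
#'   filtered to a stratum.
#' @return A tibble: `measure`, `point`, `ci_low`, `ci_high`, `family`,
#'   `n_patients`, `total_exposure_months`.
#' @export
cohort_pppm_table <- function(period_metrics) {
  pm <- tibble::as_tibble(period_metrics)
  if (nrow(pm) == 0) {
    stop("no patients in stratum", call. = FALSE)
  }
  exposure <- sum(pm$exposure_months)
  n <- nrow(pm)
  count_rows <- lapply(
    c("er_visit", "outpatient_visit", "procedure", "inpatient_admission"),
    function(cat) {
      est <- pppm_count(sum(pm[[cat]]), exposure, n)
      dplyr::mutate(est, measure = cat, .before = 1)
    })
  cost_cols <- c(total_pppm_brl = "total_cost_brl",
                 total_pppm_usd = "total_cost_usd",
                 inpatient_pppm_brl = "inpatient_cost_brl",
                 inpatient_pppm_usd = "inpatient_cost_usd",
                 outpatient_pppm_brl = "outpatient_cost_brl",
                 outpatient_pppm_usd = "outpatient_cost_usd")
  cost_rows <- lapply(names(cost_cols), function(col) {
    est <- pppm_cost(pm[[col]])
    dplyr::mutate(est, measure = cost_cols[[col]], .before = 1)
  })
  dplyr::bind_rows(c(count_rows, cost_rows))
}
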