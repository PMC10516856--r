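# Independent rule-replay oracles and small claim-set generators used by the
# property tests. These are deliberately naive re-statements of the rules,
# kept separate from the package implementation.

# Brute-force staging oracle: enumerate all pairs of qualifying claims and
# check window membership and pairwise separation.
oracle_stage <- function(claims, index_date, catalog,
                         before = 30, after = 183, sep = 15) {
  index_date <- as.Date(index_date)
  qual_dates <- as.Date(character(0))
  for (i in seq_len(nrow(claims))) {
    is_met_icd <- claims$category[i] == "diagnosis" &&
      is_metastatic_code(claims$code[i], catalog)
    is_mgmt <- claims$code[i] %in% catalog$metastatic_management_codes
    in_win <- claims$service_date[i] >= index_date - before &&
      claims$service_date[i] <= index_date + after
    if ((is_met_icd || is_mgmt) && in_win) {
      qual_dates <- c(qual_dates, claims$service_date[i])
    }
  }
  met <- FALSE
  if (length(qual_dates) >= 2) {
    for (i in seq_along(qual_dates)) {
      for (j in seq_along(qual_dates)) {
        if (i < j && abs(as.numeric(qual_dates[i] - qual_dates[j])) >= sep) {
          met <- TRUE
        }
      }
    }
  }
  if (met) "metastatic" else "early_locally_advanced"
}

# Random small claim sets around an index date for the staging properties.
random_staging_claims <- function(index_date, max_claims = 8) {
  n <- sample.int(max_claims, 1)
  codes <- sample(c("C78.0", "C79.5", "C80", "C77.3", "C773", "C50.9",
                    "MM001", "ZZ999"), n, replace = TRUE)
  category <- ifelse(startsWith(codes, "C") & !startsWith(codes, "MM"),
                     "diagnosis", "procedure")
  tibble::tibble(
    patient_id = "X", service_date = index_date + sample(-400:400, n, replace = TRUE),
    category = category, code = codes, setting = "outpatient",
    cost_brl_nominal = 0, admission_days = 0L)
}

# Step-by-step line-of-therapy oracle: walk service dates in order and apply,
# in this order, the treatment-free-gap rule then the switch rule.
oracle_lines <- function(dates, molecules, switch_days = 60, gap_days = 120) {
  ord <- order(dates)
  dates <- dates[ord]
  molecules <- molecules[ord]
  udates <- sort(unique(dates))
  line_starts <- udates[1]
  triggers <- "initiation"
  regimen <- unique(molecules[dates == udates[1]])
  line_start <- udates[1]
  prev_date <- udates[1]
  for (d in as.list(udates[-1])) {
    mols <- unique(molecules[dates == d])
    if (as.numeric(d - prev_date) >= gap_days) {
      line_starts <- c(line_starts, d)
      triggers <- c(triggers, "gap_120d")
      regimen <- mols
      line_start <- d
    } else if (as.numeric(d - line_start) >= switch_days &&
               length(setdiff(mols, regimen)) > 0) {
      line_starts <- c(line_starts, d)
      triggers <- c(triggers, "switch_60d")
      regimen <- mols
      line_start <- d
    } else {
      regimen <- union(regimen, mols)
    }
    prev_date <- d
  }
  list(n_lines = length(line_starts), starts = as.Date(line_starts),
       triggers = triggers)
}

# Random drug-claim sequences over the critical day offsets for the line
# builder properties.
critical_offsets <- c(0, 14, 28, 45, 46, 59, 60, 61, 119, 120, 121)

random_drug_claims <- function(base = as.Date("2014-01-01"), max_claims = 5) {
  n <- sample.int(max_claims, 1)
  gaps <- sample(critical_offsets, n, replace = TRUE)
  days <- cumsum(c(0, gaps[-1]))
  tibble::tibble(
    patient_id = "X", service_date = base + days, category = "drug",
    code = sample(c("paclitaxel", "gemcitabine"), n, replace = TRUE),
    setting = "outpatient", cost_brl_nominal = 10, admission_days = 0L)
}

# Random mixed-category claim tables for cost-conservation properties.
random_cost_claims <- function(n = 30) {
  cats <- sample(c("diagnosis", "drug", "procedure", "outpatient_visit",
                   "er_visit", "inpatient_admission", "surgery",
                   "radiotherapy"), n, replace = TRUE)
  tibble::tibble(
    patient_id = "X",
    service_date = as.Date("2014-01-01") + sample(0:200, n, replace = TRUE),
    category = cats,
    code = ifelse(cats == "drug", "paclitaxel", "P1"),
    setting = ifelse(cats %in% c("inpatient_admission", "surgery"),
                     "inpatient", "outpatient"),
    cost_brl_nominal = round(stats::runif(n, 0, 5000), 2),
    admission_days = ifelse(cats == "inpatient_admission",
                            sample(1:10, n, replace = TRUE), 0L))
}
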