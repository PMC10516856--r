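mk_claim <- function(id, date, category, code, setting = "outpatient") {
  tibble::tibble(patient_id = id, service_date = as.Date(date),
                 category = category, code = code, setting = setting,
                 cost_brl_nominal = 0, admission_days = 0L)
}
mk_demo <- function(id, age = 48L) {
  tibble::tibble(patient_id = id, age_at_first_claim = age, region = "Southeast")
}

test_that("a patient meeting every rule is eligible with the first C50 as index date", {
  claims <- dplyr::bind_rows(
    mk_claim("P1", "2013-04-01", "diagnosis", "C50.9"),
    mk_claim("P1", "2013-04-20", "drug", "docetaxel"))
  res <- select_cohort(claims, mk_demo("P1"))
  expect_true(res$eligible)
  expect_equal(res$exclusion_reasons, "")
  expect_equal(res$index_date, as.Date("2013-04-01"))
})

test_that("hormone/targeted therapy at any time excludes the patient", {
  fx <- make_fixture("hormone_user")
  res <- select_cohort(fx$claims, fx$demographics)
  expect_false(res$eligible)
  expect_equal(res$exclusion_reasons, "exclusion_molecule")
})

test_that("any C50 or treatment claim in the 2011 washout year excludes the patient", {
  fx <- make_fixture("pre2012")
  res <- select_cohort(fx$claims, fx$demographics)
  expect_false(res$eligible)
  expect_equal(res$exclusion_reasons, "activity_in_2011")
  # a 2011 drug claim triggers the same rule
  claims <- dplyr::bind_rows(
    mk_claim("P2", "2011-07-01", "drug", "doxorubicin"),
    mk_claim("P2", "2013-04-01", "diagnosis", "C50.9"),
    mk_claim("P2", "2013-04-20", "drug", "docetaxel"))
  expect_equal(select_cohort(claims, mk_demo("P2"))$exclusion_reasons,
               "activity_in_2011")
})

test_that("age, diagnosis and treatment rules are enforced and reasons accumulate", {
  claims <- mk_claim("P3", "2013-04-01", "diagnosis", "C44.0")
  res <- select_cohort(claims, mk_demo("P3", age = 17L))
  expect_false(res$eligible)
  expect_setequal(strsplit(res$exclusion_reasons, ";")[[1]],
                  c("no_c50_in_window", "no_inclusion_molecule", "under_18"))
  expect_true(is.na(res$index_date))
})

test_that("missing age retains the patient with a flag", {
  claims <- dplyr::bind_rows(
    mk_claim("P4", "2013-04-01", "diagnosis", "C50.9"),
    mk_claim("P4", "2013-04-20", "drug", "docetaxel"))
  res <- select_cohort(claims, demographics = NULL)
  expect_true(res$eligible)
  expect_true(res$age_missing)
})

test_that("eligibility is invariant to the order claims are presented", {
  sim <- simulate_claims(simulation_config(
    n_patients = 40, seed = 8,
    contaminant_fractions = c(screening_only = 0.15, hormone_therapy_user = 0.15,
                              pre2012_activity = 0.15)))
  ref <- select_cohort(sim$claims, sim$demographics)
  set.seed(1)
  shuffled <- sim$claims[sample.int(nrow(sim$claims)), ]
  res <- select_cohort(shuffled, sim$demographics)
  expect_equal(dplyr::arrange(res, patient_id), dplyr::arrange(ref, patient_id))
})

test_that("planted contaminants are rejected for exactly their planted reason", {
  sim <- simulate_claims(simulation_config(
    n_patients = 200, seed = 41,
    contaminant_fractions = c(screening_only = 0.2, hormone_therapy_user = 0.2,
                              pre2012_activity = 0.2)))
  res <- select_cohort(sim$claims, sim$demographics)
  truth <- sim$truth$patients
  merged <- dplyr::left_join(res, truth, by = "patient_id")
  reason_of <- c(screening_only = "no_inclusion_molecule",
                 hormone_therapy_user = "exclusion_molecule",
                 pre2012_activity = "activity_in_2011")
  expect_true(all(merged$eligible[!merged$is_contaminant]))
  for (kind in names(reason_of)) {
    planted <- merged[merged$contaminant_kind == kind, ]
    expect_gt(nrow(planted), 0)
    expect_false(any(planted$eligible))
    expect_true(all(planted$exclusion_reasons == reason_of[[kind]]))
  }
  # rejected fraction per reason equals the planted fraction exactly
  for (kind in names(reason_of)) {
    expect_equal(sum(res$exclusion_reasons == reason_of[[kind]]),
                 sum(truth$contaminant_kind == kind))
  }
})

test_that("contaminant-free cohorts pass selection in full; screening-only cohorts fail in full", {
  clean <- simulate_claims(simulation_config(n_patients = 50, seed = 2))
  expect_true(all(select_cohort(clean$claims, clean$demographics)$eligible))
  screen <- simulate_claims(simulation_config(
    n_patients = 30, seed = 2,
    contaminant_fractions = c(screening_only = 1, hormone_therapy_user = 0,
                              pre2012_activity = 0)))
  expect_false(any(select_cohort(screen$claims, screen$demographics)$eligible))
})

test_that("empty input yields an empty eligibility table", {
  sim0 <- simulate_claims(simulation_config(n_patients = 0, seed = 1))
  expect_equal(nrow(select_cohort(sim0$claims, sim0$demographics)), 0)
})

test_that("surgery subcohort keeps early surgical patients and flags metastatic surgery", {
  claims <- dplyr::bind_rows(
    mk_claim("E1", "2013-05-01", "surgery", "S1", "inpatient"),
    mk_claim("E2", "2013-05-01", "drug", "paclitaxel"),
    mk_claim("M1", "2013-05-01", "surgery", "S1", "inpatient"),
    mk_claim("M2", "2013-05-01", "drug", "paclitaxel"))
  stages <- tibble::tibble(
    patient_id = c("E1", "E2", "M1", "M2"),
    stage = c("early_locally_advanced", "early_locally_advanced",
              "metastatic", "metastatic"))
  sub <- surgery_subcohort(claims, stages)
  expect_equal(sub$early_surgery$patient_id, "E1")
  expect_equal(sub$metastatic$patient_id[sub$metastatic$has_surgery], "M1")
  expect_equal(nrow(sub$metastatic), 2)
})
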