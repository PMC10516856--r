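#' Apply cohort eligibility rules and assign index dates
#'
#' A patient is eligible when all of the following hold: age at least 18;
#' at least one C50-prefixed diagnosis claim inside the enrolment window; at
#' least one drug claim for an inclusion molecule; no drug claim for an
#' exclusion molecule (hormone or targeted therapy) at any time; and no C50
#' diagnosis claim nor inclusion/exclusion-molecule drug claim dated in the
#' washout year 2011 (which removes prevalent cases with ongoing treatment).
#' Every failed rule is listed, so exclusion reasons are exhaustive and do
#' not depend on the order claims are stored.
#'
#' The index date of an eligible patient is the date of their first C50
#' diagnosis claim. Patients with missing age are retained and flagged
#' (`age_missing`), mirroring a claims source where demographics are
#' incomplete.
#'
#' @param claims A claims tibble (see [read_claims()]).
#' @param demographics A demographics tibble; patients absent from it are
#'   treated as having missing age.
#' @param catalog A [molecule_catalog()].
#' @param window Two dates bounding enrolment; default 2012-01-01 to
#'   2017-12-31.
#' @param washout_year Calendar year scanned for pre-existing disease or
#'   treatment activity.
#' @return A tibble with one row per patient: `patient_id`, `eligible`,
#'   `exclusion_reasons` (`";"`-joined, empty when eligible), `index_date`
#'   (`NA` when ineligible) and `age_missing`.
#' @examples
#' fx <- make_fixture("hormone_user")
#' select_cohort(fx$claims, fx$demographics)
#' @export
select_cohort <- function(claims, demographics = NULL,
                          catalog = molecule_catalog(),
                          window = as.Date(c("2012-01-01", "2017-12-31")),
                          washout_year = 2011L) {
  if (nrow(claims) == 0) {
    return(tibble::tibble(patient_id = character(0), eligible = logical(0),
                          exclusion_reasons = character(0),
                          index_date = as.Date(character(0)),
                          age_missing = logical(0)))
  }
  window <- as.Date(window)
  claims <- dplyr::mutate(
    claims,
    norm_code = normalize_icd10(.data$code),
    molecule = ifelse(.data$category == "drug", normalize_molecule(.data$code), NA),
    is_c50 = .data$category == "diagnosis" & startsWith(.data$norm_code, "C50"),
    is_inclusion = .data$category == "drug" &
      .data$molecule %in% catalog$inclusion_molecules,
    is_exclusion = .data$category == "drug" &
      .data$molecule %in% catalog$exclusion_molecules,
    in_window = .data$service_date >= window[1] & .data$service_date <= window[2],
    in_washout = as.integer(format(.data$service_date, "%Y")) == washout_year)

  per_patient <- dplyr::summarise(
    dplyr::group_by(claims, .data$patient_id),
    has_c50_in_window = any(.data$is_c50 & .data$in_window),
    has_inclusion = any(.data$is_inclusion),
    has_exclusion = any(.data$is_exclusion),
    activity_2011 = any(.data$in_washout &
                          (.data$is_c50 | .data$is_inclusion | .data$is_exclusion)),
    first_c50 = if (any(.data$is_c50 & .data$in_window)) {
      min(.data$service_date[.data$is_c50 & .data$in_window])
    } else {
      as.Date(NA)
    },
    .groups = "drop")

  if (!is.null(demographics)) {
    per_patient <- dplyr::left_join(
      per_patient,
      dplyr::select(tibble::as_tibble(demographics), "patient_id",
                    "age_at_first_claim"),
      by = "patient_id")
  } else {
    per_patient$age_at_first_claim <- NA_integer_
  }

  append_reason <- function(cur, cond, tag) {
    ifelse(cond, ifelse(nzchar(cur), paste(cur, tag, sep = ";"), tag), cur)
  }
  r <- character(nrow(per_patient))
  r <- append_reason(r, !per_patient$has_c50_in_window, "no_c50_in_window")
  r <- append_reason(r, !per_patient$has_inclusion, "no_inclusion_molecule")
  r <- append_reason(r, !is.na(per_patient$age_at_first_claim) &
                       per_patient$age_at_first_claim < 18, "under_18")
  r <- append_reason(r, per_patient$has_exclusion, "exclusion_molecule")
  r <- append_reason(r, per_patient$activity_2011, "activity_in_2011")
  eligible <- !nzchar(r)
  tibble::tibble(
    patient_id = per_patient$patient_id,
    eligible = eligible,
    exclusion_reasons = r,
    index_date = dplyr::if_else(eligible, per_patient$first_c50, as.Date(NA)),
    age_missing = is.na(per_patient$age_at_first_claim))
}

#' Carve the surgery subcohort
#'
#' The utilization and cost analyses of early / locally advanced patients
#' are restricted to those with a breast-surgery claim, since the surgery
#' date anchors the neoadjuvant/adjuvant split. Metastatic patients are
#' returned separately with a surgery flag (and their surgery date), which
#' feeds the share of surgical metastatic patients who received chemotherapy
#' before surgery.
#'
#' @param claims A claims tibble restricted to eligible patients.
#' @param stages A tibble with `patient_id` and `stage` (output of
#'   [classify_cohort_stage()]).
#' @return A list with `early_surgery` (tibble of early patients with
#'   surgery: `patient_id`, `surgery_date` = first surgery claim) and
#'   `metastatic` (tibble of all metastatic patients: `patient_id`,
#'   `has_surgery`, `surgery_date`).
#' @export
surgery_subcohort <- function(claims, stages) {
  surg <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(claims, .data$category == "surgery"),
                    .data$patient_id),
    surgery_date = min(.data$service_date), .groups = "drop")
  stages <- dplyr::left_join(tibble::as_tibble(stages), surg, by = "patient_id")
  list(
    early_surgery = dplyr::select(
      dplyr::filter(stages, .data$stage == "early_locally_advanced",
                    !is.na(.data$surgery_date)),
      "patient_id", "surgery_date"),
    metastatic = dplyr::mutate(
      dplyr::select(dplyr::filter(stages, .data$stage == "metastatic"),
                    "patient_id", "surgery_date"),
      has_surgery = !is.na(.data$surgery_date)))
}
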