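#' Infer disease stage at index from claim patterns
#'
#' A patient is classified as metastatic when at least two qualifying claims
#' fall inside the staging window around the index date and some pair of
#' them is at least 15 days apart; otherwise the patient is early / locally
#' advanced. Qualifying claims are diagnosis claims whose ICD-10 code is
#' metastatic ([is_metastatic_code()]; C76--C80 except C77.3 by default) and
#' claims whose code is in the catalog's metastatic-management set — the two
#' kinds pool, so one metastatic ICD code plus one metastatic-management
#' procedure suffices. The same code on two dates also suffices; the rule is
#' about repeated evidence, not code diversity.
#'
#' The staging window is one month before to six months after the index
#' date, realised as 30 and 183 days (6 x 30.4375, rounded), both endpoints
#' inclusive.
#'
#' @param claims Claims of one patient (tibble).
#' @param index_date The patient's index date (first C50 claim).
#' @param catalog A [molecule_catalog()].
#' @param window_before,window_after Days before/after index bounding the
#'   staging window.
#' @param min_separation_days Minimum calendar-day separation between two
#'   qualifying claims.
#' @return A list with `stage` (`"metastatic"` or
#'   `"early_locally_advanced"`) and `evidence` (tibble of qualifying
#'   claims: `service_date`, `code`).
#' @examples
#' fx <- make_fixture("met_two_c78")
#' classify_stage(fx$claims, as.Date("2013-03-01"))$stage
#' @export
classify_stage <- function(claims, index_date, catalog = molecule_catalog(),
                           window_before = 30L, window_after = 183L,
                           min_separation_days = 15L) {
  if (length(index_date) != 1 || is.na(index_date)) {
    stop("classify_stage requires a non-missing index date", call. = FALSE)
  }
  index_date <- as.Date(index_date)
  qualifies <- ((claims$category == "diagnosis" &
                   is_metastatic_code(claims$code, catalog)) |
                  claims$code %in% catalog$metastatic_management_codes) &
    claims$service_date >= index_date - window_before &
    claims$service_date <= index_date + window_after
  evidence <- claims[qualifies, c("service_date", "code"), drop = FALSE]
  evidence <- evidence[order(evidence$service_date), , drop = FALSE]
  met <- nrow(evidence) >= 2 &&
    as.numeric(max(evidence$service_date) - min(evidence$service_date)) >=
      min_separation_days
  list(stage = if (met) "metastatic" else "early_locally_advanced",
       evidence = if (met) evidence else evidence[0, ])
}

#' Stage every eligible patient in a cohort
#'
#' Applies [classify_stage()] per patient using the index dates from
#' [select_cohort()].
#'
#' @param claims A claims tibble.
#' @param eligibility Output of [select_cohort()]; only eligible rows are
#'   staged.
#' @inheritParams classify_stage
#' @return A tibble: `patient_id`, `stage`, `n_evidence_claims`.
#' @export
classify_cohort_stage <- function(claims, eligibility,
                                  catalog = molecule_catalog(),
                                  window_before = 30L, window_after = 183L,
                                  min_separation_days = 15L) {
  elig <- dplyr::filter(tibble::as_tibble(eligibility), .data$eligible)
  by_patient <- split(claims, claims$patient_id)
  rows <- lapply(seq_len(nrow(elig)), function(i) {
    pid <- elig$patient_id[i]
    res <- classify_stage(by_patient[[pid]] %||% claims[0, ],
                          elig$index_date[i], catalog,
                          window_before, window_after, min_separation_days)
    tibble::tibble(patient_id = pid, stage = res$stage,
                   n_evidence_claims = nrow(res$evidence))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(patient_id = character(0), stage = character(0),
                          n_evidence_claims = integer(0)))
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
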