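#' @importFrom rlang .data
NULL

#' Claim categories and care settings
#'
#' Claims carry one of eight categories. `diagnosis` rows hold an ICD-10
#' code; `drug` rows hold a molecule name; all other categories hold a
#' procedure code (possibly empty for visits). `setting` is the care setting
#' the claim was billed under.
#'
#' @name claim-vocab
#' @keywords internal
NULL

claim_categories <- function() {
  c("diagnosis", "drug", "procedure", "outpatient_visit", "er_visit",
    "inpatient_admission", "surgery", "radiotherapy")
}

claim_settings <- function() c("inpatient", "outpatient")

claims_columns <- function() {
  c("patient_id", "service_date", "category", "code", "setting",
    "cost_brl_nominal", "admission_days")
}

#' Validate a claims table
#'
#' Checks the structural invariants every downstream stage assumes: known
#' categories and settings, parseable dates, non-negative costs,
#' non-negative admission days that are zero outside `inpatient_admission`
#' rows, and non-empty molecule names on drug rows. Rows violating a rule
#' are reported with their row numbers.
#'
#' @param claims A data frame with the columns of the claims CSV.
#' @return The validated claims tibble, typed and sorted by patient and
#'   service date.
#' @export
validate_claims <- function(claims) {
  claims <- tibble::as_tibble(claims)
  missing <- setdiff(claims_columns(), names(claims))
  if (length(missing) > 0) {
    stop("claims table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  claims$patient_id <- as.character(claims$patient_id)
  claims$service_date <- as.Date(claims$service_date)
  claims$category <- as.character(claims$category)
  claims$code <- ifelse(is.na(claims$code), "", as.character(claims$code))
  claims$setting <- as.character(claims$setting)
  claims$cost_brl_nominal <- as.numeric(claims$cost_brl_nominal)
  claims$admission_days <- as.integer(claims$admission_days)

  problems <- character(0)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      shown <- utils::head(rows, 10)
      problems <<- c(problems, sprintf(
        "%s (row%s %s%s)", what, if (length(rows) > 1) "s" else "",
        paste(shown, collapse = ", "),
        if (length(rows) > length(shown)) ", ..." else ""))
    }
  }
  bad(is.na(claims$service_date), "unparseable service_date")
  bad(!claims$category %in% claim_categories(), "unknown claim category")
  bad(!claims$setting %in% claim_settings(), "unknown care setting")
  bad(is.na(claims$cost_brl_nominal) | claims$cost_brl_nominal < 0,
      "negative or missing cost_brl_nominal")
  bad(is.na(claims$admission_days) | claims$admission_days < 0,
      "negative or missing admission_days")
  bad(!is.na(claims$admission_days) & claims$admission_days > 0 &
        claims$category != "inpatient_admission",
      "admission_days > 0 outside inpatient_admission")
  bad(claims$category == "drug" & !nzchar(trimws(claims$code)),
      "drug claim with empty molecule name")
  if (length(problems) > 0) {
    stop("invalid claims table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  dplyr::arrange(claims, .data$patient_id, .data$service_date)
}

#' Read a claims CSV
#'
#' Reads a claims table in the package's interchange format (one row per
#' dated, costed service event), validates it with [validate_claims()], and
#' returns claims sorted by patient and service date. A `schema` mapping
#' allows reading files whose columns are named differently.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (`patient_id`, `service_date`, `category`, `code`, `setting`,
#'   `cost_brl_nominal`, `admission_days`) to the column names used in the
#'   file.
#' @return A claims tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_claims(make_fixture("met_two_c78")$claims, path)
#' read_claims(path)
#' @export
read_claims <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    present <- intersect(unname(schema), names(raw))
    if (length(present) < length(schema)) {
      stop("schema maps to column(s) absent from file: ",
           paste(setdiff(unname(schema), names(raw)), collapse = ", "),
           call. = FALSE)
    }
    raw <- dplyr::rename(raw, !!!stats::setNames(unname(schema), names(schema)))
  }
  validate_claims(raw)
}

#' Write a claims CSV
#'
#' Inverse of [read_claims()]: `read_claims(write_claims(x))` reproduces `x`
#' exactly (dates ISO-8601, costs at full stored precision, codes verbatim
#' including non-ASCII molecule names).
#'
#' @param claims A claims tibble (validated or validatable).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  if (nrow(claims) > 0) claims <- validate_claims(claims)
  claims <- tibble::as_tibble(claims)[, claims_columns(), drop = FALSE]
  readr::write_csv(claims, path)
  invisible(path)
}

#' Read / write a demographics CSV
#'
#' Demographics carry one row per patient: `patient_id`,
#' `age_at_first_claim` (integer years, may be missing), and `region` (one
#' of the five Brazilian macro-regions or `"unknown"`).
#'
#' @param path CSV path.
#' @return A demographics tibble.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) stop("demographics file not found: ", path, call. = FALSE)
  demo <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    age_at_first_claim = readr::col_integer(),
    region = readr::col_character()))
  missing <- setdiff(c("patient_id", "age_at_first_claim", "region"), names(demo))
  if (length(missing) > 0) {
    stop("demographics table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  demo
}

#' @rdname read_demographics
#' @param demographics A demographics tibble.
#' @export
write_demographics <- function(demographics, path) {
  readr::write_csv(tibble::as_tibble(demographics), path)
  invisible(path)
}
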