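#' Canned single-patient fixtures with documented expected labels
#'
#' Tiny hand-specified patient sets exercising one rule each, used in the
#' test-suite and in examples. Each fixture returns the claims and
#' demographics tables plus an `expected` list stating the downstream label
#' the rules should produce.
#'
#' Available scenarios:
#' \describe{
#'   \item{`switch_day70`}{AC cycles on days 0/21/42, paclitaxel on day 70:
#'     two lines, the second opened by the 60-day switch rule.}
#'   \item{`gap_130`}{paclitaxel on day 0 and day 130: two lines, the second
#'     opened by the 120-day gap rule.}
#'   \item{`sequential_27d`}{AC ending day 63, paclitaxel starting day 90
#'     (27-day treatment-free gap): follow-on tagged sequential.}
#'   \item{`met_two_c78`}{C78 diagnosis claims at index+10 and index+40:
#'     classified metastatic.}
#'   \item{`c773_only`}{two C77.3 claims 30 days apart and nothing else
#'     metastatic: classified early (C77.3 is excluded).}
#'   \item{`hormone_user`}{an otherwise eligible patient with a tamoxifen
#'     claim: rejected for an exclusion molecule.}
#'   \item{`pre2012`}{an otherwise eligible patient with a C50 claim in
#'     2011: rejected by the washout rule.}
#' }
#'
#' @param name Scenario name.
#' @return A list with `claims`, `demographics` and `expected`.
#' @examples
#' fx <- make_fixture("gap_130")
#' fx$expected
#' @export
make_fixture <- function(name) {
  base <- as.Date("2013-03-01")
  demo <- function(id) tibble::tibble(patient_id = id, age_at_first_claim = 48L,
                                      region = "Southeast")
  drug <- function(id, day, mol) {
    claim_row(id, base + day, "drug", mol, "outpatient", 100)
  }
  diag <- function(id, day, code) claim_row(id, base + day, "diagnosis", code)

  fx <- switch(
    name,
    switch_day70 = list(
      claims = dplyr::bind_rows(
        diag("F01", 0, "C50.9"),
        drug("F01", 0, "doxorubicin"), drug("F01", 0, "cyclophosphamide"),
        drug("F01", 21, "doxorubicin"), drug("F01", 21, "cyclophosphamide"),
        drug("F01", 42, "doxorubicin"), drug("F01", 42, "cyclophosphamide"),
        drug("F01", 70, "paclitaxel")),
      demographics = demo("F01"),
      expected = list(n_lines = 2, trigger = "switch_60d",
                      line2_start = base + 70)),
    gap_130 = list(
      claims = dplyr::bind_rows(
        diag("F02", 0, "C50.9"),
        drug("F02", 0, "paclitaxel"), drug("F02", 130, "paclitaxel")),
      demographics = demo("F02"),
      expected = list(n_lines = 2, trigger = "gap_120d",
                      line2_start = base + 130)),
    sequential_27d = list(
      claims = dplyr::bind_rows(
        diag("F03", 0, "C50.9"),
        drug("F03", 0, "doxorubicin"), drug("F03", 0, "cyclophosphamide"),
        drug("F03", 21, "doxorubicin"), drug("F03", 21, "cyclophosphamide"),
        drug("F03", 42, "doxorubicin"), drug("F03", 42, "cyclophosphamide"),
        drug("F03", 63, "doxorubicin"), drug("F03", 63, "cyclophosphamide"),
        drug("F03", 90, "paclitaxel"), drug("F03", 111, "paclitaxel")),
      demographics = demo("F03"),
      expected = list(n_lines = 2, gap_days = 27, tag = "sequential")),
    met_two_c78 = list(
      claims = dplyr::bind_rows(
        diag("F04", 0, "C50.9"),
        diag("F04", 10, "C78.0"), diag("F04", 40, "C78.0"),
        drug("F04", 14, "paclitaxel")),
      demographics = demo("F04"),
      expected = list(stage = "metastatic")),
    c773_only = list(
      claims = dplyr::bind_rows(
        diag("F05", 0, "C50.9"),
        diag("F05", 10, "C77.3"), diag("F05", 40, "C773"),
        drug("F05", 14, "paclitaxel")),
      demographics = demo("F05"),
      expected = list(stage = "early_locally_advanced")),
    hormone_user = list(
      claims = dplyr::bind_rows(
        diag("F06", 0, "C50.9"),
        drug("F06", 14, "paclitaxel"),
        drug("F06", 60, "tamoxifen")),
      demographics = demo("F06"),
      expected = list(eligible = FALSE, reason = "exclusion_molecule")),
    pre2012 = list(
      claims = dplyr::bind_rows(
        claim_row("F07", as.Date("2011-06-01"), "diagnosis", "C50.9"),
        diag("F07", 0, "C50.9"),
        drug("F07", 14, "doxorubicin")),
      demographics = demo("F07"),
      expected = list(eligible = FALSE, reason = "activity_in_2011")),
    stop("unknown fixture scenario: ", name, call. = FALSE))
  fx$claims <- validate_claims(fx$claims)
  fx
}
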