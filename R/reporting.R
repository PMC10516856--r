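#' Round half-up
#'
#' Report tables round half-up (2.5 -> 3) rather than using banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param decimals Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, decimals = 0) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share
#'
#' `100 * numerator / denominator`, rounded half-up. Shares are stored as
#' numerator/denominator pairs throughout the flow report and rendered with
#' this function, so a printed percentage always recomputes exactly from
#' its counts.
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param decimals Decimal places of the rendered percentage.
#' @return Percentage.
#' @examples
#' share(2488, 3004, 1)
#' @export
share <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(numerator < 0 | numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Relative excess of one amount over another
#'
#' `100 * (a - b) / b`, rounded half-up: how much larger `a` is than `b`,
#' in percent.
#'
#' @param a,b Positive reals; `b` is the reference.
#' @param decimals Decimal places.
#' @return Percentage.
#' @examples
#' relative_excess(10005.95, 7351.72, 0)
#' @export
relative_excess <- function(a, b, decimals = 0) {
  if (any(b <= 0)) stop("reference amount must be positive", call. = FALSE)
  round_half_up(100 * (a - b) / b, decimals)
}

#' First-regimen frequency table by stratum
#'
#' Counts patients by the regimen label of a chosen line within each
#' stratum and renders shares that sum to 100% up to rounding. Empty strata
#' are omitted with a message.
#'
#' @param lines Cohort lines, with a `stratum` column attached (e.g. stage,
#'   setting or LOT index).
#' @param line_index Which line to tabulate (default 1, the first regimen).
#' @param decimals Decimal places for the share.
#' @return A tibble: `stratum`, `regimen_label`, `n`, `pct`.
#' @export
regimen_frequency_table <- function(lines, line_index = 1L, decimals = 1) {
  lines <- dplyr::filter(tibble::as_tibble(lines),
                         .data$line_index == !!line_index)
  if (nrow(lines) == 0) {
    message("no lines at index ", line_index, "; empty frequency table")
    return(tibble::tibble(stratum = character(0), regimen_label = character(0),
                          n = integer(0), pct = numeric(0)))
  }
  if (!"stratum" %in% names(lines)) lines$stratum <- "all"
  counts <- dplyr::count(lines, .data$stratum, .data$regimen_label, name = "n")
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$stratum),
    pct = share(.data$n, sum(.data$n), decimals))
  dplyr::arrange(dplyr::ungroup(counts), .data$stratum, dplyr::desc(.data$n))
}

#' Cohort flow report
#'
#' Collects the counts at each selection and classification step together
#' with the derived percentages, each stored as a numerator/denominator
#' pair so percentages always recompute exactly.
#'
#' @param eligibility Output of [select_cohort()].
#' @param stages Output of [classify_cohort_stage()].
#' @param subcohort Output of [surgery_subcohort()].
#' @param settings Optional tibble `patient_id`, `setting` for the early
#'   surgical subcohort.
#' @return A `cohort_flow` list of steps; each step holds `n`,
#'   `denominator` and `pct`.
#' @export
cohort_flow <- function(eligibility, stages, subcohort, settings = NULL) {
  step <- function(n, den) list(n = n, denominator = den,
                                pct = if (den > 0) share(n, den, 1) else NA_real_)
  screened <- nrow(eligibility)
  eligible <- sum(eligibility$eligible)
  early <- sum(stages$stage == "early_locally_advanced")
  met <- sum(stages$stage == "metastatic")
  flow <- list(
    screened = step(screened, screened),
    eligible = step(eligible, screened),
    early_locally_advanced = step(early, eligible),
    metastatic = step(met, eligible),
    early_surgery_subcohort = step(nrow(subcohort$early_surgery), early),
    metastatic_with_surgery = step(sum(subcohort$metastatic$has_surgery), met))
  if (!is.null(settings) && nrow(settings) > 0) {
    den <- nrow(settings)
    for (s in c("AT_only", "NAT_only", "NAT_AT")) {
      flow[[paste0("setting_", s)]] <- step(sum(settings$setting == s), den)
    }
  }
  structure(flow, class = "cohort_flow")
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("<cohort_flow>\n")
  for (name in names(x)) {
    cat(sprintf("  %-26s %6d / %6d  (%s%%)\n", name, x[[name]]$n,
                x[[name]]$denominator,
                formatC(x[[name]]$pct, format = "fg")))
  }
  invisible(x)
}

#' Run the full claims-analysis pipeline
#'
#' Orchestrates the stages end-to-end: cohort selection, staging, surgery
#' subcohort, line-of-therapy construction, treatment-setting
#' classification and sequential/progression tagging for early surgical
#' patients, transition counts, per-patient treatment-period metrics and
#' the stage-level PPPM tables, plus the cohort-flow report. Given
#' identical inputs and options the result is identical.
#'
#' @param claims Claims tibble (or path to a claims CSV).
#' @param demographics Demographics tibble (or path to a CSV).
#' @param catalog A [molecule_catalog()].
#' @param window Enrolment window.
#' @param conv A [month_convention()].
#' @param params A [currency_parameters()].
#' @param outdir Optional directory; when given, all result tables are
#'   written there as CSV (flow report as JSON) together with a run
#'   manifest recording every threshold.
#' @return A list: `eligibility`, `stages`, `subcohort`, `lines` (with
#'   per-line `setting_tag` and sequential/progression `tag`), `settings`,
#'   `transitions`, `period_metrics`, `pppm` (per-stage tables), `flow`.
#' @examples
#' sim <- simulate_claims(simulation_config(n_patients = 40, seed = 7))
#' res <- run_pipeline(sim$claims, sim$demographics)
#' res$flow
#' @export
run_pipeline <- function(claims, demographics = NULL,
                         catalog = molecule_catalog(),
                         window = as.Date(c("2012-01-01", "2017-12-31")),
                         conv = month_convention(),
                         params = currency_parameters(),
                         outdir = NULL) {
  if (is.character(claims)) claims <- read_claims(claims)
  if (is.character(demographics)) demographics <- read_demographics(demographics)

  eligibility <- select_cohort(claims, demographics, catalog, window)
  eligible_ids <- eligibility$patient_id[eligibility$eligible]
  cohort_claims <- dplyr::filter(claims, .data$patient_id %in% eligible_ids)
  stages <- classify_cohort_stage(cohort_claims, eligibility, catalog)
  subcohort <- surgery_subcohort(cohort_claims, stages)
  lines <- build_cohort_lines(cohort_claims, catalog = catalog)

  # setting + sequential/progression tags for the early surgical subcohort
  settings <- NULL
  lines$setting_tag <- NA_character_
  lines$tag <- NA_character_
  es <- subcohort$early_surgery
  if (nrow(es) > 0) {
    srows <- lapply(seq_len(nrow(es)), function(i) {
      pid <- es$patient_id[i]
      pl <- lines[lines$patient_id == pid, , drop = FALSE]
      cls <- classify_setting(pl, es$surgery_date[i])
      tagged <- tag_sequential_or_progression(pl)
      lines$setting_tag[lines$patient_id == pid] <<- cls$line_setting
      lines$tag[lines$patient_id == pid] <<- tagged$tag
      tibble::tibble(patient_id = pid, setting = cls$setting,
                     progression = attr(tagged, "progression_flag"))
    })
    settings <- dplyr::bind_rows(srows)
    settings <- dplyr::filter(settings, .data$setting != "none")
  }
  met <- subcohort$metastatic
  lines$setting_tag[lines$patient_id %in% met$patient_id] <-
    paste0("LOT", lines$line_index[lines$patient_id %in% met$patient_id])
  if (any(met$has_surgery)) {
    for (i in which(met$has_surgery)) {
      pid <- met$patient_id[i]
      pre <- lines$patient_id == pid & lines$start_date < met$surgery_date[i]
      lines$setting_tag[pre] <- "NAT"
    }
  }

  transitions <- transition_matrix(lines)
  period_metrics <- patient_period_metrics(cohort_claims, lines, conv, params)
  period_metrics <- dplyr::left_join(period_metrics,
                                     dplyr::select(stages, "patient_id", "stage"),
                                     by = "patient_id")
  pppm <- list()
  hcru_ids <- c(subcohort$early_surgery$patient_id, met$patient_id)
  for (st in unique(stats::na.omit(period_metrics$stage))) {
    stratum <- dplyr::filter(period_metrics, .data$stage == st,
                             .data$patient_id %in% hcru_ids)
    if (nrow(stratum) >= 2) pppm[[st]] <- cohort_pppm_table(stratum)
  }
  flow <- cohort_flow(eligibility, stages, subcohort, settings)

  result <- list(eligibility = eligibility, stages = stages,
                 subcohort = subcohort, lines = lines, settings = settings,
                 transitions = transitions, period_metrics = period_metrics,
                 pppm = pppm, flow = flow)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir, conv, params)
  result
}

write_pipeline_outputs <- function(result, outdir, conv, params) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$eligibility, file.path(outdir, "eligibility.csv"))
  readr::write_csv(result$stages, file.path(outdir, "stages.csv"))
  readr::write_csv(result$lines, file.path(outdir, "lines.csv"))
  readr::write_csv(result$transitions, file.path(outdir, "transitions.csv"))
  readr::write_csv(result$period_metrics, file.path(outdir, "period_metrics.csv"))
  if (!is.null(result$settings)) {
    readr::write_csv(result$settings, file.path(outdir, "settings.csv"))
  }
  for (st in names(result$pppm)) {
    readr::write_csv(result$pppm[[st]],
                     file.path(outdir, paste0("pppm_", st, ".csv")))
  }
  jsonlite::write_json(unclass(result$flow), file.path(outdir, "flow.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    thresholds = list(staging_window_before_days = 30,
                      staging_window_after_days = 183,
                      staging_min_separation_days = 15,
                      regimen_grouping_window_days = 28,
                      switch_days = 60, gap_days = 120,
                      sequential_window_days = 45,
                      exposure_floor_months = 0.25),
    days_per_month = conv$days_per_month,
    inflation_factor = params$inflation_factor,
    brl_to_usd = params$brl_to_usd,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
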