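#' Build lines of therapy from one patient's drug claims
#'
#' Groups dated drug claims into treatment lines using switch and gap rules.
#' Line 1 starts at the first drug claim. Molecules claimed within the
#' grouping window of a line's start form its initial regimen, and a new
#' molecule appearing before the switch threshold extends the regimen
#' (an early addition is a regimen modification, not a switch). A new line
#' opens when either
#' \itemize{
#'   \item any drug claim falls `gap_days` (default 120) or more after the
#'     previous drug claim (`gap_120d` trigger) — checked first, or
#'   \item a molecule not in the current regimen is claimed `switch_days`
#'     (default 60) or more after the current line's start (`switch_60d`
#'     trigger).
#' }
#' The switch clock runs from the current line's start date. Each line ends
#' at its last claim before the next line opens (or the last claim overall).
#' Claims on the same day are processed together, so a same-day combination
#' start never splits across lines.
#'
#' @param drug_claims Drug claims of a single patient (tibble with
#'   `service_date` and molecule names in `code`); other categories are
#'   ignored.
#' @param grouping_window Days from line start within which molecules form
#'   the initial regimen.
#' @param switch_days Switch threshold in days from line start.
#' @param gap_days Treatment-free gap (days between consecutive drug
#'   claims) that forces a new line regardless of molecule.
#' @param catalog A [molecule_catalog()] used for regimen labels.
#' @return A tibble of lines: `line_index`, `molecules` (sorted,
#'   `"+"`-joined), `regimen_label`, `start_date`, `end_date`,
#'   `start_trigger` (`initiation`, `switch_60d` or `gap_120d`) and
#'   `n_claims`.
#' @examples
#' fx <- make_fixture("switch_day70")
#' build_lines(dplyr::filter(fx$claims, category == "drug"))
#' @export
build_lines <- function(drug_claims, grouping_window = 28L, switch_days = 60L,
                        gap_days = 120L, catalog = molecule_catalog()) {
  drugs <- dplyr::filter(tibble::as_tibble(drug_claims), .data$category == "drug")
  if (nrow(drugs) == 0) {
    return(tibble::tibble(line_index = integer(0), molecules = character(0),
                          regimen_label = character(0),
                          start_date = as.Date(character(0)),
                          end_date = as.Date(character(0)),
                          start_trigger = character(0), n_claims = integer(0)))
  }
  if (length(unique(drugs$patient_id)) > 1) {
    stop("build_lines expects claims of a single patient", call. = FALSE)
  }
  drugs <- dplyr::arrange(drugs, .data$service_date)
  drugs$molecule <- normalize_molecule(drugs$code)
  days <- split(drugs$molecule, drugs$service_date)
  dates <- as.Date(names(days))

  lines <- list()
  open_line <- function(date, molecules, trigger) {
    lines[[length(lines) + 1]] <<- list(
      start = date, end = date, molecules = unique(molecules),
      trigger = trigger, n_claims = length(molecules))
  }
  open_line(dates[1], days[[1]], "initiation")
  for (k in seq_along(dates)[-1]) {
    d <- dates[k]
    mols <- days[[k]]
    cur <- lines[[length(lines)]]
    if (as.numeric(d - cur$end) >= gap_days) {
      open_line(d, mols, "gap_120d")
    } else if (as.numeric(d - cur$start) >= switch_days &&
               !all(mols %in% cur$molecules)) {
      open_line(d, mols, "switch_60d")
    } else {
      cur$molecules <- unique(c(cur$molecules, mols))
      cur$end <- d
      cur$n_claims <- cur$n_claims + length(mols)
      lines[[length(lines)]] <- cur
    }
  }
  tibble::tibble(
    line_index = seq_along(lines),
    molecules = vapply(lines, function(l) paste(sort(l$molecules), collapse = "+"), ""),
    regimen_label = vapply(lines, function(l) regimen_label(l$molecules, catalog), ""),
    start_date = as.Date(vapply(lines, function(l) as.character(l$start), "")),
    end_date = as.Date(vapply(lines, function(l) as.character(l$end), "")),
    start_trigger = vapply(lines, function(l) l$trigger, ""),
    n_claims = vapply(lines, function(l) l$n_claims, integer(1)))
}

#' Build lines of therapy for a whole cohort
#'
#' Applies [build_lines()] per patient to the inclusion-molecule drug claims
#' of eligible patients.
#'
#' @param claims A claims tibble.
#' @param patient_ids Patients to process (default: all in `claims`).
#' @inheritParams build_lines
#' @return A tibble of lines with a leading `patient_id` column.
#' @export
build_cohort_lines <- function(claims, patient_ids = NULL,
                               grouping_window = 28L, switch_days = 60L,
                               gap_days = 120L, catalog = molecule_catalog()) {
  drugs <- dplyr::filter(
    claims, .data$category == "drug",
    normalize_molecule(.data$code) %in% catalog$inclusion_molecules)
  if (!is.null(patient_ids)) {
    drugs <- dplyr::filter(drugs, .data$patient_id %in% patient_ids)
  }
  if (nrow(drugs) == 0) {
    return(tibble::tibble(patient_id = character(0), line_index = integer(0),
                          molecules = character(0), regimen_label = character(0),
                          start_date = as.Date(character(0)),
                          end_date = as.Date(character(0)),
                          start_trigger = character(0), n_claims = integer(0)))
  }
  parts <- lapply(split(drugs, drugs$patient_id), function(d) {
    out <- build_lines(d, grouping_window, switch_days, gap_days, catalog)
    out$patient_id <- d$patient_id[1]
    out
  })
  dplyr::relocate(dplyr::bind_rows(parts), "patient_id")
}

#' Classify the treatment setting of an early-stage surgical patient
#'
#' Splits a patient's treatment lines around the surgery date: lines
#' starting strictly before surgery are neoadjuvant (NAT), lines starting on
#' or after it are adjuvant (AT).
#'
#' @param lines Lines of one patient ([build_lines()] output).
#' @param surgery_date The patient's first breast-surgery claim date;
#'   required (patients without surgery are outside this subcohort).
#' @return A list with `setting` (`"NAT_only"`, `"AT_only"`, `"NAT_AT"` or
#'   `"none"` when the patient has no lines) and `line_setting` (per-line
#'   `"NAT"`/`"AT"` vector).
#' @export
classify_setting <- function(lines, surgery_date) {
  if (length(surgery_date) != 1 || is.na(surgery_date)) {
    stop("classify_setting requires a surgery date", call. = FALSE)
  }
  surgery_date <- as.Date(surgery_date)
  if (nrow(lines) == 0) {
    return(list(setting = "none", line_setting = character(0)))
  }
  line_setting <- ifelse(lines$start_date < surgery_date, "NAT", "AT")
  setting <- if (all(line_setting == "NAT")) "NAT_only"
  else if (all(line_setting == "AT")) "AT_only"
  else "NAT_AT"
  list(setting = setting, line_setting = line_setting)
}

#' Tag follow-on regimens as sequential or progressive disease
#'
#' For early / locally advanced patients, a regimen starting within 45 days
#' of the previous regimen's end (last claim) is planned sequential
#' chemotherapy; a regimen starting after a longer treatment-free gap is
#' read as treatment for progressive disease.
#'
#' @param lines Lines of one patient, in order.
#' @param sequential_window Maximum treatment-free gap in days for the
#'   sequential label.
#' @return `lines` with added columns `gap_days` (`NA` for the first line)
#'   and `tag` (`NA`, `"sequential"` or `"progressive_disease"`), plus an
#'   attribute `progression_flag`.
#' @examples
#' fx <- make_fixture("sequential_27d")
#' tag_sequential_or_progression(build_lines(fx$claims))
#' @export
tag_sequential_or_progression <- function(lines, sequential_window = 45L) {
  lines <- dplyr::arrange(tibble::as_tibble(lines), .data$start_date)
  n <- nrow(lines)
  gap <- rep(NA_real_, n)
  tag <- rep(NA_character_, n)
  if (n > 1) {
    gap[-1] <- as.numeric(lines$start_date[-1] - lines$end_date[-n])
    tag[-1] <- ifelse(gap[-1] <= sequential_window, "sequential",
                      "progressive_disease")
  }
  lines$gap_days <- gap
  lines$tag <- tag
  attr(lines, "progression_flag") <- any(tag == "progressive_disease", na.rm = TRUE)
  lines
}

#' Count regimen-to-regimen transitions across a cohort
#'
#' Every pair of adjacent lines of a patient contributes one transition
#' count; the edge list feeds a Sankey-style treatment-pattern diagram.
#'
#' @param lines Cohort-level lines ([build_cohort_lines()] output).
#' @return A tibble `from`, `to`, `n`, sorted by decreasing `n`.
#' @export
transition_matrix <- function(lines) {
  lines <- dplyr::arrange(tibble::as_tibble(lines), .data$patient_id,
                          .data$line_index)
  pairs <- dplyr::mutate(
    dplyr::group_by(lines, .data$patient_id),
    from = dplyr::lag(.data$regimen_label))
  pairs <- dplyr::filter(dplyr::ungroup(pairs), !is.na(.data$from))
  if (nrow(pairs) == 0) {
    return(tibble::tibble(from = character(0), to = character(0), n = integer(0)))
  }
  dplyr::arrange(
    dplyr::count(pairs, .data$from, to = .data$regimen_label, name = "n"),
    dplyr::desc(.data$n))
}
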