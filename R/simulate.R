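#' Configuration for the synthetic claims generator
#'
#' Builds the parameter set driving [simulate_claims()]. Defaults encode the
#' cohort structure of a Brazilian private-sector triple-negative breast
#' cancer population: 82.8% of patients early / locally advanced, breast
#' surgery in 41.6% (early) and 37.4% (metastatic) of patients, adjuvant
#' therapy dominating the surgical early cohort, 21-day chemotherapy cycles,
#' and per-patient-per-month event rates and gamma-distributed nominal BRL
#' costs of the magnitude seen in that population.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed. Each patient draws from an independent
#'   sub-stream derived from the seed and the patient index, so adding or
#'   removing patients never perturbs the claims of others.
#' @param stage_mix Probability that a patient is early / locally advanced
#'   (the remainder are metastatic).
#' @param surgery_prob_early,surgery_prob_met Probability of a breast
#'   surgery claim by stage.
#' @param setting_mix_early Named probabilities (`AT_only`, `NAT_only`,
#'   `NAT_AT`) of the treatment setting among early patients with surgery.
#' @param nat_prob_met_surgery Probability that a metastatic patient with
#'   surgery received chemotherapy before it (neoadjuvant).
#' @param seq_prob_at,seq_prob_nat_at Probability of a sequential follow-on
#'   regimen for early patients treated in AT or NAT/AT.
#' @param progression_prob_early Probability that an early patient receives
#'   a later regimen after a treatment-free gap exceeding the 45-day
#'   sequential window (progressive disease).
#' @param line_continue_probs_met Probabilities of advancing LOT1 to LOT2
#'   and LOT2 to LOT3 for metastatic patients.
#' @param regimen_menu Per-context regimen menus: lists of
#'   `list(molecules =, prob =)` entries; probabilities must sum to 1
#'   within each menu.
#' @param cycle_interval_days Days between chemotherapy cycles.
#' @param cycles_per_regimen Integer vector of possible cycle counts per
#'   regimen (sampled uniformly).
#' @param event_rates_pppm Per-stage named vectors of mean events per
#'   patient-month for `er_visit`, `outpatient_visit`, `procedure`,
#'   `inpatient_admission`. Events are drawn only over treatment-duration
#'   months, mirroring the analysis's exposure restriction.
#' @param cost_distributions Per-category `c(shape =, scale =)` gamma
#'   parameters for nominal BRL claim costs.
#' @param los_mean_days Per-stage mean additional hospital days per
#'   admission (length of stay is `1 + Poisson(mean)`).
#' @param radiotherapy_prob Probability of a radiotherapy claim.
#' @param contaminant_fractions Named probabilities (`screening_only`,
#'   `hormone_therapy_user`, `pre2012_activity`) that a patient is generated
#'   as a contaminant violating exactly that eligibility rule.
#' @param study_window Two dates bounding the enrolment window.
#' @param days_per_month Month convention used when converting treatment
#'   spans to exposure months.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 300,
                              seed = 1L,
                              stage_mix = 0.828,
                              surgery_prob_early = 0.416,
                              surgery_prob_met = 0.374,
                              setting_mix_early = c(AT_only = 0.753, NAT_only = 0.075, NAT_AT = 0.171),
                              nat_prob_met_surgery = 0.399,
                              seq_prob_at = 0.573,
                              seq_prob_nat_at = 0.13,
                              progression_prob_early = 0.044,
                              line_continue_probs_met = c(0.484, 0.126),
                              regimen_menu = default_regimen_menu(),
                              cycle_interval_days = 21L,
                              cycles_per_regimen = 4:6,
                              event_rates_pppm = list(
                                early = c(er_visit = 0.25, outpatient_visit = 0.37,
                                          procedure = 23.15, inpatient_admission = 0.23),
                                metastatic = c(er_visit = 0.60, outpatient_visit = 0.66,
                                               procedure = 34.60, inpatient_admission = 0.38)),
                              cost_distributions = list(
                                procedure = c(shape = 2, scale = 400),
                                er_visit = c(shape = 2, scale = 250),
                                outpatient_visit = c(shape = 2, scale = 150),
                                inpatient_admission = c(shape = 1.5, scale = 12500),
                                surgery = c(shape = 2, scale = 4000),
                                drug = c(shape = 2, scale = 750),
                                radiotherapy = c(shape = 2, scale = 1000)),
                              los_mean_days = c(early = 2.6, metastatic = 6.6),
                              radiotherapy_prob = 0.059,
                              contaminant_fractions = c(screening_only = 0,
                                                        hormone_therapy_user = 0,
                                                        pre2012_activity = 0),
                              study_window = as.Date(c("2012-01-01", "2017-12-31")),
                              days_per_month = 30.4375) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    stage_mix = stage_mix, surgery_prob_early = surgery_prob_early,
    surgery_prob_met = surgery_prob_met,
    setting_mix_early = setting_mix_early,
    nat_prob_met_surgery = nat_prob_met_surgery,
    seq_prob_at = seq_prob_at, seq_prob_nat_at = seq_prob_nat_at,
    progression_prob_early = progression_prob_early,
    line_continue_probs_met = line_continue_probs_met,
    regimen_menu = regimen_menu,
    cycle_interval_days = as.integer(cycle_interval_days),
    cycles_per_regimen = as.integer(cycles_per_regimen),
    event_rates_pppm = event_rates_pppm,
    cost_distributions = cost_distributions,
    los_mean_days = los_mean_days,
    radiotherapy_prob = radiotherapy_prob,
    contaminant_fractions = contaminant_fractions,
    study_window = as.Date(study_window),
    days_per_month = days_per_month)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  probs <- c(cfg$stage_mix, cfg$surgery_prob_early, cfg$surgery_prob_met,
             cfg$setting_mix_early, cfg$nat_prob_met_surgery, cfg$seq_prob_at,
             cfg$seq_prob_nat_at, cfg$progression_prob_early,
             cfg$line_continue_probs_met, cfg$radiotherapy_prob,
             cfg$contaminant_fractions)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("simulation config: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(cfg$contaminant_fractions) > 1) {
    stop("simulation config: contaminant fractions sum to more than 1", call. = FALSE)
  }
  if (abs(sum(cfg$setting_mix_early) - 1) > 0.01) {
    stop("simulation config: setting_mix_early must sum to 1", call. = FALSE)
  }
  for (name in names(cfg$regimen_menu)) {
    p <- vapply(cfg$regimen_menu[[name]], function(e) e$prob, numeric(1))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("simulation config: regimen menu '", name,
           "' probabilities must be non-negative and sum to 1", call. = FALSE)
    }
  }
  rates <- unlist(cfg$event_rates_pppm)
  gam <- unlist(cfg$cost_distributions)
  if (any(rates <= 0) || any(gam <= 0)) {
    stop("simulation config: event rates and gamma parameters must be positive",
         call. = FALSE)
  }
  if (cfg$n_patients < 0) stop("simulation config: n_patients must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Default regimen menus by stage and line
#'
#' Menus approximate the prescription mix of the target population:
#' anthracycline-based combinations (AC) dominating early disease,
#' bevacizumab plus paclitaxel prominent in first-line metastatic therapy,
#' taxane then gemcitabine/capecitabine regimens in later lines.
#'
#' @return A named list of menus; each menu is a list of
#'   `list(molecules =, prob =)` entries.
#' @export
default_regimen_menu <- function() {
  m <- function(mol, p) list(molecules = mol, prob = p)
  list(
    early = list(
      m(c("doxorubicin", "cyclophosphamide"), 0.50),
      m(c("docetaxel", "cyclophosphamide"), 0.18),
      m("doxorubicin", 0.12),
      m("paclitaxel", 0.12),
      m("docetaxel", 0.08)),
    early_followon = list(
      m("paclitaxel", 0.60),
      m("docetaxel", 0.25),
      m(c("doxorubicin", "cyclophosphamide"), 0.15)),
    met_lot1 = list(
      m(c("bevacizumab", "paclitaxel"), 0.216),
      m(c("doxorubicin", "cyclophosphamide"), 0.30),
      m("paclitaxel", 0.18),
      m("gemcitabine", 0.17),
      m("capecitabine", 0.134)),
    met_lot2 = list(
      m("paclitaxel", 0.344),
      m("gemcitabine", 0.124),
      m(c("gemcitabine", "cisplatin"), 0.06),
      m("capecitabine", 0.25),
      m(c("doxorubicin", "cyclophosphamide"), 0.222)),
    met_lot3 = list(
      m("capecitabine", 0.215),
      m("gemcitabine", 0.154),
      m("paclitaxel", 0.40),
      m("carboplatin", 0.231)))
}

# Independent per-patient RNG sub-streams: the global seed drives one RNG
# from which each patient's own seed is drawn, so patient i's claims depend
# only on (seed, i) and never on how many other patients are generated.
patient_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n, replace = TRUE)
}

draw_menu <- function(menu, exclude = character(0)) {
  if (length(exclude) > 0) {
    keep <- vapply(menu, function(e) length(intersect(e$molecules, exclude)) == 0,
                   logical(1))
    if (any(keep)) menu <- menu[keep]
  }
  p <- vapply(menu, function(e) e$prob, numeric(1))
  menu[[sample.int(length(menu), 1, prob = p)]]$molecules
}

#' Simulate an oncology claims cohort with ground truth
#'
#' Generates a longitudinal claims table, a demographics table and the
#' per-patient ground truth (true stage, planted treatment lines, treatment
#' setting, contaminant status) under a [simulation_config()]. Every
#' non-contaminant patient carries at least one C50 diagnosis claim inside
#' the study window and at least one inclusion-molecule drug claim; every
#' metastatic patient carries two metastatic-code claims at least 15 days
#' apart inside the staging window; drug claims fall on cycle dates; visit,
#' ER, procedure and admission events are drawn month-by-month at the
#' configured Poisson rates over treatment-duration months only, with
#' gamma-distributed nominal BRL costs. Contaminants violate exactly the
#' eligibility rule their kind names.
#'
#' The generation is deterministic given the seed, patient by patient.
#'
#' @param config A [simulation_config()].
#' @param catalog A [molecule_catalog()] (supplies the hormone molecule used
#'   by `hormone_therapy_user` contaminants).
#' @return A list with elements `claims` (claims tibble), `demographics`
#'   (demographics tibble) and `truth` (list of `patients` and `lines`
#'   tibbles).
#' @examples
#' sim <- simulate_claims(simulation_config(n_patients = 20, seed = 42))
#' dplyr::count(sim$truth$patients, true_stage)
#' @export
simulate_claims <- function(config = simulation_config(),
                            catalog = molecule_catalog()) {
  validate_simulation_config(config)
  out_claims <- vector("list", config$n_patients)
  out_demo <- vector("list", config$n_patients)
  out_truth <- vector("list", config$n_patients)
  out_lines <- vector("list", config$n_patients)
  seeds <- patient_seeds(config$seed, config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(seeds[i])
    p <- simulate_patient(sprintf("P%05d", i), config, catalog)
    out_claims[[i]] <- p$claims
    out_demo[[i]] <- p$demographics
    out_truth[[i]] <- p$truth
    out_lines[[i]] <- p$lines
  }
  claims <- if (config$n_patients > 0) {
    validate_claims(dplyr::bind_rows(out_claims))
  } else {
    empty_claims()
  }
  list(claims = claims,
       demographics = dplyr::bind_rows(out_demo),
       truth = list(patients = dplyr::bind_rows(out_truth),
                    lines = dplyr::bind_rows(out_lines)))
}

empty_claims <- function() {
  tibble::tibble(patient_id = character(0),
                 service_date = as.Date(character(0)),
                 category = character(0), code = character(0),
                 setting = character(0), cost_brl_nominal = numeric(0),
                 admission_days = integer(0))
}

# Fast vectorized claim-row constructor (recycles scalars over `date`).
claim_row <- function(patient_id, date, category, code = "",
                      setting = "outpatient", cost = 0, days = 0L) {
  date <- as.Date(date)
  n <- length(date)
  structure(list(patient_id = rep_len(patient_id, n), service_date = date,
                 category = rep_len(category, n), code = rep_len(code, n),
                 setting = rep_len(setting, n),
                 cost_brl_nominal = rep_len(as.numeric(cost), n),
                 admission_days = rep_len(as.integer(days), n)),
            class = "data.frame", row.names = c(NA_integer_, -n))
}

draw_cost <- function(category, config) {
  g <- config$cost_distributions[[category]]
  if (is.null(g)) return(0)
  stats::rgamma(1, shape = g[["shape"]], scale = g[["scale"]])
}

# One chemotherapy regimen: every molecule claimed on each 21-day cycle date.
regimen_claims <- function(patient_id, molecules, start, n_cycles, config) {
  cycle_dates <- start + (seq_len(n_cycles) - 1) * config$cycle_interval_days
  dates <- rep(cycle_dates, each = length(molecules))
  mols <- rep(molecules, times = n_cycles)
  g <- config$cost_distributions$drug
  costs <- stats::rgamma(length(dates), shape = g[["shape"]], scale = g[["scale"]])
  claim_row(patient_id, dates, "drug", mols, "outpatient", costs)
}

# Utilization events over one treatment line, drawn at the configured PPPM
# rates over the line's exposure months (0.25-month floor for one-day lines).
event_claims <- function(patient_id, start, end, stage, config) {
  months <- max(as.numeric(end - start) / config$days_per_month, 0.25)
  rates <- config$event_rates_pppm[[if (stage == "metastatic") "metastatic" else "early"]]
  los <- config$los_mean_days[[if (stage == "metastatic") "metastatic" else "early"]]
  span <- as.integer(end - start)
  rows <- list()
  for (cat in names(rates)) {
    n <- stats::rpois(1, rates[[cat]] * months)
    if (n == 0) next
    dates <- start + sample.int(span + 1, n, replace = TRUE) - 1
    setting <- if (cat == "inpatient_admission") "inpatient" else "outpatient"
    days <- if (cat == "inpatient_admission") 1L + stats::rpois(n, los) else 0L
    costs <- stats::rgamma(n, shape = config$cost_distributions[[cat]][["shape"]],
                           scale = config$cost_distributions[[cat]][["scale"]])
    rows[[cat]] <- claim_row(patient_id, dates, cat, "", setting, costs, days)
  }
  dplyr::bind_rows(rows)
}

truth_line <- function(patient_id, idx, molecules, start, end,
                       setting_tag = NA_character_) {
  tibble::tibble(patient_id = patient_id, line_index = idx,
                 molecules = paste(sort(molecules), collapse = "+"),
                 start_date = as.Date(start), end_date = as.Date(end),
                 setting_tag = setting_tag)
}

simulate_patient <- function(patient_id, config, catalog) {
  kind_probs <- config$contaminant_fractions
  u <- stats::runif(1)
  kind <- "none"
  cum <- 0
  for (k in names(kind_probs)) {
    cum <- cum + kind_probs[[k]]
    if (u < cum) { kind <- k; break }
  }

  window <- config$study_window
  # leave room after the index date so planted lines stay inside follow-up
  latest_index <- window[2] - 700
  index_date <- window[1] + floor(stats::runif(1) * as.numeric(latest_index - window[1]))
  stage <- if (stats::runif(1) < config$stage_mix) "early_locally_advanced" else "metastatic"

  age <- max(18L, as.integer(round(stats::rnorm(1, 49, 12))))
  region <- sample(c("Southeast", "South", "Northeast", "Central-West", "North", "unknown"),
                   1, prob = c(0.685, 0.10, 0.09, 0.05, 0.035, 0.04))
  demo <- tibble::tibble(patient_id = patient_id, age_at_first_claim = age,
                         region = region)

  claims <- list(claim_row(patient_id, index_date, "diagnosis", "C50.9"))
  lines <- list()
  surgery_date <- as.Date(NA)
  true_setting <- "none"

  if (kind == "screening_only") {
    # a screening work-up: C50 diagnosis plus a visit, never any drug claim
    claims[[length(claims) + 1]] <-
      claim_row(patient_id, index_date + 7, "outpatient_visit", "",
                "outpatient", draw_cost("outpatient_visit", config))
    truth <- tibble::tibble(
      patient_id = patient_id, true_stage = stage, true_setting = "none",
      index_date = index_date, surgery_date = as.Date(NA),
      is_contaminant = TRUE, contaminant_kind = kind)
    return(list(claims = dplyr::bind_rows(claims), demographics = demo,
                truth = truth, lines = NULL))
  }

  add_line <- function(molecules, start, setting_tag = NA_character_) {
    n_cycles <- sample(config$cycles_per_regimen, 1)
    end <- start + (n_cycles - 1) * config$cycle_interval_days
    claims[[length(claims) + 1]] <<-
      regimen_claims(patient_id, molecules, start, n_cycles, config)
    claims[[length(claims) + 1]] <<-
      event_claims(patient_id, start, end, stage, config)
    lines[[length(lines) + 1]] <<-
      truth_line(patient_id, length(lines) + 1, molecules, start, end, setting_tag)
    list(molecules = molecules, start = start, end = end)
  }
  add_surgery <- function(date) {
    surgery_date <<- as.Date(date)
    claims[[length(claims) + 1]] <<-
      claim_row(patient_id, date, "surgery", "SURG01", "inpatient",
                draw_cost("surgery", config))
  }

  if (stage == "early_locally_advanced") {
    has_surgery <- stats::runif(1) < config$surgery_prob_early
    if (has_surgery) {
      setting <- sample(names(config$setting_mix_early), 1,
                        prob = config$setting_mix_early)
      if (setting == "AT_only") {
        add_surgery(index_date + sample(14:28, 1))
        at <- add_line(draw_menu(config$regimen_menu$early),
                       surgery_date + sample(35:49, 1), "AT")
        if (stats::runif(1) < config$seq_prob_at) {
          add_line(draw_menu(config$regimen_menu$early_followon, at$molecules),
                   at$end + sample(14:44, 1), "AT")
        } else if (stats::runif(1) < config$progression_prob_early) {
          add_line(draw_menu(config$regimen_menu$early_followon, at$molecules),
                   at$end + sample(60:110, 1), "AT")
        }
        true_setting <- "AT_only"
      } else if (setting == "NAT_only") {
        nat <- add_line(draw_menu(config$regimen_menu$early),
                        index_date + sample(3:21, 1), "NAT")
        add_surgery(nat$end + sample(7:21, 1))
        true_setting <- "NAT_only"
      } else {
        nat <- add_line(draw_menu(config$regimen_menu$early),
                        index_date + sample(3:21, 1), "NAT")
        add_surgery(nat$end + sample(7:14, 1))
        gap_left <- 45 - as.integer(surgery_date - nat$end)
        at <- add_line(draw_menu(config$regimen_menu$early_followon, nat$molecules),
                       surgery_date + sample(seq(21, max(21, gap_left)), 1), "AT")
        if (stats::runif(1) < config$seq_prob_nat_at) {
          add_line(draw_menu(config$regimen_menu$early_followon,
                             c(nat$molecules, at$molecules)),
                   at$end + sample(14:44, 1), "AT")
        }
        true_setting <- "NAT_AT"
      }
    } else {
      add_line(draw_menu(config$regimen_menu$early), index_date + sample(7:28, 1))
    }
  } else {
    # metastatic: plant the staging evidence inside [-30, +183] around index
    ev1 <- index_date + sample(0:60, 1)
    ev2 <- ev1 + sample(15:60, 1)
    claims[[length(claims) + 1]] <- claim_row(patient_id, ev1, "diagnosis", "C78.0")
    claims[[length(claims) + 1]] <- claim_row(patient_id, ev2, "diagnosis", "C79.5")
    has_surgery <- stats::runif(1) < config$surgery_prob_met
    lot_start <- index_date + sample(14:90, 1)
    if (has_surgery) {
      if (stats::runif(1) < config$nat_prob_met_surgery) {
        nat <- add_line(draw_menu(config$regimen_menu$met_lot1),
                        index_date + sample(3:21, 1), "NAT")
        add_surgery(nat$end + sample(7:21, 1))
        lot_start <- surgery_date + sample(130:180, 1)
        true_setting <- "NAT"
      } else {
        add_surgery(index_date + sample(7:28, 1))
        lot_start <- surgery_date + sample(14:60, 1)
      }
    }
    prev <- add_line(draw_menu(config$regimen_menu$met_lot1,
                               if (true_setting == "NAT") lines[[1]]$molecules else character(0)),
                     lot_start, "LOT")
    continue <- config$line_continue_probs_met
    for (step in seq_along(continue)) {
      if (stats::runif(1) >= continue[step]) break
      menu <- config$regimen_menu[[c("met_lot2", "met_lot3")[step]]]
      gap <- if (stats::runif(1) < 0.7) sample(14:45, 1) else sample(121:180, 1)
      prev <- add_line(draw_menu(menu, prev$molecules), prev$end + gap, "LOT")
    }
  }

  if (stats::runif(1) < config$radiotherapy_prob) {
    claims[[length(claims) + 1]] <-
      claim_row(patient_id, index_date + sample(30:200, 1), "radiotherapy",
                "RT001", "outpatient", draw_cost("radiotherapy", config))
  }

  if (kind == "hormone_therapy_user") {
    hormone <- catalog$exclusion_molecules[1]
    claims[[length(claims) + 1]] <-
      claim_row(patient_id, index_date + sample(30:120, 1), "drug", hormone,
                "outpatient", draw_cost("drug", config))
  } else if (kind == "pre2012_activity") {
    pre_date <- as.Date("2011-01-01") + sample(0:364, 1)
    claims[[length(claims) + 1]] <-
      claim_row(patient_id, pre_date, "diagnosis", "C50.1")
  }

  truth <- tibble::tibble(
    patient_id = patient_id, true_stage = stage, true_setting = true_setting,
    index_date = index_date, surgery_date = surgery_date,
    is_contaminant = kind != "none", contaminant_kind = kind)
  list(claims = dplyr::bind_rows(claims), demographics = demo, truth = truth,
       lines = if (length(lines) > 0) dplyr::bind_rows(lines) else NULL)
}

#' Write a simulated cohort to disk
#'
#' Writes the claims, demographics and ground-truth tables of a
#' [simulate_claims()] result as CSV files under a directory.
#'
#' @param sim Result of [simulate_claims()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_claims(sim$claims, file.path(dir, "claims.csv"))
  write_demographics(sim$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(sim$truth$patients, file.path(dir, "truth_patients.csv"))
  readr::write_csv(sim$truth$lines, file.path(dir, "truth_lines.csv"))
  invisible(dir)
}
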