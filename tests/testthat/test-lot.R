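drugs <- function(days, mols, base = as.Date("2014-01-01")) {
  tibble::tibble(patient_id = "X", service_date = base + days,
                 category = "drug", code = mols, setting = "outpatient",
                 cost_brl_nominal = 10, admission_days = 0L)
}

test_that("a different molecule 60+ days after line start opens a switch line", {
  fx <- make_fixture("switch_day70")
  lines <- build_lines(fx$claims)
  expect_equal(nrow(lines), fx$expected$n_lines)
  expect_equal(lines$start_trigger, c("initiation", "switch_60d"))
  expect_equal(lines$start_date[2], fx$expected$line2_start)
  expect_equal(lines$regimen_label[1], "AC")
  expect_equal(lines$end_date[1], fx$expected$line2_start - 28)
})

test_that("a 120+ day treatment-free gap opens a new line regardless of molecule", {
  fx <- make_fixture("gap_130")
  lines <- build_lines(fx$claims)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$start_trigger[2], "gap_120d")
  expect_equal(lines$start_date[2], fx$expected$line2_start)
})

test_that("molecules within the grouping window form one combination regimen", {
  lines <- build_lines(drugs(c(0, 14), c("doxorubicin", "cyclophosphamide")))
  expect_equal(nrow(lines), 1)
  expect_equal(lines$molecules, "cyclophosphamide+doxorubicin")
  expect_equal(lines$regimen_label, "AC")
})

test_that("a new molecule before the switch threshold extends the current regimen", {
  lines <- build_lines(drugs(c(0, 50), c("carboplatin", "gemcitabine")))
  expect_equal(nrow(lines), 1)
  expect_equal(lines$molecules, "carboplatin+gemcitabine")
})

test_that("an already-claimed molecule after 60 days continues the line", {
  lines <- build_lines(drugs(c(0, 21, 42, 63, 84), rep("paclitaxel", 5)))
  expect_equal(nrow(lines), 1)
  expect_equal(lines$end_date, as.Date("2014-01-01") + 84)
})

test_that("an empty drug-claim list yields no lines", {
  expect_equal(nrow(build_lines(drugs(numeric(0), character(0)))), 0)
})

test_that("line builder matches the step-by-step rule-replay oracle on critical offsets", {
  set.seed(515)
  for (k in 1:300) {
    claims <- random_drug_claims()
    got <- build_lines(claims)
    want <- oracle_lines(claims$service_date, claims$code)
    expect_equal(nrow(got), want$n_lines, label = paste("case", k))
    expect_equal(got$start_date, want$starts, label = paste("case", k))
    expect_equal(got$start_trigger, want$triggers, label = paste("case", k))
  }
})

test_that("lines partition the claims: starts increase, claim counts are conserved", {
  set.seed(616)
  for (k in 1:100) {
    claims <- random_drug_claims()
    lines <- build_lines(claims)
    expect_true(all(diff(as.numeric(lines$start_date)) > 0))
    expect_true(all(lines$start_date <= lines$end_date))
    expect_equal(sum(lines$n_claims), nrow(claims))
    # every claim lies inside exactly one line span
    for (d in claims$service_date) {
      expect_equal(sum(d >= lines$start_date & d <= lines$end_date), 1)
    }
  }
})

test_that("setting classification splits lines around the surgery date", {
  surgery <- as.Date("2014-01-01")
  nat_at <- dplyr::bind_rows(
    build_lines(drugs(c(-60, -39), rep("doxorubicin", 2), base = surgery)),
    build_lines(drugs(c(30, 51), rep("paclitaxel", 2), base = surgery)))
  expect_equal(classify_setting(nat_at, surgery)$setting, "NAT_AT")
  at <- build_lines(drugs(c(30, 51), rep("paclitaxel", 2), base = surgery))
  expect_equal(classify_setting(at, surgery)$setting, "AT_only")
  nat <- build_lines(drugs(c(-60, -39), rep("doxorubicin", 2), base = surgery))
  expect_equal(classify_setting(nat, surgery)$setting, "NAT_only")
  # a line starting on the surgery day is adjuvant
  on_day <- build_lines(drugs(0, "paclitaxel", base = surgery))
  expect_equal(classify_setting(on_day, surgery)$line_setting, "AT")
  expect_error(classify_setting(at, as.Date(NA)), "surgery date")
})

test_that("follow-on regimens split at the 45-day sequential window", {
  fx <- make_fixture("sequential_27d")
  tagged <- tag_sequential_or_progression(build_lines(fx$claims))
  expect_equal(tagged$gap_days[2], fx$expected$gap_days)
  expect_equal(tagged$tag[2], "sequential")
  expect_false(attr(tagged, "progression_flag"))

  late <- dplyr::bind_rows(
    drugs(c(0, 21, 42, 63), rep("doxorubicin", 4)),
    drugs(c(130, 151), rep("paclitaxel", 2)))
  tagged2 <- tag_sequential_or_progression(build_lines(late))
  expect_equal(tagged2$gap_days[2], 67)
  expect_equal(tagged2$tag[2], "progressive_disease")
  expect_true(attr(tagged2, "progression_flag"))

  single <- tag_sequential_or_progression(build_lines(drugs(0, "paclitaxel")))
  expect_true(all(is.na(single$tag)))
  expect_false(attr(single, "progression_flag"))
})

test_that("a 45-day gap is sequential and a 46-day gap is progression", {
  for (gap in c(45, 46)) {
    lines <- build_lines(dplyr::bind_rows(drugs(c(0, 21), rep("doxorubicin", 2)),
                                          drugs(21 + gap, "paclitaxel")))
    tagged <- tag_sequential_or_progression(lines)
    expect_equal(tagged$tag[2],
                 if (gap <= 45) "sequential" else "progressive_disease")
  }
})

test_that("transition counts tally adjacent regimen pairs and conserve totals", {
  lines <- dplyr::bind_rows(
    tibble::tibble(patient_id = "A", line_index = 1:2,
                   regimen_label = c("AC", "paclitaxel")),
    tibble::tibble(patient_id = "B", line_index = 1:2,
                   regimen_label = c("AC", "paclitaxel")),
    tibble::tibble(patient_id = "C", line_index = 1:2,
                   regimen_label = c("AC", "docetaxel")),
    tibble::tibble(patient_id = "D", line_index = 1L, regimen_label = "AC"))
  tm <- transition_matrix(lines)
  expect_equal(tm$n[tm$from == "AC" & tm$to == "paclitaxel"], 2L)
  expect_equal(tm$n[tm$from == "AC" & tm$to == "docetaxel"], 1L)
  n_lines_per_patient <- table(lines$patient_id)
  expect_equal(sum(tm$n), sum(n_lines_per_patient - 1))
  # single-regimen patients only: empty edge list
  expect_equal(nrow(transition_matrix(lines[lines$patient_id == "D", ])), 0)
})

test_that("recovered lines match the planted ground truth on a noise-free cohort", {
  sim <- simulate_claims(simulation_config(n_patients = 250, seed = 23))
  lines <- build_cohort_lines(sim$claims)
  truth <- sim$truth$lines
  ok <- 0
  ids <- unique(truth$patient_id)
  for (pid in ids) {
    got <- lines[lines$patient_id == pid, ]
    want <- truth[truth$patient_id == pid, ]
    if (nrow(got) == nrow(want) &&
        all(got$start_date == want$start_date) &&
        all(got$end_date == want$end_date) &&
        all(got$molecules == want$molecules)) {
      ok <- ok + 1
    }
  }
  expect_gte(ok / length(ids), 0.99)
})
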