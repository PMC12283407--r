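# Hand-constructed toy cohort exercising every emulation rule.
toy_cohort <- function() {
  patients <- data.frame(
    id = sprintf("T%02d", 1:10),
    diagnosis = rep(0, 10),
    age = c(50, 70, 60, 55, 66, 48, 72, 59, 63, 51),
    age_group = c("<65", ">=65", "<65", "<65", ">=65", "<65", ">=65",
                  "<65", "<65", "<65"),
    stage = "III", grade = 3,
    last_followup = c(800, 900, 300, 1000, 850, 900, 950, 1000, 1000, 900),
    death = c(500, NA, NA, NA, 600, NA, NA, 700, NA, NA),
    biomarker = rep(c("resistant", "sensitive"), 5),
    stringsAsFactors = FALSE)
  lines <- rbind(
    # T01: taxane at lines 2 and 4 -> line 2 selected
    data.frame(patient = "T01", drugs = "carboplatin", start = 10,
               end = 120, cycles = 6, line_number = 1),
    data.frame(patient = "T01", drugs = "paclitaxel", start = 150,
               end = 250, cycles = 4, line_number = 2),
    data.frame(patient = "T01", drugs = "paclitaxel", start = 300,
               end = 400, cycles = 4, line_number = 4),
    # T02: taxane with 2 cycles and 20 days -> fails exposure, but a
    # gemcitabine line qualifies for control
    data.frame(patient = "T02", drugs = "docetaxel", start = 20,
               end = 40, cycles = 2, line_number = 1),
    data.frame(patient = "T02", drugs = "gemcitabine", start = 100,
               end = 200, cycles = 4, line_number = 2),
    # T03: taxane with 2 cycles but 40 days -> passes exposure (OR rule)
    data.frame(patient = "T03", drugs = "paclitaxel", start = 15,
               end = 55, cycles = 2, line_number = 1),
    # T04: taxane AND gemcitabine lines -> experimental, removed from
    # control by the both-arms rule
    data.frame(patient = "T04", drugs = "paclitaxel", start = 10,
               end = 150, cycles = 6, line_number = 1),
    data.frame(patient = "T04", drugs = "gemcitabine", start = 200,
               end = 300, cycles = 4, line_number = 2),
    # T05-T08: control candidates across 6 monotherapies
    data.frame(patient = "T05", drugs = "gemcitabine", start = 10,
               end = 110, cycles = 4, line_number = 1),
    data.frame(patient = "T05", drugs = "topotecan", start = 200,
               end = 300, cycles = 4, line_number = 2),
    data.frame(patient = "T06", drugs = "cyclophosphamide", start = 10,
               end = 110, cycles = 4, line_number = 1),
    data.frame(patient = "T06", drugs = "vinorelbine", start = 200,
               end = 260, cycles = 3, line_number = 2),
    data.frame(patient = "T07", drugs = "doxorubicin", start = 10,
               end = 110, cycles = 4, line_number = 1),
    data.frame(patient = "T07", drugs = "etoposide", start = 200,
               end = 300, cycles = 4, line_number = 2),
    data.frame(patient = "T08", drugs = "gemcitabine", start = 10,
               end = 110, cycles = 4, line_number = 1),
    # T08 second gemcitabine line under-exposed: dropped by exposure rule
    data.frame(patient = "T08", drugs = "gemcitabine", start = 400,
               end = 410, cycles = 1, line_number = 2),
    # T09: long ongoing line (TTF 990 > 730) with only 200 days of
    # follow-up past its end -> excluded late
    data.frame(patient = "T09", drugs = "paclitaxel", start = 10,
               end = 800, cycles = 6, line_number = 1),
    # T10: combination line is not a monotherapy -> never in control
    data.frame(patient = "T10", drugs = "gemcitabine + cisplatin",
               start = 10, end = 110, cycles = 4, line_number = 1))
  lines$biopsy <- NA_real_
  list(patients = patients, lines = lines)
}

test_that("TTF uses next line, death, then censoring at follow-up", {
  tc <- toy_cohort()
  tt <- compute_ttf(tc$lines, tc$patients)
  # T01 line 1 fails at line 2 start: 150 - 10 = 140, uncensored
  expect_equal(tt$ttf[tt$patient == "T01" & tt$line_number == 1], 140)
  expect_false(tt$censored[tt$patient == "T01" & tt$line_number == 1])
  # T01 line 4 has no later line, death at 500: 500 - 300 = 200
  expect_equal(tt$ttf[tt$patient == "T01" & tt$line_number == 4], 200)
  # T03's only line: censored at follow-up 300 - 15 = 285
  i3 <- tt$patient == "T03"
  expect_equal(tt$ttf[i3], 285)
  expect_true(tt$censored[i3])
  # T09: censored at 1000 - 10 = 990 (the >730 trap)
  expect_equal(tt$ttf[tt$patient == "T09"], 990)

  bad <- data.frame(patient = "T01", drugs = "x", start = 5000, end = 5100,
                    cycles = 1, line_number = 9)
  expect_error(compute_ttf(bad, tc$patients), "negative TTF")
})

test_that("arm construction and finalisation match brute-force enumeration", {
  tc <- toy_cohort()
  ex <- assign_experimental(tc$lines, "taxane")
  # by hand: T01 (line 2), T03 (OR rule), T04, T09; T02 fails exposure
  expect_setequal(ex$patient, c("T01", "T03", "T04", "T09"))
  expect_equal(ex$line_number[ex$patient == "T01"], 2)

  ctl <- assign_control(tc$lines, "taxane", ex)
  # hand tally of monotherapy frequencies among non-taxane patients not in
  # the experimental arm: gemcitabine 3 lines (T02, T08 x2), then one line
  # each of cyclophosphamide, doxorubicin, etoposide, topotecan,
  # vinorelbine; lexicographic tie-break keeps cyclophosphamide,
  # doxorubicin, etoposide, topotecan and drops vinorelbine (n_top = 5)
  expect_setequal(attr(ctl, "soc"),
                  c("gemcitabine", "cyclophosphamide", "doxorubicin",
                    "etoposide", "topotecan"))
  # T04 removed by the both-arms rule; T08's 1-cycle/10-day line dropped
  expect_false("T04" %in% ctl$patient)
  expect_setequal(ctl$patient, c("T02", "T05", "T06", "T07", "T08"))
  expect_equal(sum(ctl$patient == "T08"), 1)
  # T06's vinorelbine line excluded with the 6th-ranked monotherapy
  expect_false("vinorelbine" %in% ctl$drugs)

  cohort <- finalize_cohort(ex, ctl, tc$patients, all_lines = tc$lines)
  # T05 has two viable control lines: first (gemcitabine, start 10) kept
  expect_equal(cohort$start[cohort$patient == "T05"], 10)
  # T09: 200 days follow-up past line end, last-line TTF 990 > 730 ->
  # excluded
  expect_false("T09" %in% cohort$patient)
  # surviving counts equal the brute-force expectation
  expect_setequal(cohort$patient[cohort$arm == "experimental"],
                  c("T01", "T03", "T04"))
  expect_setequal(cohort$patient[cohort$arm == "control"],
                  c("T02", "T05", "T06", "T07", "T08"))
  flow <- attr(cohort, "flow")
  expect_equal(unname(flow["patients_in_arms"]), 9)
  expect_equal(unname(flow["excluded_followup_rule"]), 1)
  expect_equal(unname(flow["analyzed"]), 8)

  expect_error(assign_control(tc$lines[tc$lines$patient == "T01", ],
                              "taxane", ex), "control arm empty")
})

test_that("arm construction is invariant to row order", {
  tc <- toy_cohort()
  set.seed(9)
  shuffled <- tc$lines[sample(nrow(tc$lines)), ]
  ex1 <- assign_experimental(tc$lines, "taxane")
  ex2 <- assign_experimental(shuffled, "taxane")
  expect_setequal(paste(ex1$patient, ex1$line_number),
                  paste(ex2$patient, ex2$line_number))
  ctl1 <- assign_control(tc$lines, "taxane", ex1)
  ctl2 <- assign_control(shuffled, "taxane", ex2)
  expect_setequal(paste(ctl1$patient, ctl1$line_number),
                  paste(ctl2$patient, ctl2$line_number))
})

test_that("stabilized IPW weights match hand computation", {
  cohort <- data.frame(
    arm = c(rep("experimental", 6), rep("control", 6)),
    year = c(rep("2010", 4), rep("2011", 2), rep("2010", 2), rep("2011", 4)),
    stringsAsFactors = FALSE)
  w <- ipw_weights(cohort)
  # marginal P(exp) = 0.5; 2010: P(exp|y) = 4/6; 2011: 2/6
  expect_equal(w[1], 0.5 / (4 / 6))
  expect_equal(w[5], 0.5 / (2 / 6))
  expect_equal(w[7], 0.5 / (2 / 6))
  expect_equal(w[12], 0.5 / (4 / 6))
  # stabilized weights average to about 1
  expect_equal(mean(w), 1, tolerance = 0.01)

  balanced <- data.frame(arm = rep(c("experimental", "control"), 4),
                         year = rep(c("2010", "2011"), each = 4))
  expect_equal(unique(ipw_weights(balanced)), 1)

  lonely <- data.frame(arm = c("control", "control", "experimental"),
                       year = c("2012", "2012", "2013"))
  expect_error(ipw_weights(lonely), "2012")
})

test_that("run_emulation estimates hazard ratios through the survival package", {
  sim <- simulate_cohort(n = 300, true_hr = 3, censor_rate = 0.2, seed = 11)
  ex <- assign_experimental(sim$lines, "taxane")
  ctl <- assign_control(sim$lines, "taxane", ex)
  cohort <- finalize_cohort(ex, ctl, sim$patients, all_lines = sim$lines)
  w <- ipw_weights(cohort)
  res <- run_emulation(cohort, design = "phase3_rct", strata = "age_group",
                       weights = w)
  hr_res <- res$fits$hr[res$fits$group == "resistant"]
  hr_sen <- res$fits$hr[res$fits$group == "sensitive"]
  expect_true(res$fits$lcl[res$fits$group == "resistant"] < 3 &
                res$fits$ucl[res$fits$group == "resistant"] > 3)
  expect_true(res$fits$lcl[res$fits$group == "sensitive"] < 1 &
                res$fits$ucl[res$fits$group == "sensitive"] > 1)
  expect_gt(hr_res, hr_sen)

  # phase 2 single-arm: resistant vs sensitive within the treated
  res2 <- run_emulation(cohort, design = "phase2_single_arm",
                        biomarker = "biomarker")
  expect_gt(res2$fits$hr, 1)

  single <- cohort[cohort$arm == "experimental", ]
  expect_error(run_emulation(single, design = "phase3_rct"), "both arms")
})

test_that("Schoenfeld events formula matches its closed form and scales", {
  # hr = 2, one-tailed alpha 0.05, power 0.8, balanced arms, all events
  out <- power_required_n(2, alpha = 0.05, power = 0.8, allocation = 0.5,
                          event_fraction = 1)
  expect_equal(out$events,
               ceiling(4 * (qnorm(0.95) + qnorm(0.8))^2 / log(2)^2))
  expect_equal(out$events, 52)
  # halving the event fraction doubles the required enrolment
  out2 <- power_required_n(2, event_fraction = 0.5)
  expect_equal(out2$n,
               ceiling(2 * 4 * (qnorm(0.95) + qnorm(0.8))^2 / log(2)^2))
  # (z sum)^2 proportionality: quadrupling the z-sum squared quadruples events
  z1 <- (qnorm(0.95) + qnorm(0.8))^2
  hr_easier <- exp(log(2) / 2)  # halves log hr -> 4x events
  out3 <- power_required_n(hr_easier)
  expect_equal(out3$events, ceiling(4 * z1 / log(2)^2 * 4 / 4 * 4) )
  expect_error(power_required_n(1), "undetectable")
})
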