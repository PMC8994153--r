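dc <- utc("2018-03-09 12:00:00")   # reference index discharge

test_that("complication detection matches a brute-force scan of E11 subcodes", {
  expect_false(detect_complications(dx_events("E11.9"), dc))
  expect_true(detect_complications(dx_events("E11.22"), dc))
  expect_false(detect_complications(dx_events("E11.9")[0, ], dc))
  # brute force: every E11.0-E11.9 subcode against the configured 2-8 range
  for (d in 0:9) {
    code <- sprintf("E11.%d1", d)
    expect_equal(detect_complications(dx_events(code), dc),
                 d %in% 2:8, info = code)
  }
  # post-discharge diagnoses never retroactively complicate
  late <- dx_events("E11.22", "2018-06-01 00:00:00")
  expect_false(detect_complications(late, dc))
})

test_that("CVD detection covers the MI / heart failure / angina triad only", {
  expect_true(detect_cvd(dx_events("I50.9"), dc))
  expect_false(detect_cvd(dx_events("I10"), dc))
  expect_true(detect_cvd(dx_events(c("I21.4", "E11.9")), dc))
  expect_true(detect_cvd(dx_events("I20.0"), dc))
  expect_false(detect_cvd(dx_events("I63.9"), dc))
})

test_that("individualized HbA1c targets follow the age-band x complication table", {
  expect_equal(assign_control_target(50, FALSE), 7.0)
  expect_equal(assign_control_target(64, TRUE), 8.0)
  expect_equal(assign_control_target(65, FALSE), 7.5)
  expect_equal(assign_control_target(80, TRUE), 8.5)
  # exhaustive: the four cells are the only attainable thresholds
  grid <- expand.grid(age = c(18:64, 65:95), comp = c(FALSE, TRUE))
  thr <- assign_control_target(grid$age, grid$comp)
  expect_setequal(unique(thr), c(7.0, 7.5, 8.0, 8.5))
  expect_true(all(thr[grid$age < 65 & !grid$comp] == 7.0))
  expect_true(all(thr[grid$age >= 65 & grid$comp] == 8.5))
  expect_error(assign_control_target(NA, FALSE), "missing age")
})

test_that("linkage requires a qualifying prescription inside the closed 90-day window", {
  day <- 86400
  expect_true(classify_linkage(med_events("metformin", dc + 90 * day), dc))
  expect_false(classify_linkage(med_events("insulin glargine", dc + 91 * day), dc))
  expect_true(classify_linkage(med_events("metformin", dc), dc))   # discharge day
  expect_false(classify_linkage(med_events("atorvastatin", dc + 10 * day), dc))
  expect_false(classify_linkage(med_events("metformin", dc)[0, ], dc))
})

test_that("inpatient administrations never satisfy linkage, exhaustively", {
  # every drug class x timing combination as administration-kind events
  day <- 86400
  drugs <- c("insulin lispro", "liraglutide", "metformin", "atorvastatin")
  offsets <- c(-2, 0, 1, 45, 90) * day
  for (d in drugs) {
    for (o in offsets) {
      ev <- med_events(d, dc + o, kind = "administration")
      expect_false(classify_linkage(ev, dc), info = sprintf("%s @ %+d d", d, o / day))
    }
  }
  # whereas the same events as prescriptions link iff in class and window
  expect_true(classify_linkage(med_events("insulin lispro", dc + 45 * day), dc))
})

test_that("follow-up HbA1c is the latest value strictly inside (0, 180] days", {
  day <- 86400
  labs <- dplyr::bind_rows(lab_events(7.4, dc + 30 * day),
                           lab_events(6.8, dc + 120 * day))
  expect_equal(select_followup_a1c(labs, dc), 6.8)
  expect_true(is.na(select_followup_a1c(lab_events(7.1, dc + 200 * day), dc)))
  expect_true(is.na(select_followup_a1c(lab_events(7.1, dc)[0, ], dc)))
  # a discharge-instant value is not follow-up; the 180-day bound is included
  expect_true(is.na(select_followup_a1c(lab_events(7.1, dc), dc)))
  expect_equal(select_followup_a1c(lab_events(7.1, dc + 180 * day), dc), 7.1)
  # duplicate timestamps average, with a warning
  dup <- dplyr::bind_rows(lab_events(7.0, dc + 10 * day),
                          lab_events(8.0, dc + 10 * day))
  expect_warning(got <- select_followup_a1c(dup, dc), "mean")
  expect_equal(got, 7.5)
  # implausible values are ignored, not selected
  mixed <- dplyr::bind_rows(lab_events(55, dc + 100 * day),
                            lab_events(7.2, dc + 50 * day))
  expect_equal(select_followup_a1c(mixed, dc), 7.2)
})

test_that("control status uses inclusive thresholds on one-decimal values", {
  expect_equal(classify_control(6.9, 7.0), "controlled")
  expect_equal(classify_control(7.0, 7.0), "controlled")
  expect_equal(classify_control(8.6, 8.5), "uncontrolled")
  expect_equal(classify_control(NA, 7.5), "missing")
  # float-boundary guard: 7.0 reached through arithmetic still controls
  expect_equal(classify_control(6.3 + 0.7, 7.0), "controlled")
})

test_that("control classification is monotone in value and in threshold", {
  values <- seq(5.5, 10.5, by = 0.1)
  for (thr in c(7.0, 7.5, 8.0, 8.5)) {
    status <- classify_control(values, thr)
    # once uncontrolled, higher values stay uncontrolled
    expect_true(all(diff(status == "uncontrolled") >= 0), info = thr)
  }
  # raising the threshold never shrinks the controlled set
  s1 <- classify_control(values, 7.0)
  s2 <- classify_control(values, 8.5)
  expect_true(all(!(s1 == "controlled" & s2 != "controlled")))
})

test_that("vectorized cascade classification agrees with the per-patient operations", {
  tabs <- small_sim(300, seed = 21)
  codes <- synthetic_code_config()
  built <- build_cohort(tabs, codes)
  assigned <- classify_cascade(built$cohort, tabs, codes)
  for (i in sample(nrow(assigned), 40)) {
    pid <- assigned$patient_id[i]
    dcp <- assigned$discharge_ts[i]
    meds <- tabs$medications[tabs$medications$patient_id == pid, ]
    labs <- tabs$labs[tabs$labs$patient_id == pid, ]
    dxs <- tabs$diagnoses[tabs$diagnoses$patient_id == pid, ]
    expect_equal(assigned$linked[i], classify_linkage(meds, dcp, codes = codes))
    expect_equal(assigned$followup_a1c[i], select_followup_a1c(labs, dcp))
    comp <- detect_complications(dxs, dcp, codes) || detect_cvd(dxs, dcp, codes)
    expect_equal(assigned$threshold[i],
                 assign_control_target(assigned$age_at_index[i], comp))
    expect_equal(assigned$control_status[i],
                 classify_control(assigned$followup_a1c[i], assigned$threshold[i]))
  }
})

test_that("classifications are invariant under a global time translation", {
  tabs <- small_sim(250, seed = 5)
  codes <- synthetic_code_config()
  shift <- 37 * 86400
  shifted <- tabs
  for (nm in names(shifted)) {
    for (col in names(shifted[[nm]])) {
      if (inherits(shifted[[nm]][[col]], "POSIXct")) {
        shifted[[nm]][[col]] <- shifted[[nm]][[col]] + shift
      }
      if (inherits(shifted[[nm]][[col]], "Date")) {
        shifted[[nm]][[col]] <- shifted[[nm]][[col]] + shift / 86400
      }
    }
  }
  a <- run_pipeline(tabs, codes = codes, verbose = FALSE)$assignments
  b <- run_pipeline(shifted, codes = codes, verbose = FALSE)$assignments
  cols <- c("patient_id", "linked", "followup_a1c", "control_status",
            "a1c_measured_24h", "lispro_24h", "endo_consult", "any_marker")
  expect_equal(a[cols], b[cols])
})

test_that("every diagnosed patient receives exactly one linkage and control label", {
  tabs <- small_sim(400, seed = 13)
  res <- run_pipeline(tabs, codes = synthetic_code_config(), verbose = FALSE)
  a <- res$assignments
  expect_false(any(is.na(a$linked)))
  expect_true(all(a$control_status %in% c("controlled", "uncontrolled", "missing")))
  expect_equal(sum(is.na(a$followup_a1c)), sum(a$control_status == "missing"))
})
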