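test_that("exclusion rules retain E11 problem-list patients and exclude by precedence", {
  patients <- dplyr::bind_rows(lapply(1:3, function(i) patient_row(paste0("P", i))))
  diagnoses <- dplyr::bind_rows(
    dx_events("E11.9", id = "P1"),
    dx_events(c("E11.9", "O24.4"), id = "P2"),
    dx_events("E11.9", pl = FALSE, id = "P3")   # never on the problem list
  )
  res <- apply_exclusions(patients, diagnoses)
  expect_equal(res$cohort$patient_id, "P1")
  expect_equal(res$tally$n_gestational_excluded, 1)
  expect_equal(res$tally$n_no_problem_list_excluded, 1)
  expect_equal(res$tally$n_final, 1)
})

test_that("every combination of code flags lands in exactly one exclusion bucket", {
  # brute-force enumeration of (O24, E10, E11-on-problem-list) presence
  combos <- expand.grid(o24 = c(FALSE, TRUE), e10 = c(FALSE, TRUE),
                        e11pl = c(FALSE, TRUE))
  ids <- sprintf("P%d", seq_len(nrow(combos)))
  patients <- dplyr::bind_rows(lapply(ids, patient_row))
  diagnoses <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    rows <- list()
    if (combos$o24[i]) rows <- c(rows, list(dx_events("O24.419", id = ids[i])))
    if (combos$e10[i]) rows <- c(rows, list(dx_events("E10.9", id = ids[i])))
    if (combos$e11pl[i]) rows <- c(rows, list(dx_events("E11.9", id = ids[i])))
    dplyr::bind_rows(rows)
  }))
  res <- apply_exclusions(patients, diagnoses)
  t <- res$tally
  # conservation: each patient in exactly one bucket, first rule wins
  expect_equal(t$n_gestational_excluded, sum(combos$o24))
  expect_equal(t$n_type1_excluded, sum(!combos$o24 & combos$e10))
  expect_equal(t$n_no_problem_list_excluded,
               sum(!combos$o24 & !combos$e10 & !combos$e11pl))
  expect_equal(t$n_final, sum(!combos$o24 & !combos$e10 & combos$e11pl))
  expect_equal(t$n_input,
               t$n_final + t$n_gestational_excluded + t$n_type1_excluded +
                 t$n_no_problem_list_excluded)
})

test_that("empty input yields an empty cohort with a zeroed tally", {
  res <- apply_exclusions(patient_row()[0, ], dx_events("E11.9")[0, ])
  expect_equal(nrow(res$cohort), 0)
  expect_equal(res$tally$n_input, 0)
  expect_equal(res$tally$n_final, 0)
})

test_that("index admission selection anchors the first problem-list diagnosis", {
  cohort <- patient_row()
  # diagnosis on day 5 of a day 3-9 stay
  adm <- admission_row(admit = "2018-03-03 08:00:00",
                       discharge = "2018-03-09 12:00:00")
  inside <- select_index_admission(cohort, dx_events("E11.9", "2018-03-05 10:00:00"),
                                   adm)
  expect_equal(inside$index$admission_id, "A1")
  expect_equal(inside$n_no_index_admission, 0)
  # one day before admission still anchors (+/- 1 day tolerance)
  before <- select_index_admission(cohort,
                                   dx_events("E11.9", "2018-03-02 09:00:00"), adm)
  expect_equal(nrow(before$index), 1)
  # ten days before any admission does not
  far <- select_index_admission(cohort,
                                dx_events("E11.9", "2018-02-21 09:00:00"), adm)
  expect_equal(nrow(far$index), 0)
  expect_equal(far$n_no_index_admission, 1)
})

test_that("overlapping candidate admissions resolve deterministically", {
  cohort <- patient_row()
  dxs <- dx_events("E11.9", "2018-03-05 10:00:00")
  adms <- dplyr::bind_rows(
    admission_row(admit = "2018-03-04 08:00:00", discharge = "2018-03-10 08:00:00",
                  admission_id = "A9"),
    admission_row(admit = "2018-03-01 08:00:00", discharge = "2018-03-08 08:00:00",
                  admission_id = "A5"),
    # same admit instant as A5: lexicographically smaller id must win
    admission_row(admit = "2018-03-01 08:00:00", discharge = "2018-03-07 08:00:00",
                  admission_id = "A2")
  )
  res <- select_index_admission(cohort, dxs, adms)
  expect_equal(res$index$admission_id, "A2")
})

test_that("age strata use completed years at admission with closed bounds", {
  adm <- admission_row(admit = "2018-06-01 08:00:00")
  mk <- function(birth) derive_strata(patient_row(birth = birth), adm,
                                      code_config())
  expect_equal(mk("1953-06-02")$age_at_index, 64)   # birthday tomorrow
  expect_equal(mk("1953-06-02")$age_group, "45-64")
  expect_equal(mk("1953-06-01")$age_at_index, 65)   # birthday today
  expect_equal(mk("1953-06-01")$age_group, ">=65")
  expect_equal(mk("1974-01-01")$age_group, "18-44")
  expect_equal(mk("2000-05-30")$age_group, "18-44")
  missing_birth <- derive_strata(
    dplyr::mutate(patient_row(), birth_date = as.Date(NA)), adm, code_config())
  expect_equal(missing_birth$age_group, "missing")
})

test_that("insurance mapping follows Medicare > Medicaid > private > uninsured precedence", {
  expect_equal(map_insurance("Self-pay"), "uninsured_selfpay")
  expect_equal(map_insurance(NA), "missing")
  # brute-force enumeration of payer label combinations against an
  # independent statement of the precedence rule
  parts <- c("Medicare", "Medicaid", "Commercial", "Self-pay")
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(parts, k, paste, collapse = " + ", simplify = FALSE)
  }))
  oracle <- function(lbl) {
    l <- tolower(lbl)
    if (grepl("medicare", l)) "medicare"
    else if (grepl("medicaid", l)) "medicaid"
    else if (grepl("self-pay", l) && !grepl("commercial", l)) "uninsured_selfpay"
    else "private"
  }
  expect_equal(map_insurance(combos), vapply(combos, oracle, character(1)),
               ignore_attr = TRUE)
})

test_that("Promise Zone residence is zip-list membership", {
  codes <- code_config(promise_zone_zips = c("63106", "63107"))
  adm <- admission_row()
  expect_true(derive_strata(patient_row(zip = "63106"), adm, codes)$promise_zone)
  expect_false(derive_strata(patient_row(zip = "63109"), adm, codes)$promise_zone)
})

test_that("age grouping partitions a simulated cohort", {
  tabs <- small_sim(400, seed = 3)
  built <- build_cohort(tabs, synthetic_code_config())
  grp <- built$cohort$age_group
  expect_true(all(grp %in% c("18-44", "45-64", ">=65", "missing")))
  known <- !is.na(built$cohort$age_at_index)
  # each patient with known age falls in exactly the group its age implies
  expect_equal(grp[known], age_group(built$cohort$age_at_index[known]))
})
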