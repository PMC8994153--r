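test_that("generator configuration validates probabilities before any generation", {
  expect_error(generator_config(p_linkage = 1.2), "probability")
  expect_error(generator_config(sex_probs = c(female = 0.6, male = 0.6)),
               "summing to 1")
  expect_error(generator_config(p_gestational = 0.6, p_type1 = 0.5),
               "no diagnosed cohort")
  expect_error(generator_config(n_patients = 0), "n_patients")
  cfg <- generator_config()
  expect_equal(cfg$p_linkage, 0.352)
  expect_equal(cfg$p_marker_lispro, 0.725)
})

test_that("generation is reproducible under a fixed seed", {
  a <- simulate_ehr(generator_config(n_patients = 1000, seed = 7))
  b <- simulate_ehr(generator_config(n_patients = 1000, seed = 7))
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]], label = nm)
  c <- simulate_ehr(generator_config(n_patients = 1000, seed = 8))
  expect_false(identical(a$patients, c$patients))
})

test_that("degenerate linkage probabilities propagate through the pipeline", {
  none <- simulate_ehr(generator_config(n_patients = 400, seed = 2,
                                        p_linkage = 0))
  res <- run_pipeline(none, codes = synthetic_code_config(), verbose = FALSE)
  expect_equal(res$flow$n_linked, 0)
  all_link <- simulate_ehr(generator_config(n_patients = 400, seed = 2,
                                            p_linkage = 1))
  res2 <- run_pipeline(all_link, codes = synthetic_code_config(), verbose = FALSE)
  expect_equal(res2$flow$n_unlinked, 0)
})

test_that("the pipeline recovers generator parameters within binomial error", {
  cfg <- generator_config(n_patients = 5000, seed = 19)
  res <- run_pipeline(simulate_ehr(cfg), codes = synthetic_code_config(),
                      verbose = FALSE)
  a <- res$assignments
  n <- nrow(a)
  within3se <- function(est, p, m) abs(est - p) < 3 * sqrt(p * (1 - p) / m)
  expect_true(within3se(mean(a$linked), cfg$p_linkage, n))
  expect_true(within3se(mean(a$a1c_measured_24h), cfg$p_marker_a1c, n))
  expect_true(within3se(mean(a$lispro_24h), cfg$p_marker_lispro, n))
  expect_true(within3se(mean(a$endo_consult), cfg$p_marker_consult, n))
  expect_true(within3se(mean(a$control_status[a$linked] == "missing"),
                        cfg$p_missing_a1c_linked, sum(a$linked)))
  expect_true(within3se(mean(a$control_status[!a$linked] == "missing"),
                        cfg$p_missing_a1c_unlinked, sum(!a$linked)))
  expect_true(within3se(mean(a$promise_zone), cfg$p_promise_zone, n))
})

test_that("controlled fractions match the HbA1c distribution's CDF at each target", {
  cfg <- generator_config(n_patients = 8000, seed = 23,
                          p_missing_a1c_linked = 0, p_missing_a1c_unlinked = 0)
  res <- run_pipeline(simulate_ehr(cfg), codes = synthetic_code_config(),
                      verbose = FALSE)
  a <- res$assignments
  # values are rounded to one decimal at generation, so the oracle CDF is
  # evaluated at threshold + 0.05 (everything rounding down to the target)
  for (thr in c(7.0, 7.5, 8.0, 8.5)) {
    sub <- a[a$threshold == thr & !is.na(a$followup_a1c), ]
    if (nrow(sub) < 200) next
    p_oracle <- stats::plnorm(thr + 0.05, cfg$a1c_meanlog, cfg$a1c_sdlog)
    got <- mean(sub$control_status == "controlled")
    expect_lt(abs(got - p_oracle),
              3 * sqrt(p_oracle * (1 - p_oracle) / nrow(sub)))
  }
})

test_that("a stratum-conditional linkage override injects the intended disparity", {
  cfg <- generator_config(n_patients = 6000, seed = 37,
                          p_linkage_promise_zone = 0.6)
  res <- run_pipeline(simulate_ehr(cfg), codes = synthetic_code_config(),
                      verbose = FALSE)
  a <- res$assignments
  expect_gt(mean(a$linked[a$promise_zone]), mean(a$linked[!a$promise_zone]))
  expect_lt(abs(mean(a$linked[a$promise_zone]) - 0.6),
            3 * sqrt(0.6 * 0.4 / sum(a$promise_zone)))
})

test_that("the exclusion fixture is deterministic and reproduces the published funnel", {
  f1 <- generate_exclusion_fixture()
  f2 <- generate_exclusion_fixture()
  expect_identical(f1$diagnoses, f2$diagnoses)
  expect_equal(nrow(f1$patients), 93433)
  res <- apply_exclusions(f1$patients, f1$diagnoses)
  expect_equal(res$tally$n_gestational_excluded, 3875)
  expect_equal(res$tally$n_type1_excluded, 7925)
  expect_equal(res$tally$n_final, 81633)
})

test_that("overlapping exclusion codes still conserve the tally", {
  # brute-force: give every type 1 carrier in a small copy an O24 code too
  f <- generate_exclusion_fixture()
  keep <- c(1:100, 3876:3975, 11801:11900)   # 100 per original bucket
  patients <- f$patients[keep, ]
  diagnoses <- f$diagnoses[keep, ]
  t1_ids <- diagnoses$patient_id[startsWith(diagnoses$code, "E10")]
  overlap <- dx_events("O24.419", id = t1_ids[1:50])
  overlap$patient_id <- t1_ids[1:50]
  res <- apply_exclusions(patients, dplyr::bind_rows(diagnoses, overlap))
  t <- res$tally
  expect_equal(t$n_input, 300)
  # the 50 dual carriers count once, as gestational (first rule wins)
  expect_equal(t$n_gestational_excluded, 150)
  expect_equal(t$n_type1_excluded, 50)
  expect_equal(t$n_final, 100)
  expect_equal(t$n_input, t$n_final + t$n_gestational_excluded +
                 t$n_type1_excluded + t$n_no_problem_list_excluded)
})
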