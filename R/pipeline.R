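ehr_table_names <- c("patients", "admissions", "diagnoses", "medications",
                     "labs", "consults")

ehr_required_columns <- list(
  patients = c("patient_id", "sex", "race", "birth_date", "zip_code",
               "insurance_raw"),
  admissions = c("patient_id", "admit_ts", "discharge_ts"),
  diagnoses = c("patient_id", "code", "on_problem_list", "recorded_ts"),
  medications = c("patient_id", "drug_name", "kind", "ts"),
  labs = c("patient_id", "analyte", "value", "ts"),
  consults = c("patient_id", "service", "ts")
)

ehr_col_types <- list(
  patients = readr::cols(
    patient_id = readr::col_character(), sex = readr::col_character(),
    race = readr::col_character(), birth_date = readr::col_date(),
    zip_code = readr::col_character(), insurance_raw = readr::col_character()
  ),
  admissions = readr::cols(
    patient_id = readr::col_character(),
    admit_ts = readr::col_datetime(), discharge_ts = readr::col_datetime(),
    .default = readr::col_character()
  ),
  diagnoses = readr::cols(
    patient_id = readr::col_character(), code = readr::col_character(),
    on_problem_list = readr::col_logical(),
    recorded_ts = readr::col_datetime()
  ),
  medications = readr::cols(
    patient_id = readr::col_character(), drug_name = readr::col_character(),
    kind = readr::col_character(), ts = readr::col_datetime(),
    .default = readr::col_character()
  ),
  labs = readr::cols(
    patient_id = readr::col_character(), analyte = readr::col_character(),
    value = readr::col_double(), ts = readr::col_datetime()
  ),
  consults = readr::cols(
    patient_id = readr::col_character(), service = readr::col_character(),
    ts = readr::col_datetime()
  )
)

#' Read the six event tables from a directory of CSV files
#'
#' Expects `patients.csv`, `admissions.csv`, `diagnoses.csv`,
#' `medications.csv`, `labs.csv`, `consults.csv` with ISO-8601 timestamps.
#' Schema and referential integrity are validated on read (see
#' [validate_ehr_tables()]).
#'
#' @param dir Directory containing the six CSV files.
#' @return Named list of tibbles.
#' @export
read_ehr_tables <- function(dir) {
  tables <- stats::setNames(lapply(ehr_table_names, function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing input table: ", path, call. = FALSE)
    readr::read_csv(path, col_types = ehr_col_types[[nm]], progress = FALSE)
  }), ehr_table_names)
  validate_ehr_tables(tables)
  tables
}

#' Write event tables as CSV
#' @param tables Named list of event tables.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ehr_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in intersect(ehr_table_names, names(tables))) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Validate event tables against the pipeline schema
#'
#' Checks required columns per table (error names the table and columns),
#' referential integrity of every event table against the patient table
#' (error lists the offending ids), the admission interval invariant
#' `admit_ts <= discharge_ts`, uniqueness of `patient_id`, and that birth
#' dates precede admission timestamps. HbA1c values outside the plausible
#' (3, 20)% band are counted and reported via a warning — they are flagged
#' downstream, never silently dropped here.
#'
#' @param tables Named list of event tables.
#' @return `tables`, invisibly.
#' @export
validate_ehr_tables <- function(tables) {
  missing_tab <- setdiff(ehr_table_names, names(tables))
  if (length(missing_tab) > 0) {
    stop("missing event tables: ", paste(missing_tab, collapse = ", "),
         call. = FALSE)
  }
  for (nm in ehr_table_names) {
    absent <- setdiff(ehr_required_columns[[nm]], names(tables[[nm]]))
    if (length(absent) > 0) {
      stop(sprintf("table '%s' lacks required column(s): %s", nm,
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  if (anyDuplicated(tables$patients$patient_id)) {
    stop("duplicated patient_id in patients table", call. = FALSE)
  }
  known <- tables$patients$patient_id
  for (nm in setdiff(ehr_table_names, "patients")) {
    unknown <- setdiff(unique(tables[[nm]]$patient_id), known)
    if (length(unknown) > 0) {
      stop(sprintf("table '%s' references unknown patient id(s): %s%s",
                   nm, paste(utils::head(unknown, 5), collapse = ", "),
                   if (length(unknown) > 5) ", ..." else ""), call. = FALSE)
    }
  }
  adm <- tables$admissions
  bad <- which(adm$admit_ts > adm$discharge_ts)
  if (length(bad) > 0) {
    stop("admissions with admit_ts after discharge_ts at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  birth <- dplyr::inner_join(
    dplyr::select(tables$patients, "patient_id", "birth_date"),
    dplyr::select(adm, "patient_id", "admit_ts"),
    by = "patient_id"
  )
  if (any(!is.na(birth$birth_date) &
            as.Date(birth$birth_date) > as.Date(birth$admit_ts))) {
    stop("birth_date after admission timestamp for some patients",
         call. = FALSE)
  }
  n_implausible <- sum(tables$labs$analyte == "hba1c" &
                         !a1c_plausible(tables$labs$value))
  if (n_implausible > 0) {
    warning(n_implausible,
            " HbA1c value(s) outside the plausible (3, 20)% band; ",
            "they are ignored by follow-up selection", call. = FALSE)
  }
  invisible(tables)
}

#' Run the cascade pipeline end to end
#'
#' Composes the whole analysis: validation, exclusions, index-admission
#' anchoring, strata, cascade classification, inpatient markers, flow
#' counts, the stratified cascade table, and the stage-comparison test
#' suite. The run log records counts at every stage so the attrition
#' ("leaky pipeline") is auditable. Deterministic for fixed inputs.
#'
#' @param tables Named list of event tables, or `NULL` to read from
#'   `input_dir`.
#' @param input_dir Directory of CSV inputs (used when `tables` is `NULL`).
#' @param codes A [code_config()].
#' @param out_dir Optional output directory; when given, the assignment
#'   table, cascade table (CSV and aligned text), flow counts, exclusion
#'   tally, test suite and log are written there.
#' @param linkage_window_days,followup_window_days Window overrides (days).
#' @param tol_days Index-admission anchoring tolerance (days).
#' @param verbose Emit the stage log via [message()].
#' @return List: `tally`, `cohort`, `assignments`, `flow`, `table`,
#'   `tests`, `log`.
#' @export
run_pipeline <- function(tables = NULL, input_dir = NULL,
                         codes = code_config(), out_dir = NULL,
                         linkage_window_days = 90, followup_window_days = 180,
                         tol_days = 1, verbose = TRUE) {
  stopifnot(linkage_window_days > 0, followup_window_days > 0, tol_days >= 0)
  if (is.null(tables)) {
    stopifnot(!is.null(input_dir))
    tables <- read_ehr_tables(input_dir)
  } else {
    validate_ehr_tables(tables)
  }
  built <- build_cohort(tables, codes, tol_days = tol_days)
  assignments <- classify_cascade(
    built$cohort, tables, codes,
    linkage_window_days = linkage_window_days,
    followup_window_days = followup_window_days
  ) |>
    compute_markers(tables, codes)
  flow <- build_flow_counts(assignments)
  table <- cascade_table(assignments)
  tests <- stage_comparison_suite(table)
  t <- built$tally
  log <- c(
    sprintf("input patients: %d", t$n_input),
    sprintf("excluded gestational (O24.xx): %d", t$n_gestational_excluded),
    sprintf("excluded type 1 (E10.xx): %d", t$n_type1_excluded),
    sprintf("excluded, no E11 problem-list diagnosis: %d",
            t$n_no_problem_list_excluded),
    sprintf("after exclusions: %d", t$n_final),
    sprintf("dropped, no anchoring index admission: %d",
            built$n_no_index_admission),
    sprintf("diagnosed cohort: %d", flow$n_diagnosed),
    sprintf("linked to care: %d (%s%%)", flow$n_linked,
            format_percent(flow$n_linked, flow$n_diagnosed)),
    sprintf("unlinked: %d", flow$n_unlinked),
    sprintf("linked arm controlled/uncontrolled/missing: %d/%d/%d",
            flow$linked["controlled"], flow$linked["uncontrolled"],
            flow$linked["missing"]),
    sprintf("unlinked arm controlled/uncontrolled/missing: %d/%d/%d",
            flow$unlinked["controlled"], flow$unlinked["uncontrolled"],
            flow$unlinked["missing"])
  )
  if (verbose) message(paste(log, collapse = "\n"))
  result <- list(tally = t, cohort = built$cohort, assignments = assignments,
                 flow = flow, table = table, tests = tests, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(assignments, file.path(out_dir, "assignments.csv"))
    readr::write_csv(tibble::as_tibble(table),
                     file.path(out_dir, "cascade_table.csv"))
    writeLines(format_cascade_table(table, marks = tests),
               file.path(out_dir, "cascade_table.txt"))
    readr::write_csv(tests, file.path(out_dir, "prop_tests.csv"))
    jsonlite::write_json(
      list(tally = unclass(t),
           flow = list(n_diagnosed = flow$n_diagnosed,
                       n_linked = flow$n_linked, n_unlinked = flow$n_unlinked,
                       linked = as.list(flow$linked),
                       unlinked = as.list(flow$unlinked))),
      file.path(out_dir, "flow.json"), auto_unbox = TRUE, pretty = TRUE
    )
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  invisible(result)
}

#' Reproduce the published aggregate results from the packaged fixture
#'
#' Recomputes, from the fixture counts and the deterministic exclusion
#' fixture, the study's key printed quantities: the 93,433 to 81,633
#' exclusion funnel, the 35.2% linkage and 70.4% missing-HbA1c
#' proportions, the targeted stratified cells, the formatted p-values of
#' the diagnosed-vs-linked comparisons, and the bit-exact reproduction of
#' every arithmetically consistent printed table cell. Returns a pass/fail
#' report; the `ok` attribute is `TRUE` when every check passes.
#'
#' @param fixture A [load_published_counts()] result.
#' @param run_exclusion_fixture Also regenerate and run the 93,433-patient
#'   exclusion fixture (a few seconds).
#' @return Tibble: `check`, `expected`, `got`, `pass`; attribute `ok`.
#' @export
reproduce_published <- function(fixture = load_published_counts(),
                            run_exclusion_fixture = TRUE) {
  checks <- list()
  add <- function(check, expected, got) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, expected = as.character(expected),
      got = as.character(got), pass = identical(as.character(expected),
                                                as.character(got))
    )
  }
  if (run_exclusion_fixture) {
    tally <- apply_exclusions(
      generate_exclusion_fixture()$patients,
      generate_exclusion_fixture()$diagnoses
    )$tally
    add("exclusion fixture final cohort", fixture$exclusions$n_final,
        tally$n_final)
  }
  fl <- fixture$flow
  add("linked percent of diagnosed", "35.2",
      format_percent(fl$n_linked, fl$n_diagnosed))
  add("missing follow-up HbA1c percent", "70.4",
      format_percent(fl$linked["missing"] + fl$unlinked["missing"],
                     fl$n_diagnosed))
  cell <- function(variable, category, stage) {
    i <- fixture$table$variable == variable & fixture$table$category == category
    fixture$table[[paste0("pct_", stage)]][i]
  }
  add("Promise Zone share of diagnosed", "17.5",
      cell("promise_zone", "yes", "diagnosed"))
  add("Promise Zone share of linked", "18.7",
      cell("promise_zone", "yes", "linked"))
  add("self-pay share of linked", "9.7",
      cell("insurance", "uninsured_selfpay", "linked"))
  add("age 18-44 share of linked", "6.8", cell("age_group", "18-44", "linked"))
  add("lispro share of linked", "80.1", cell("lispro_24h", "yes", "linked"))
  add("any-marker share of diagnosed", "77.4",
      cell("any_marker", "yes", "diagnosed"))
  rt <- fixture$results_text$pz_linked_controlled
  add("controlled share of linked Promise Zone residents", rt$pct,
      format_percent(rt$n, rt$denominator))
  p_dvl <- function(variable, category) {
    i <- fixture$table$variable == variable & fixture$table$category == category
    two_prop_test(fixture$table$n_diagnosed[i], fl$n_diagnosed,
                  fixture$table$n_linked[i], fl$n_linked)$p_formatted
  }
  add("P, sex female diagnosed vs linked", ".03", p_dvl("sex", "female"))
  add("P, age 18-44 diagnosed vs linked", ".03", p_dvl("age_group", "18-44"))
  add("P, Promise Zone diagnosed vs linked", "<.001",
      p_dvl("promise_zone", "yes"))
  add("P, self-pay diagnosed vs linked", "<.001",
      p_dvl("insurance", "uninsured_selfpay"))
  add("P, private insurance diagnosed vs linked", "<.001",
      p_dvl("insurance", "private"))
  cons <- fixture$consistency
  add("arithmetically consistent printed cells reproduced bit-exactly",
      sum(cons$consistent),
      sum(cons$consistent & cons$printed_pct == cons$computed_pct))
  report <- dplyr::bind_rows(checks)
  attr(report, "ok") <- all(report$pass)
  report
}
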