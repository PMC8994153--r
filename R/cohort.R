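#' Whole years between two dates
#'
#' Calendar age in completed years; a birthday falling during a hospital stay
#' does not change any stratum because age is always taken at one anchor
#' date.
#'
#' @param birth_date Date (or coercible) vector of birth dates.
#' @param at Date (or coercible) vector of anchor dates, recycled.
#' @return Integer vector of completed years; `NA` where either input is
#'   missing.
#' @export
age_years <- function(birth_date, at) {
  b <- as.POSIXlt(as.Date(birth_date))
  a <- as.POSIXlt(as.Date(at))
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - as.integer(before_birthday))
}

new_exclusion_tally <- function(n_input, n_gestational, n_type1, n_no_problem_list) {
  n_final <- n_input - n_gestational - n_type1 - n_no_problem_list
  stopifnot(n_final >= 0)
  structure(
    list(
      n_input = n_input,
      n_gestational_excluded = n_gestational,
      n_type1_excluded = n_type1,
      n_no_problem_list_excluded = n_no_problem_list,
      n_final = n_final
    ),
    class = "exclusion_tally"
  )
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Exclusion cascade\n")
  cat(sprintf("  input patients            %9d\n", x$n_input))
  cat(sprintf("  - gestational (O24.xx)    %9d\n", x$n_gestational_excluded))
  cat(sprintf("  - type 1 (E10.xx)         %9d\n", x$n_type1_excluded))
  cat(sprintf("  - no E11 problem-list dx  %9d\n", x$n_no_problem_list_excluded))
  cat(sprintf("  final diagnosed cohort    %9d\n", x$n_final))
  invisible(x)
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Retains patients with at least one type 2 diabetes diagnosis (`E11.xx`)
#' flagged on the problem list, excluding first anyone carrying a
#' gestational-diabetes code (`O24.xx`), then anyone carrying a type 1 code
#' (`E10.xx`), then anyone whose E11 codes never appear on the problem list.
#' Each patient is excluded exactly once: the first matching rule wins, so a
#' patient with both `O24` and `E10` codes counts as gestational. The
#' returned tally reconciles by construction
#' (`n_final = n_input - sum of exclusions`).
#'
#' @param patients Patient table (one row per `patient_id`).
#' @param diagnoses Diagnosis events with `patient_id`, `code`,
#'   `on_problem_list`, `recorded_ts`.
#' @param codes A [code_config()].
#' @return A list with `cohort` (retained patient rows) and `tally`
#'   (an `exclusion_tally`).
#' @export
apply_exclusions <- function(patients, diagnoses, codes = code_config()) {
  stopifnot(!anyDuplicated(patients$patient_id))
  if (nrow(patients) == 0) {
    return(list(cohort = patients, tally = new_exclusion_tally(0L, 0L, 0L, 0L)))
  }
  unknown <- setdiff(unique(diagnoses$patient_id), patients$patient_id)
  if (length(unknown) > 0) {
    stop("diagnoses reference unknown patient ids: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(diagnoses) > 0) {
    norm <- normalize_icd10(diagnoses$code)
    flags <- tibble::tibble(
      patient_id = diagnoses$patient_id,
      gest = match_prefix_normalized(norm, codes$gestational_prefixes),
      t1 = match_prefix_normalized(norm, codes$t1dm_prefixes),
      t2_pl = match_prefix_normalized(norm, codes$t2dm_prefixes) &
        diagnoses$on_problem_list
    ) |>
      dplyr::summarise(
        gest = any(.data$gest), t1 = any(.data$t1), t2_pl = any(.data$t2_pl),
        .by = "patient_id"
      )
  } else {
    flags <- tibble::tibble(patient_id = character(), gest = logical(),
                            t1 = logical(), t2_pl = logical())
  }
  pat <- dplyr::left_join(patients, flags, by = "patient_id") |>
    dplyr::mutate(
      gest = dplyr::coalesce(.data$gest, FALSE),
      t1 = dplyr::coalesce(.data$t1, FALSE),
      t2_pl = dplyr::coalesce(.data$t2_pl, FALSE),
      bucket = dplyr::case_when(
        .data$gest ~ "gestational",
        .data$t1 ~ "type1",
        !.data$t2_pl ~ "no_problem_list",
        TRUE ~ "retained"
      )
    )
  tally <- new_exclusion_tally(
    n_input = nrow(pat),
    n_gestational = sum(pat$bucket == "gestational"),
    n_type1 = sum(pat$bucket == "type1"),
    n_no_problem_list = sum(pat$bucket == "no_problem_list")
  )
  cohort <- pat |>
    dplyr::filter(.data$bucket == "retained") |>
    dplyr::select(-"gest", -"t1", -"t2_pl", -"bucket")
  list(cohort = cohort, tally = tally)
}

# prefix match on codes already normalized (internal fast path)
match_prefix_normalized <- function(norm_code, prefixes) {
  if (length(prefixes) == 0) {
    return(rep(FALSE, length(norm_code)))
  }
  Reduce(`|`, lapply(prefixes, function(p) startsWith(norm_code, p)))
}

#' Select each patient's index admission
#'
#' The index admission is the earliest admission whose interval, widened by
#' the tolerance (one calendar day on each side by default), contains the
#' patient's first type 2 diabetes problem-list timestamp — the "first
#' recorded diagnosis within a day of admission" anchor. Ties on admission
#' start resolve to the lexicographically smallest admission identifier, so
#' selection is deterministic. Patients with no qualifying admission are
#' dropped from the cohort (the cascade is inpatient-anchored) and counted.
#'
#' @param cohort Retained patients from [apply_exclusions()].
#' @param diagnoses Diagnosis events.
#' @param admissions Admission events with `patient_id`, `admit_ts`,
#'   `discharge_ts` (and optionally `admission_id`).
#' @param codes A [code_config()].
#' @param tol_days Tolerance around the admission interval, in days.
#' @return A list with `index` (tibble: `patient_id`, `admission_id`,
#'   `admit_ts`, `discharge_ts`, `first_t2dm_problem_ts`) and
#'   `n_no_index_admission`.
#' @export
select_index_admission <- function(cohort, diagnoses, admissions,
                                   codes = code_config(), tol_days = 1) {
  stopifnot(tol_days >= 0)
  tol <- tol_days * 86400
  if (nrow(admissions) > 0 && any(admissions$admit_ts > admissions$discharge_ts)) {
    stop("admissions with admit_ts after discharge_ts", call. = FALSE)
  }
  if (!"admission_id" %in% names(admissions)) {
    admissions <- dplyr::mutate(
      admissions,
      admission_id = sprintf("A%07d", dplyr::row_number())
    )
  }
  norm <- normalize_icd10(diagnoses$code)
  first_ts <- diagnoses |>
    dplyr::filter(
      match_prefix_normalized(norm, codes$t2dm_prefixes) & .data$on_problem_list,
      .data$patient_id %in% cohort$patient_id
    ) |>
    dplyr::summarise(
      first_t2dm_problem_ts = min(.data$recorded_ts),
      .by = "patient_id"
    )
  index <- dplyr::inner_join(
    first_ts,
    dplyr::select(admissions, "patient_id", "admission_id",
                  "admit_ts", "discharge_ts"),
    by = "patient_id", relationship = "one-to-many"
  ) |>
    dplyr::filter(
      .data$first_t2dm_problem_ts >= .data$admit_ts - tol,
      .data$first_t2dm_problem_ts <= .data$discharge_ts + tol
    ) |>
    dplyr::arrange(.data$patient_id, .data$admit_ts, .data$admission_id) |>
    dplyr::slice_head(n = 1, by = "patient_id") |>
    dplyr::select("patient_id", "admission_id", "admit_ts", "discharge_ts",
                  "first_t2dm_problem_ts")
  list(
    index = index,
    n_no_index_admission = nrow(first_ts) - nrow(index) +
      sum(!cohort$patient_id %in% first_ts$patient_id)
  )
}

#' Map raw payer labels to the four insurance strata
#'
#' Precedence is Medicare over Medicaid over private, so a dual
#' Medicare+Medicaid label counts as Medicare. Self-pay, "none", "uninsured"
#' or an empty payer string map to `uninsured_selfpay`; a genuinely missing
#' (`NA`) label maps to `missing`. Any other recorded payer is private
#' insurance.
#'
#' @param insurance_raw Character vector of payer labels.
#' @return Character vector over `{private, medicare, medicaid,
#'   uninsured_selfpay, missing}`.
#' @export
map_insurance <- function(insurance_raw) {
  r <- tolower(trimws(as.character(insurance_raw)))
  out <- rep("private", length(r))
  # uninsured only when the label carries no other payer signal: a mixed
  # "Commercial + Self-pay" label still counts as privately insured
  uninsured_terms <- "self[ -]?pay|\\bnone\\b|uninsured|no insurance"
  residue <- gsub("[^a-z]", "", gsub(uninsured_terms, "", r))
  out[!is.na(r) & (r == "" | (grepl(uninsured_terms, r) & residue == ""))] <-
    "uninsured_selfpay"
  out[!is.na(r) & grepl("medicaid", r)] <- "medicaid"
  out[!is.na(r) & grepl("medicare", r)] <- "medicare"
  out[is.na(r)] <- "missing"
  out
}

#' Age-group stratum from age in years
#'
#' Adult groups 18-44, 45-64 and >=65, closed on the stated bounds; missing
#' age (or an age below 18, which the adult cohort should not contain) maps
#' to `missing`.
#'
#' @param age Integer vector of ages in completed years.
#' @return Character vector over `{18-44, 45-64, >=65, missing}`.
#' @export
age_group <- function(age) {
  out <- dplyr::case_when(
    is.na(age) ~ "missing",
    age < 18 ~ "missing",
    age <= 44 ~ "18-44",
    age <= 64 ~ "45-64",
    TRUE ~ ">=65"
  )
  if (any(!is.na(age) & age < 18)) {
    warning("ages below 18 mapped to the 'missing' age group", call. = FALSE)
  }
  out
}

#' Derive demographic and socioeconomic strata at the index admission
#'
#' Computes age at index admission in completed years, the age-group stratum,
#' the insurance stratum (see [map_insurance()]), and Promise Zone residence
#' (zip code membership in the configured list). Sex and race are passed
#' through with `NA` normalized to `"missing"`.
#'
#' @param patients Patient table.
#' @param index Index-admission tibble from [select_index_admission()].
#' @param codes A [code_config()] carrying `promise_zone_zips`.
#' @return Tibble: `patient_id`, `sex`, `race`, `age_at_index`, `age_group`,
#'   `insurance`, `promise_zone`, plus the index admission columns.
#' @export
derive_strata <- function(patients, index, codes = code_config()) {
  dplyr::inner_join(patients, index, by = "patient_id") |>
    dplyr::mutate(
      sex = dplyr::coalesce(as.character(.data$sex), "missing"),
      race = dplyr::coalesce(as.character(.data$race), "missing"),
      age_at_index = age_years(.data$birth_date, .data$admit_ts),
      age_group = age_group(.data$age_at_index),
      insurance = map_insurance(.data$insurance_raw),
      promise_zone = .data$zip_code %in% codes$promise_zone_zips
    ) |>
    dplyr::select(
      "patient_id", "sex", "race", "age_at_index", "age_group", "insurance",
      "promise_zone", "admission_id", "admit_ts", "discharge_ts",
      dplyr::any_of("first_t2dm_problem_ts")
    )
}

#' Build the diagnosed cohort end to end
#'
#' Chains [apply_exclusions()], [select_index_admission()] and
#' [derive_strata()]: exclusion rules, inpatient anchoring, then strata.
#'
#' @param tables Named list of event tables (`patients`, `admissions`,
#'   `diagnoses`, ...) as returned by [read_ehr_tables()] or
#'   [simulate_ehr()].
#' @param codes A [code_config()].
#' @param tol_days Index-admission anchoring tolerance in days.
#' @return List with `cohort` (strata tibble), `tally` (exclusions), and
#'   `n_no_index_admission`.
#' @export
build_cohort <- function(tables, codes = code_config(), tol_days = 1) {
  excl <- apply_exclusions(tables$patients, tables$diagnoses, codes)
  idx <- select_index_admission(excl$cohort, tables$diagnoses,
                                tables$admissions, codes, tol_days)
  cohort <- derive_strata(excl$cohort, idx$index, codes)
  list(
    cohort = cohort,
    tally = excl$tally,
    n_no_index_admission = idx$n_no_index_admission
  )
}
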