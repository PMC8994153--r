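#' Round half up at a fixed number of decimals
#'
#' Deterministic round-half-up (so 0.05 rounds to 0.1), used for HbA1c
#' values before threshold comparison and for table percentages. A small
#' epsilon absorbs binary-representation error on exact .5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Detect diabetes complications for one patient
#'
#' `TRUE` when any diagnosis code in the configured complication subcode
#' range (default `E11.2`-`E11.8`) is recorded on or before the index
#' discharge. Later diagnoses never retroactively change the control target.
#'
#' @param diagnoses Diagnosis events for one patient.
#' @param index_discharge_ts Discharge timestamp of the index admission.
#' @param codes A [code_config()].
#' @return Logical scalar.
#' @export
detect_complications <- function(diagnoses, index_discharge_ts,
                                 codes = code_config()) {
  if (nrow(diagnoses) == 0) return(FALSE)
  norm <- normalize_icd10(diagnoses$code)
  any(match_prefix_normalized(norm, codes$complication_subcodes) &
        diagnoses$recorded_ts <= index_discharge_ts)
}

#' Detect cardiovascular disease for one patient
#'
#' `TRUE` when any diagnosis matches the configured CVD prefixes —
#' myocardial infarction (`I21`/`I22`), heart failure (`I50`) or angina
#' (`I20`) by default — on or before the index discharge.
#'
#' @inheritParams detect_complications
#' @return Logical scalar.
#' @export
detect_cvd <- function(diagnoses, index_discharge_ts, codes = code_config()) {
  if (nrow(diagnoses) == 0) return(FALSE)
  norm <- normalize_icd10(diagnoses$code)
  any(match_prefix_normalized(norm, codes$cvd_prefixes) &
        diagnoses$recorded_ts <= index_discharge_ts)
}

#' Individualized HbA1c control target
#'
#' The glycemic target depends on the age band at the index admission and on
#' complication/CVD status:
#'
#' | age band | uncomplicated | complicated or CVD |
#' |----------|---------------|--------------------|
#' | < 65     | 7.0 %         | 8.0 %              |
#' | >= 65    | 7.5 %         | 8.5 %              |
#'
#' @param age_at_index Integer vector of ages in completed years; must be
#'   known (route missing-age patients around this call).
#' @param complicated Logical vector: diabetes complications or CVD present.
#' @return Numeric vector of thresholds in percent HbA1c.
#' @export
#' @examples
#' assign_control_target(c(50, 64, 65, 80), c(FALSE, TRUE, FALSE, TRUE))
assign_control_target <- function(age_at_index, complicated) {
  if (any(is.na(age_at_index))) {
    stop("assign_control_target: missing age; route such patients to ",
         "missing-strata handling", call. = FALSE)
  }
  stopifnot(length(complicated) == length(age_at_index) || length(complicated) == 1)
  older <- age_at_index >= 65
  7.0 + 0.5 * older + 1.0 * complicated
}

#' Linkage to care for one patient
#'
#' A patient is linked when any *prescription* of an anti-diabetes drug
#' (insulin, noninsulin injectable or oral agent) falls within the window
#' `[discharge, discharge + 90 days]`, both ends included — a discharge-day
#' prescription counts. Inpatient administrations never satisfy linkage.
#'
#' @param medications Medication events for one patient (`drug_name`,
#'   `kind`, `ts`; `med_class` is derived if absent).
#' @param discharge_ts Index discharge timestamp.
#' @param window_days Length of the post-discharge window, default 90.
#' @param codes A [code_config()] supplying the medication class map.
#' @return Logical scalar.
#' @export
classify_linkage <- function(medications, discharge_ts, window_days = 90,
                             codes = code_config()) {
  stopifnot(window_days > 0)
  if (nrow(medications) == 0) return(FALSE)
  cls <- medication_classes(medications, codes)
  any(
    medications$kind == "prescription" &
      cls %in% linkage_classes() &
      medications$ts >= discharge_ts &
      medications$ts <= discharge_ts + window_days * 86400
  )
}

medication_classes <- function(medications, codes) {
  if ("med_class" %in% names(medications)) {
    medications$med_class
  } else {
    classify_medication(medications$drug_name, codes$medication_class_map)
  }
}

#' Follow-up HbA1c for one patient
#'
#' Returns the latest plausible HbA1c value with a timestamp in
#' `(discharge, discharge + 180 days]` — strictly after discharge, so
#' inpatient results from the stay itself are not follow-up. Several results
#' sharing the single latest timestamp average (and are flagged via a
#' warning); no result in the window yields `NA`.
#'
#' @param labs Lab events for one patient (`analyte`, `value`, `ts`).
#' @param discharge_ts Index discharge timestamp.
#' @param window_days Length of the follow-up window, default 180.
#' @return Numeric scalar in percent HbA1c, or `NA_real_`.
#' @export
select_followup_a1c <- function(labs, discharge_ts, window_days = 180) {
  stopifnot(window_days > 0)
  hits <- labs[labs$analyte == "hba1c" &
                 a1c_plausible(labs$value) &
                 labs$ts > discharge_ts &
                 labs$ts <= discharge_ts + window_days * 86400, , drop = FALSE]
  if (nrow(hits) == 0) return(NA_real_)
  latest <- hits$value[hits$ts == max(hits$ts)]
  if (length(latest) > 1) {
    warning("multiple HbA1c results at the same timestamp; using their mean",
            call. = FALSE)
  }
  mean(latest)
}

# plausibility guard, not a clinical rule: HbA1c outside (3, 20) % is treated
# as a recording artifact
a1c_plausible <- function(value) {
  !is.na(value) & value > 3 & value < 20
}

#' Glycemic control status from a follow-up HbA1c and a target
#'
#' Status is `missing` when no follow-up value exists, `controlled` when the
#' value (rounded to one decimal) is at or below the threshold, else
#' `uncontrolled`. Comparison happens on tenths of a percent as integers so
#' boundary values like 7.0 vs a 7.0 target are never misclassified by
#' floating-point representation.
#'
#' @param followup_a1c Numeric vector (possibly `NA`) in percent.
#' @param threshold Numeric vector of targets from
#'   [assign_control_target()].
#' @return Character vector over `{controlled, uncontrolled, missing}`.
#' @export
#' @examples
#' classify_control(c(6.9, 7.0, 8.6, NA), c(7.0, 7.0, 8.5, 7.5))
classify_control <- function(followup_a1c, threshold) {
  a10 <- as.integer(round_half_up(followup_a1c, 1) * 10)
  t10 <- as.integer(round_half_up(threshold, 1) * 10)
  dplyr::case_when(
    is.na(followup_a1c) ~ "missing",
    a10 <= t10 ~ "controlled",
    TRUE ~ "uncontrolled"
  )
}

#' Classify the full cascade for a diagnosed cohort
#'
#' Vectorized pipeline stage: for every cohort patient, detects
#' complications and CVD up to index discharge, assigns the individualized
#' HbA1c target, classifies linkage to care over the 90-day prescription
#' window, selects the follow-up HbA1c over the 180-day window, and derives
#' the control status. Semantically identical to mapping the per-patient
#' operations ([classify_linkage()], [select_followup_a1c()], ...) over the
#' cohort, which the test suite verifies.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param tables Named list of event tables.
#' @param codes A [code_config()].
#' @param linkage_window_days,followup_window_days Window overrides (days);
#'   must be positive.
#' @return Assignment tibble: strata columns plus `complicated`, `cvd`,
#'   `threshold`, `linked`, `followup_a1c`, `control_status`.
#' @export
classify_cascade <- function(cohort, tables, codes = code_config(),
                             linkage_window_days = 90,
                             followup_window_days = 180) {
  stopifnot(linkage_window_days > 0, followup_window_days > 0)
  if (nrow(cohort) == 0) {
    return(dplyr::mutate(cohort, complicated = logical(), cvd = logical(),
                         threshold = numeric(), linked = logical(),
                         followup_a1c = numeric(), control_status = character()))
  }
  dx <- dplyr::inner_join(
    tables$diagnoses,
    dplyr::select(cohort, "patient_id", "discharge_ts"),
    by = "patient_id", relationship = "many-to-one"
  )
  dx_norm <- normalize_icd10(dx$code)
  before_dc <- dx$recorded_ts <= dx$discharge_ts
  comp_ids <- unique(dx$patient_id[
    match_prefix_normalized(dx_norm, codes$complication_subcodes) & before_dc
  ])
  cvd_ids <- unique(dx$patient_id[
    match_prefix_normalized(dx_norm, codes$cvd_prefixes) & before_dc
  ])

  meds <- tables$medications
  linked_ids <- character()
  if (!is.null(meds) && nrow(meds) > 0) {
    meds <- dplyr::inner_join(
      meds, dplyr::select(cohort, "patient_id", "discharge_ts"),
      by = "patient_id", relationship = "many-to-one"
    )
    cls <- medication_classes(meds, codes)
    linked_ids <- unique(meds$patient_id[
      meds$kind == "prescription" &
        cls %in% linkage_classes() &
        meds$ts >= meds$discharge_ts &
        meds$ts <= meds$discharge_ts + linkage_window_days * 86400
    ])
  }

  labs <- tables$labs
  followup <- tibble::tibble(patient_id = character(), followup_a1c = numeric())
  if (!is.null(labs) && nrow(labs) > 0) {
    followup <- dplyr::inner_join(
      labs, dplyr::select(cohort, "patient_id", "discharge_ts"),
      by = "patient_id", relationship = "many-to-one"
    ) |>
      dplyr::filter(
        .data$analyte == "hba1c",
        a1c_plausible(.data$value),
        .data$ts > .data$discharge_ts,
        .data$ts <= .data$discharge_ts + followup_window_days * 86400
      ) |>
      dplyr::filter(.data$ts == max(.data$ts), .by = "patient_id") |>
      dplyr::summarise(followup_a1c = mean(.data$value), .by = "patient_id")
  }

  out <- cohort |>
    dplyr::mutate(
      complicated_dx = .data$patient_id %in% comp_ids,
      cvd = .data$patient_id %in% cvd_ids,
      complicated = .data$complicated_dx | .data$cvd,
      linked = .data$patient_id %in% linked_ids
    ) |>
    dplyr::left_join(followup, by = "patient_id")
  known_age <- !is.na(out$age_at_index)
  out$threshold <- NA_real_
  out$threshold[known_age] <-
    assign_control_target(out$age_at_index[known_age], out$complicated[known_age])
  out$control_status <- ifelse(
    known_age,
    classify_control(out$followup_a1c, out$threshold),
    "missing"
  )
  if (any(!known_age)) {
    warning(sum(!known_age), " patient(s) with unknown age routed to ",
            "control_status 'missing'", call. = FALSE)
  }
  dplyr::select(out, -"complicated_dx")
}
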