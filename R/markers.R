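#' HbA1c measured within 24 hours of admission
#'
#' `TRUE` when any HbA1c result carries a timestamp in
#' `[admit, admit + 24 h]`, both ends included (24 hours means exactly
#' 86,400 seconds). Any result timestamp counts; order-vs-collection
#' semantics are not distinguished.
#'
#' @param labs Lab events for one patient.
#' @param admit_ts Index admission timestamp.
#' @return Logical scalar.
#' @export
marker_a1c_measured <- function(labs, admit_ts) {
  any(labs$analyte == "hba1c" &
        labs$ts >= admit_ts & labs$ts <= admit_ts + 86400)
}

#' Insulin lispro administered within 24 hours of admission
#'
#' Keys on *administration* events only (the indicator is about drug given,
#' not ordered) whose drug name matches the configured lispro pattern, with
#' a timestamp in `[admit, admit + 24 h]`.
#'
#' @param medications Medication events for one patient.
#' @param admit_ts Index admission timestamp.
#' @param codes A [code_config()] carrying `lispro_pattern`.
#' @return Logical scalar.
#' @export
marker_lispro <- function(medications, admit_ts, codes = code_config()) {
  any(medications$kind == "administration" &
        grepl(codes$lispro_pattern, tolower(medications$drug_name)) &
        medications$ts >= admit_ts & medications$ts <= admit_ts + 86400)
}

#' Diabetes/endocrinology consult during the stay
#'
#' `TRUE` when any consult to the diabetes or endocrinology service falls
#' inside the closed admission interval `[admit, discharge]`.
#'
#' @param consults Consult events for one patient.
#' @param admit_ts,discharge_ts Index admission interval.
#' @return Logical scalar.
#' @export
marker_consult <- function(consults, admit_ts, discharge_ts) {
  any(consults$service == "diabetes_endocrinology" &
        consults$ts >= admit_ts & consults$ts <= discharge_ts)
}

#' Compute all inpatient glycemic-care markers for a cohort
#'
#' Vectorized computation of the three indicators and their composite
#' (`any_marker`, the OR of the three) for every index admission.
#' Equivalent to mapping [marker_a1c_measured()], [marker_lispro()] and
#' [marker_consult()] over patients.
#'
#' @param cohort Cohort tibble with `patient_id`, `admit_ts`,
#'   `discharge_ts`.
#' @param tables Named list of event tables (`labs`, `medications`,
#'   `consults`).
#' @param codes A [code_config()].
#' @return `cohort` with logical columns `a1c_measured_24h`, `lispro_24h`,
#'   `endo_consult`, `any_marker` appended.
#' @export
compute_markers <- function(cohort, tables, codes = code_config()) {
  window <- dplyr::select(cohort, "patient_id", "admit_ts", "discharge_ts")

  ids_in_window <- function(events, ok_event, end_col) {
    if (is.null(events) || nrow(events) == 0) return(character())
    ev <- dplyr::inner_join(events, window, by = "patient_id",
                            relationship = "many-to-one")
    unique(ev$patient_id[
      ok_event(ev) & ev$ts >= ev$admit_ts & ev$ts <= ev[[end_col]]
    ])
  }

  labs <- tables$labs
  a1c_ids <- if (is.null(labs) || nrow(labs) == 0) character() else {
    ev <- dplyr::inner_join(labs, window, by = "patient_id",
                            relationship = "many-to-one")
    unique(ev$patient_id[ev$analyte == "hba1c" &
                           ev$ts >= ev$admit_ts &
                           ev$ts <= ev$admit_ts + 86400])
  }
  meds <- tables$medications
  lispro_ids <- if (is.null(meds) || nrow(meds) == 0) character() else {
    ev <- dplyr::inner_join(meds, window, by = "patient_id",
                            relationship = "many-to-one")
    unique(ev$patient_id[ev$kind == "administration" &
                           grepl(codes$lispro_pattern, tolower(ev$drug_name)) &
                           ev$ts >= ev$admit_ts &
                           ev$ts <= ev$admit_ts + 86400])
  }
  consult_ids <- ids_in_window(
    tables$consults,
    function(ev) ev$service == "diabetes_endocrinology",
    "discharge_ts"
  )

  dplyr::mutate(
    cohort,
    a1c_measured_24h = .data$patient_id %in% a1c_ids,
    lispro_24h = .data$patient_id %in% lispro_ids,
    endo_consult = .data$patient_id %in% consult_ids,
    any_marker = .data$a1c_measured_24h | .data$lispro_24h | .data$endo_consult
  )
}
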