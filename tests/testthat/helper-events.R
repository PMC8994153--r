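# tiny event-table builders used across the suite; all timestamps UTC

utc <- function(x) as.POSIXct(x, tz = "UTC")

dx_events <- function(codes, when = "2018-03-05 10:00:00", pl = TRUE,
                      id = "P1") {
  tibble::tibble(
    patient_id = id, code = codes,
    on_problem_list = rep_len(pl, length(codes)),
    recorded_ts = rep_len(utc(when), length(codes))
  )
}

med_events <- function(drug, when, kind = "prescription", id = "P1") {
  tibble::tibble(patient_id = id, drug_name = drug,
                 kind = rep_len(kind, length(drug)),
                 ts = utc(when))
}

lab_events <- function(value, when, analyte = "hba1c", id = "P1") {
  tibble::tibble(patient_id = id, analyte = rep_len(analyte, length(value)),
                 value = value, ts = utc(when))
}

consult_events <- function(when, service = "diabetes_endocrinology",
                           id = "P1") {
  tibble::tibble(patient_id = id, service = rep_len(service, length(when)),
                 ts = utc(when))
}

patient_row <- function(id = "P1", sex = "female", race = "white",
                        birth = "1960-01-15", zip = "63101",
                        insurance = "Commercial PPO") {
  tibble::tibble(patient_id = id, sex = sex, race = race,
                 birth_date = as.Date(birth), zip_code = zip,
                 insurance_raw = insurance)
}

admission_row <- function(id = "P1", admit = "2018-03-03 08:00:00",
                          discharge = "2018-03-09 12:00:00",
                          admission_id = "A1") {
  tibble::tibble(patient_id = id, admission_id = admission_id,
                 admit_ts = utc(admit), discharge_ts = utc(discharge))
}

# small simulated world for end-to-end checks
small_sim <- function(n = 600, seed = 11, ...) {
  simulate_ehr(generator_config(n_patients = n, seed = seed, ...))
}
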