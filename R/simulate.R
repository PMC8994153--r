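#' Synthetic Promise Zone zip codes
#'
#' The zip list the synthetic generator uses to mark Promise Zone residence.
#' These are stand-in codes for a generic high-poverty urban core; any real
#' analysis must supply the actual designation list via
#' [code_config()]`$promise_zone_zips`.
#'
#' @return Character vector of 5-digit zips.
#' @export
synthetic_promise_zone_zips <- function() {
  c("63106", "63107", "63113", "63115", "63120", "63147")
}

synthetic_other_zips <- function() {
  c("63011", "63017", "63021", "63109", "63119", "63122", "63129")
}

#' Code configuration for the synthetic world
#'
#' [code_config()] with the synthetic Promise Zone zips wired in, so the
#' pipeline can be run on generator output without further setup.
#' @return A `code_config`.
#' @export
synthetic_code_config <- function() {
  code_config(promise_zone_zips = synthetic_promise_zone_zips())
}

#' Configuration of the synthetic EHR cohort generator
#'
#' Defaults are the published study's marginals: exclusion fractions from
#' the 93,433-patient funnel (3,875 gestational, 7,925 type 1), stratum
#' marginals from the diagnosed-cohort descriptive table, a global linkage
#' probability of 0.352, marker probabilities of 0.274 / 0.725 / 0.061, and
#' follow-up HbA1c missingness of 0.609 in the linked arm and 0.756 in the
#' unlinked arm (jointly compatible with the 70.4% overall missingness).
#' Complication and CVD prevalences and the HbA1c distribution are not
#' published; the defaults (40% complicated, 25% CVD, lognormal HbA1c with
#' median 7.5% and log-sd 0.2) are chosen once as realistic for an older
#' inpatient type 2 diabetes population.
#'
#' Strata and outcomes are independent by default (only marginals are
#' published); `p_linkage_promise_zone` optionally overrides linkage inside
#' the Promise Zone to inject a stratum-conditional effect.
#'
#' @param n_patients Number of patients to generate (before exclusions).
#' @param p_gestational,p_type1 Exclusion fractions.
#' @param sex_probs,race_probs,age_group_probs,insurance_probs Named
#'   probability vectors (must sum to 1).
#' @param p_promise_zone Probability of Promise Zone residence.
#' @param p_linkage Probability a diagnosed patient is linked to care.
#' @param p_linkage_promise_zone Optional Promise Zone linkage override.
#' @param p_marker_a1c,p_marker_lispro,p_marker_consult Inpatient marker
#'   probabilities.
#' @param p_missing_a1c_linked,p_missing_a1c_unlinked Follow-up HbA1c
#'   missingness by linkage arm.
#' @param p_complications,p_cvd Prevalence of diabetes complications and of
#'   cardiovascular disease.
#' @param a1c_meanlog,a1c_sdlog Lognormal parameters of the HbA1c value
#'   distribution (percent scale).
#' @param p_noise_rx Fraction of patients receiving a non-diabetes
#'   (statin) prescription post discharge — events that must never count as
#'   linkage.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 10000,
                             p_gestational = 3875 / 93433,
                             p_type1 = 7925 / 93433,
                             sex_probs = c(female = 39880, male = 41748,
                                           missing = 5) / 81633,
                             race_probs = c(white = 58291, black = 19141,
                                            other = 2625, missing = 1576) / 81633,
                             age_group_probs = c("18-44" = 5887, "45-64" = 28886,
                                                 ">=65" = 46860) / 81633,
                             insurance_probs = c(private = 28997, medicare = 31742,
                                                 medicaid = 14096,
                                                 uninsured_selfpay = 6798) / 81633,
                             p_promise_zone = 14309 / 81633,
                             p_linkage = 0.352,
                             p_linkage_promise_zone = NULL,
                             p_marker_a1c = 0.274,
                             p_marker_lispro = 0.725,
                             p_marker_consult = 0.061,
                             p_missing_a1c_linked = 17492 / 28716,
                             p_missing_a1c_unlinked = 40003 / 52917,
                             p_complications = 0.40,
                             p_cvd = 0.25,
                             a1c_meanlog = log(7.5),
                             a1c_sdlog = 0.20,
                             p_noise_rx = 0.30,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    p_gestational = p_gestational, p_type1 = p_type1,
    sex_probs = sex_probs, race_probs = race_probs,
    age_group_probs = age_group_probs, insurance_probs = insurance_probs,
    p_promise_zone = p_promise_zone,
    p_linkage = p_linkage, p_linkage_promise_zone = p_linkage_promise_zone,
    p_marker_a1c = p_marker_a1c, p_marker_lispro = p_marker_lispro,
    p_marker_consult = p_marker_consult,
    p_missing_a1c_linked = p_missing_a1c_linked,
    p_missing_a1c_unlinked = p_missing_a1c_unlinked,
    p_complications = p_complications, p_cvd = p_cvd,
    a1c_meanlog = a1c_meanlog, a1c_sdlog = a1c_sdlog,
    p_noise_rx = p_noise_rx,
    seed = as.integer(seed)
  )
  scalars <- c("p_gestational", "p_type1", "p_promise_zone", "p_linkage",
               "p_marker_a1c", "p_marker_lispro", "p_marker_consult",
               "p_missing_a1c_linked", "p_missing_a1c_unlinked",
               "p_complications", "p_cvd", "p_noise_rx")
  for (nm in scalars) {
    p <- cfg[[nm]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop("generator_config: ", nm, " must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$p_linkage_promise_zone) &&
      (cfg$p_linkage_promise_zone < 0 || cfg$p_linkage_promise_zone > 1)) {
    stop("generator_config: p_linkage_promise_zone must be in [0, 1]",
         call. = FALSE)
  }
  for (nm in c("sex_probs", "race_probs", "age_group_probs", "insurance_probs")) {
    v <- cfg[[nm]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9 || is.null(names(v))) {
      stop("generator_config: ", nm,
           " must be a named probability vector summing to 1", call. = FALSE)
    }
  }
  if (cfg$p_gestational + cfg$p_type1 >= 1) {
    stop("generator_config: exclusion fractions leave no diagnosed cohort",
         call. = FALSE)
  }
  if (cfg$n_patients < 1) stop("generator_config: n_patients must be >= 1",
                               call. = FALSE)
  structure(cfg, class = "generator_config")
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic event-level EHR cohort
#'
#' Emits the six event tables (patients, admissions, diagnoses,
#' medications, labs, consults) of a cohort with the statistical structure
#' the cascade analysis assumes. Every patient gets one admission of 2-10
#' days in 2010-2019; patients destined for exclusion carry gestational
#' (`O24`) or type 1 (`E10`) problem-list codes, all others a type 2
#' (`E11.x`) problem-list diagnosis inside the admission. Linked patients
#' receive a qualifying prescription uniformly in `[0, 90]` days after
#' discharge; patients with observed follow-up receive an HbA1c uniformly
#' in `(0, 180]` days (values lognormal, rounded to one decimal); the three
#' inpatient markers are emitted independently inside their windows. A
#' fraction of patients also receive a statin prescription — a medication
#' of class `other` that must never register as linkage.
#'
#' The per-patient ground truth (arm labels, marker draws) is attached as
#' the `truth` attribute for diagnostic use; tests recover parameters
#' through the pipeline, not from the attribute.
#'
#' @param config A [generator_config()].
#' @return Named list of six tibbles, with a `truth` attribute.
#' @export
simulate_ehr <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  day <- 86400

  group <- sample(
    c("gestational", "type1", "t2dm"), n, replace = TRUE,
    prob = c(config$p_gestational, config$p_type1,
             1 - config$p_gestational - config$p_type1)
  )
  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- sample_cat(n, config$sex_probs)
  race <- sample_cat(n, config$race_probs)
  agegrp <- sample_cat(n, config$age_group_probs)
  insurance <- sample_cat(n, config$insurance_probs)
  pz <- stats::runif(n) < config$p_promise_zone
  zip <- ifelse(pz,
                sample(synthetic_promise_zone_zips(), n, replace = TRUE),
                sample(synthetic_other_zips(), n, replace = TRUE))

  origin <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  admit_ts <- origin + stats::runif(n, 0, 9.4 * 365) * day
  los_days <- stats::runif(n, 2, 10)
  discharge_ts <- admit_ts + los_days * day

  # age drawn inside the band; the 5-360 day jitter keeps the completed-years
  # age exactly at the drawn integer despite leap-year drift
  age <- integer(n)
  age[agegrp == "18-44"] <- sample(18:44, sum(agegrp == "18-44"), replace = TRUE)
  age[agegrp == "45-64"] <- sample(45:64, sum(agegrp == "45-64"), replace = TRUE)
  age[agegrp == ">=65"] <- sample(65:90, sum(agegrp == ">=65"), replace = TRUE)
  birth_date <- as.Date(admit_ts) - round(age * 365.2425) -
    round(stats::runif(n, 5, 360))

  insurance_label <- c(
    private = "Commercial PPO", medicare = "Medicare Part A/B",
    medicaid = "Medicaid MO", uninsured_selfpay = "Self-pay"
  )[insurance]

  patients <- tibble::tibble(
    patient_id = patient_id,
    sex = ifelse(sex == "missing", NA_character_, sex),
    race = ifelse(race == "missing", NA_character_, race),
    birth_date = birth_date,
    zip_code = zip,
    insurance_raw = unname(insurance_label)
  )
  admissions <- tibble::tibble(
    patient_id = patient_id,
    admission_id = sprintf("A%06d", seq_len(n)),
    admit_ts = admit_ts,
    discharge_ts = discharge_ts
  )

  t2 <- group == "t2dm"
  complicated <- t2 & stats::runif(n) < config$p_complications
  cvd <- t2 & stats::runif(n) < config$p_cvd
  pl_code <- dplyr::case_when(
    group == "gestational" ~ "O24.419",
    group == "type1" ~ "E10.9",
    complicated ~ sample(c("E11.21", "E11.22", "E11.40", "E11.51", "E11.65"),
                         n, replace = TRUE),
    TRUE ~ "E11.9"
  )
  diagnoses <- tibble::tibble(
    patient_id = patient_id,
    code = pl_code,
    on_problem_list = TRUE,
    recorded_ts = admit_ts + stats::runif(n, 1, 24) * 3600
  )
  if (any(cvd)) {
    diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
      patient_id = patient_id[cvd],
      code = sample(c("I20.0", "I21.4", "I22.1", "I50.9"), sum(cvd),
                    replace = TRUE),
      on_problem_list = FALSE,
      recorded_ts = admit_ts[cvd] +
        stats::runif(sum(cvd), 0.1, 0.9) * los_days[cvd] * day
    ))
  }

  p_link <- rep(config$p_linkage, n)
  if (!is.null(config$p_linkage_promise_zone)) {
    p_link[pz] <- config$p_linkage_promise_zone
  }
  linked <- t2 & stats::runif(n) < p_link
  lispro <- t2 & stats::runif(n) < config$p_marker_lispro
  noise_rx <- stats::runif(n) < config$p_noise_rx

  link_drugs <- c("metformin", "insulin glargine", "glipizide",
                  "empagliflozin", "liraglutide", "sitagliptin")
  medications <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = patient_id[linked],
      drug_name = sample(link_drugs, sum(linked), replace = TRUE),
      kind = "prescription",
      ts = discharge_ts[linked] + stats::runif(sum(linked), 0, 90) * day
    ),
    tibble::tibble(
      patient_id = patient_id[lispro],
      drug_name = "insulin lispro",
      kind = "administration",
      ts = admit_ts[lispro] + stats::runif(sum(lispro), 0, 24) * 3600
    ),
    tibble::tibble(
      patient_id = patient_id[noise_rx],
      drug_name = "atorvastatin",
      kind = "prescription",
      ts = discharge_ts[noise_rx] + stats::runif(sum(noise_rx), 0, 90) * day
    )
  )
  medications$med_class <- classify_medication(medications$drug_name)

  draw_a1c <- function(k) {
    round_half_up(pmin(pmax(
      stats::rlnorm(k, config$a1c_meanlog, config$a1c_sdlog), 3.1), 19.9), 1)
  }
  a1c_24h <- t2 & stats::runif(n) < config$p_marker_a1c
  p_miss <- ifelse(linked, config$p_missing_a1c_linked,
                   config$p_missing_a1c_unlinked)
  has_followup <- t2 & stats::runif(n) >= p_miss
  labs <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = patient_id[a1c_24h],
      analyte = "hba1c",
      value = draw_a1c(sum(a1c_24h)),
      ts = admit_ts[a1c_24h] + stats::runif(sum(a1c_24h), 0, 24) * 3600
    ),
    tibble::tibble(
      patient_id = patient_id[has_followup],
      analyte = "hba1c",
      value = draw_a1c(sum(has_followup)),
      ts = discharge_ts[has_followup] +
        stats::runif(sum(has_followup), 1 / 24, 180) * day
    )
  )

  consult <- t2 & stats::runif(n) < config$p_marker_consult
  consults <- tibble::tibble(
    patient_id = patient_id[consult],
    service = "diabetes_endocrinology",
    ts = admit_ts[consult] +
      stats::runif(sum(consult), 0.05, 0.95) * los_days[consult] * day
  )

  tables <- list(
    patients = patients, admissions = admissions, diagnoses = diagnoses,
    medications = medications, labs = labs, consults = consults
  )
  attr(tables, "truth") <- tibble::tibble(
    patient_id = patient_id, group = group, linked = linked,
    complicated = complicated, cvd = cvd,
    a1c_measured_24h = a1c_24h, lispro_24h = lispro, endo_consult = consult,
    has_followup = has_followup
  )
  tables
}

#' Deterministic exclusion-funnel fixture
#'
#' Emits exactly 93,433 patients with no randomness: 3,875 carrying
#' gestational (`O24.419`) codes, a disjoint 7,925 carrying type 1
#' (`E10.9`) codes, and the remaining 81,633 carrying problem-list `E11.9`
#' diagnoses anchored inside their admissions — the published funnel's
#' input. Running [apply_exclusions()] on it reproduces the published final
#' cohort size.
#'
#' @return Named list of event tables (patients, admissions, diagnoses;
#'   empty medications/labs/consults).
#' @export
generate_exclusion_fixture <- function() {
  n <- 93433L
  n_gest <- 3875L
  n_t1 <- 7925L
  day <- 86400
  patient_id <- sprintf("P%06d", seq_len(n))
  group <- rep(c("gestational", "type1", "t2dm"),
               times = c(n_gest, n_t1, n - n_gest - n_t1))
  origin <- as.POSIXct("2015-01-01 08:00:00", tz = "UTC")
  admit_ts <- origin + (seq_len(n) %% 300L) * day
  patients <- tibble::tibble(
    patient_id = patient_id,
    sex = rep(c("female", "male"), length.out = n),
    race = "white",
    birth_date = as.Date("1955-06-15"),
    zip_code = "63101",
    insurance_raw = "Medicare Part A/B"
  )
  admissions <- tibble::tibble(
    patient_id = patient_id,
    admission_id = sprintf("A%06d", seq_len(n)),
    admit_ts = admit_ts,
    discharge_ts = admit_ts + 3 * day
  )
  diagnoses <- tibble::tibble(
    patient_id = patient_id,
    code = c(gestational = "O24.419", type1 = "E10.9", t2dm = "E11.9")[group],
    on_problem_list = TRUE,
    recorded_ts = admit_ts + 3600
  )
  empty_meds <- tibble::tibble(patient_id = character(), drug_name = character(),
                               kind = character(),
                               ts = as.POSIXct(character(), tz = "UTC"))
  list(
    patients = patients, admissions = admissions, diagnoses = diagnoses,
    medications = empty_meds,
    labs = tibble::tibble(patient_id = character(), analyte = character(),
                          value = numeric(),
                          ts = as.POSIXct(character(), tz = "UTC")),
    consults = tibble::tibble(patient_id = character(), service = character(),
                              ts = as.POSIXct(character(), tz = "UTC"))
  )
}
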