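#' Default medication classification map
#'
#' Maps lower-cased drug names to one of the three anti-diabetes medication
#' classes used by the linkage-to-care definition (`insulin`,
#' `noninsulin_injectable`, `oral_antidiabetic`). Names absent from the map
#' classify as `other` and never count toward linkage. The default covers the
#' common US formulary agents: insulins (lispro, glargine, aspart, regular,
#' NPH, detemir, degludec, glulisine), GLP-1 receptor agonists and amylin
#' analogues as noninsulin injectables, and metformin, sulfonylureas, DPP-4
#' inhibitors, SGLT2 inhibitors, thiazolidinediones, meglitinides and
#' alpha-glucosidase inhibitors as oral agents. Users with a local formulary
#' can supply their own map anywhere one is accepted.
#'
#' @return A tibble with columns `drug_name` (lower case) and `med_class`.
#' @export
#' @examples
#' default_medication_map()
default_medication_map <- function() {
  insulins <- c(
    "insulin lispro", "insulin glargine", "insulin aspart", "insulin regular",
    "insulin nph", "insulin detemir", "insulin degludec", "insulin glulisine",
    "insulin isophane", "insulin human"
  )
  noninsulin_inj <- c(
    "exenatide", "liraglutide", "dulaglutide", "semaglutide", "lixisenatide",
    "albiglutide", "pramlintide", "tirzepatide"
  )
  orals <- c(
    "metformin", "glipizide", "glyburide", "glimepiride", "tolbutamide",
    "sitagliptin", "saxagliptin", "linagliptin", "alogliptin",
    "empagliflozin", "canagliflozin", "dapagliflozin", "ertugliflozin",
    "pioglitazone", "rosiglitazone", "repaglinide", "nateglinide",
    "acarbose", "miglitol"
  )
  tibble::tibble(
    drug_name = c(insulins, noninsulin_inj, orals),
    med_class = c(
      rep("insulin", length(insulins)),
      rep("noninsulin_injectable", length(noninsulin_inj)),
      rep("oral_antidiabetic", length(orals))
    )
  )
}

#' Code-set configuration for cohort and cascade rules
#'
#' Bundles every configurable code set the pipeline uses: ICD-10 prefixes for
#' type 2 diabetes inclusion (`E11`), gestational (`O24`) and type 1 (`E10`)
#' exclusion, the diabetes-complication subcode range (`E11.2`-`E11.8`, with
#' `E11.9` the uncomplicated code), cardiovascular disease prefixes covering
#' angina (`I20`), myocardial infarction (`I21`, `I22`) and heart failure
#' (`I50`), the Promise Zone zip-code list, and the medication class map.
#'
#' ICD-9-era codes are not interpreted; a user whose extract spans the ICD-9
#' period can add ICD-9 prefixes to the relevant sets, but no defaults are
#' shipped for them.
#'
#' @param t2dm_prefixes Character, ICD-10 prefixes defining type 2 diabetes.
#' @param t1dm_prefixes Character, prefixes excluding type 1 diabetes.
#' @param gestational_prefixes Character, prefixes excluding diabetes in
#'   pregnancy.
#' @param complication_subcodes Character, prefixes marking diabetes with
#'   complications (used to pick the individualized HbA1c target).
#' @param uncomplicated_subcodes Character, prefixes for uncomplicated
#'   disease (documentation of the complement; not used as a predicate).
#' @param cvd_prefixes Character, prefixes defining cardiovascular disease.
#' @param promise_zone_zips Character vector of 5-digit zip codes counted as
#'   the Promise Zone.
#' @param medication_class_map Tibble with `drug_name`, `med_class` columns;
#'   see [default_medication_map()].
#' @param lispro_pattern Regular expression identifying insulin lispro among
#'   drug names, for the 24-hour administration marker.
#' @return A list of class `code_config`.
#' @export
code_config <- function(t2dm_prefixes = "E11",
                        t1dm_prefixes = "E10",
                        gestational_prefixes = "O24",
                        complication_subcodes = paste0("E11.", 2:8),
                        uncomplicated_subcodes = "E11.9",
                        cvd_prefixes = c("I20", "I21", "I22", "I50"),
                        promise_zone_zips = character(),
                        medication_class_map = default_medication_map(),
                        lispro_pattern = "lispro") {
  groups <- list(
    t2dm = normalize_icd10(t2dm_prefixes),
    t1dm = normalize_icd10(t1dm_prefixes),
    gestational = normalize_icd10(gestational_prefixes)
  )
  # the three inclusion/exclusion families must not overlap
  all_prefixes <- unlist(groups)
  for (i in seq_along(all_prefixes)) {
    others <- all_prefixes[-i]
    if (any(startsWith(all_prefixes[i], others))) {
      stop("code_config: t2dm/t1dm/gestational prefix sets must be pairwise disjoint",
           call. = FALSE)
    }
  }
  stopifnot(
    is.data.frame(medication_class_map),
    all(c("drug_name", "med_class") %in% names(medication_class_map))
  )
  bad <- setdiff(
    unique(medication_class_map$med_class),
    c("insulin", "noninsulin_injectable", "oral_antidiabetic", "other")
  )
  if (length(bad) > 0) {
    stop("code_config: unknown medication classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      t2dm_prefixes = groups$t2dm,
      t1dm_prefixes = groups$t1dm,
      gestational_prefixes = groups$gestational,
      complication_subcodes = normalize_icd10(complication_subcodes),
      uncomplicated_subcodes = normalize_icd10(uncomplicated_subcodes),
      cvd_prefixes = normalize_icd10(cvd_prefixes),
      promise_zone_zips = as.character(promise_zone_zips),
      medication_class_map = tibble::as_tibble(medication_class_map),
      lispro_pattern = lispro_pattern
    ),
    class = "code_config"
  )
}

#' Normalize an ICD-10 code or prefix
#'
#' Upper-cases and strips dots so that `"e11.9"`, `"E119"` and `"E11.9"`
#' compare equal. Codes must start with a letter; anything else is malformed.
#'
#' @param code Character vector of codes or prefixes.
#' @param strict If `TRUE` (default), malformed codes raise an error; if
#'   `FALSE` they become `NA`.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_icd10(c("e11.9", "I50"))
normalize_icd10 <- function(code, strict = TRUE) {
  out <- toupper(gsub(".", "", as.character(code), fixed = TRUE))
  ok <- grepl("^[A-Z]", out) & !is.na(out)
  if (any(!ok)) {
    if (strict) {
      stop("malformed ICD-10 code(s): ",
           paste(utils::head(code[!ok], 5), collapse = ", "), call. = FALSE)
    }
    out[!ok] <- NA_character_
  }
  out
}

#' Match ICD-10 codes against a prefix set
#'
#' Realizes the wildcard semantics of code families like `E11.xx`: a code
#' matches when, after upper-casing and dot removal of both sides, it begins
#' with any prefix in the set. Matching is idempotent under repeated
#' normalization and insensitive to dot placement and case.
#'
#' @param code Character vector of ICD-10 codes.
#' @param prefixes Character vector of prefixes (any dot/case convention).
#' @return Logical vector, one element per code.
#' @export
#' @examples
#' match_icd10_prefix(c("E11.9", "E10.1", "e11"), "E11")
match_icd10_prefix <- function(code, prefixes) {
  if (any(!nzchar(code) | is.na(code))) {
    stop("match_icd10_prefix: empty or missing code", call. = FALSE)
  }
  code <- normalize_icd10(code)
  prefixes <- normalize_icd10(prefixes)
  if (length(prefixes) == 0) {
    return(rep(FALSE, length(code)))
  }
  Reduce(`|`, lapply(prefixes, function(p) startsWith(code, p)))
}

#' Classify drug names into anti-diabetes medication classes
#'
#' Looks each (lower-cased, trimmed) drug name up in the medication class
#' map; unmapped names degrade to `"other"`, which never counts toward
#' linkage to care. Matching also accepts map entries appearing as a prefix
#' of a longer product string (e.g. `"metformin 500 mg tablet"`).
#'
#' @param drug_name Character vector of drug names as recorded.
#' @param map Medication class map tibble; defaults to
#'   [default_medication_map()].
#' @return Character vector of classes: `insulin`, `noninsulin_injectable`,
#'   `oral_antidiabetic`, or `other`.
#' @export
#' @examples
#' classify_medication(c("insulin lispro", "metformin", "atorvastatin"))
classify_medication <- function(drug_name, map = default_medication_map()) {
  key <- trimws(tolower(as.character(drug_name)))
  cls <- map$med_class[match(key, map$drug_name)]
  unresolved <- which(is.na(cls) & !is.na(key))
  if (length(unresolved) > 0) {
    # fall back to prefix match for product-strength strings
    for (i in unresolved) {
      hit <- which(startsWith(key[i], map$drug_name))
      if (length(hit) > 0) {
        cls[i] <- map$med_class[hit[which.max(nchar(map$drug_name[hit]))]]
      }
    }
  }
  cls[is.na(cls)] <- "other"
  cls
}

#' Linkage-eligible medication classes
#'
#' The three classes whose prescription within the post-discharge window
#' constitutes linkage to care.
#' @return Character vector of length 3.
#' @export
linkage_classes <- function() {
  c("insulin", "noninsulin_injectable", "oral_antidiabetic")
}
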