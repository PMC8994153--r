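#' Load the packaged published-count fixture
#'
#' The fixture is a JSON transcription of a published inpatient type 2
#' diabetes cascade study's aggregate counts: the exclusion funnel
#' (93,433 input; 3,875 gestational and 7,925 type 1 excluded; 81,633
#' diagnosed), the cascade flow (28,716 linked / 52,917 unlinked; the
#' linked arm's 7,076 / 4,148 / 17,492 control split), and the stratified
#' cascade table with printed one-decimal percents and significance marks.
#'
#' At load time the reconciliation invariants are enforced (flow and
#' exclusion sums must close exactly) and every cell's printed percent is
#' recomputed from its count and stage denominator; cells whose printed
#' percent does not reproduce are flagged in the `consistency` tibble
#' rather than dropped — published tables carry a small number of internal
#' inconsistencies (notably the uncontrolled-arm insurance column, whose
#' printed counts sum to 2,969 against a stated arm total of 4,148) that
#' callers should see, not silently inherit.
#'
#' @param path Path to the fixture JSON; defaults to the packaged resource.
#' @return A list of class `published_counts`: `exclusions`, `flow`
#'   (a [flow_counts()]; the unlinked arm's control split is `NA` except
#'   the missing cell, derived from the printed overall missingness),
#'   `table` (a `cascade_table` built from the counts), `cells` (raw
#'   tibble incl. printed percents and significance flags), `consistency`,
#'   `results_text`, `notes`.
#' @export
load_published_counts <- function(path = system.file("extdata", "published_counts.json",
                                                  package = "dmcascade")) {
  raw <- jsonlite::fromJSON(path)
  ex <- raw$exclusions
  if (ex$n_input - ex$n_gestational - ex$n_type1 != ex$n_final) {
    stop("published-count fixture corrupted: exclusion counts do not reconcile",
         call. = FALSE)
  }
  fl <- raw$flow
  if (fl$linked + fl$unlinked != fl$diagnosed ||
      fl$linked_controlled + fl$linked_uncontrolled + fl$linked_missing !=
        fl$linked) {
    stop("published-count fixture corrupted: flow counts do not reconcile", call. = FALSE)
  }
  unlinked_missing <- fl$overall_missing_a1c - fl$linked_missing
  flow <- flow_counts(
    n_diagnosed = fl$diagnosed, n_linked = fl$linked, n_unlinked = fl$unlinked,
    linked = c(fl$linked_controlled, fl$linked_uncontrolled, fl$linked_missing),
    unlinked = c(NA_real_, NA_real_, unlinked_missing)
  )
  cells <- tibble::as_tibble(raw$table2)
  totals <- c(diagnosed = fl$diagnosed, linked = fl$linked,
              unlinked = fl$unlinked, controlled = fl$linked_controlled,
              uncontrolled = fl$linked_uncontrolled,
              missing_a1c = fl$linked_missing)
  table <- cascade_table_from_counts(cells, totals, check_sums = FALSE)
  consistency <- purrr::map_dfr(stage_cols, function(s) {
    tibble::tibble(
      variable = cells$variable,
      category = cells$category,
      stage = s,
      n = cells[[paste0("n_", s)]],
      printed_pct = cells[[paste0("pct_", s)]],
      computed_pct = format_percent(cells[[paste0("n_", s)]], totals[[s]])
    )
  }) |>
    dplyr::mutate(consistent = .data$printed_pct == .data$computed_pct)
  structure(
    list(exclusions = ex, flow = flow, table = table, cells = cells,
         consistency = consistency, results_text = raw$results_text,
         notes = raw$notes),
    class = "published_counts"
  )
}

#' @export
print.published_counts <- function(x, ...) {
  cat("Published-count fixture\n")
  cat(sprintf("  exclusion funnel: %d -> %d\n",
              x$exclusions$n_input, x$exclusions$n_final))
  print(x$flow)
  cat(sprintf("  %d table cells, %d with printed percents inconsistent with\n",
              nrow(x$consistency), sum(!x$consistency$consistent)))
  cat("  their stage denominator (see $consistency)\n")
  invisible(x)
}
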