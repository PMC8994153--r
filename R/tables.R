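#' One-decimal percent string under the table convention
#'
#' Percentages print with one decimal, rounded half up; anything rounding
#' below 1.0 (including exact zero) prints as `"<1.0"`, matching the
#' published table style.
#'
#' @param numerator,denominator Count vectors; the denominator must be
#'   positive.
#' @return Character vector of formatted percents (no percent sign); `NA`
#'   numerators give `NA`.
#' @export
#' @examples
#' format_percent(c(28716, 0), c(81633, 10))
format_percent <- function(numerator, denominator) {
  if (any(denominator <= 0 | is.na(denominator))) {
    stop("format_percent: denominator must be positive", call. = FALSE)
  }
  pct <- round_half_up(100 * numerator / denominator, 1)
  out <- ifelse(pct < 1, "<1.0", sprintf("%.1f", pct))
  out[is.na(numerator)] <- NA_character_
  out
}

flow_arm_names <- c("controlled", "uncontrolled", "missing")

#' Construct cascade flow counts
#'
#' Validates the two conservation invariants: linked + unlinked = diagnosed,
#' and controlled + uncontrolled + missing = arm total within each linkage
#' arm. Arm splits may be `NA` (published sources do not always print the
#' unlinked arm's control split); validation then applies only to the known
#' cells.
#'
#' @param n_diagnosed,n_linked,n_unlinked Stage totals.
#' @param linked,unlinked Numeric length-3 vectors (controlled,
#'   uncontrolled, missing), possibly `NA`.
#' @return A `flow_counts` object.
#' @export
flow_counts <- function(n_diagnosed, n_linked, n_unlinked,
                        linked = rep(NA_real_, 3), unlinked = rep(NA_real_, 3)) {
  stopifnot(length(linked) == 3, length(unlinked) == 3)
  names(linked) <- names(unlinked) <- flow_arm_names
  if (n_linked + n_unlinked != n_diagnosed) {
    stop("flow_counts: linked + unlinked != diagnosed", call. = FALSE)
  }
  for (arm in list(c(sum(linked), n_linked), c(sum(unlinked), n_unlinked))) {
    if (!is.na(arm[1]) && arm[1] != arm[2]) {
      stop("flow_counts: controlled + uncontrolled + missing != arm total",
           call. = FALSE)
    }
  }
  structure(
    list(n_diagnosed = n_diagnosed, n_linked = n_linked,
         n_unlinked = n_unlinked, linked = linked, unlinked = unlinked),
    class = "flow_counts"
  )
}

#' Flow counts from patient-level cascade assignments
#'
#' Tallies the diagnosed total, the linked/unlinked split, and the
#' controlled/uncontrolled/missing split within each arm.
#'
#' @param assignments Assignment tibble from [classify_cascade()].
#' @return A [flow_counts()] object.
#' @export
build_flow_counts <- function(assignments) {
  arm <- function(linked_value) {
    sub <- assignments$control_status[assignments$linked == linked_value]
    vapply(flow_arm_names, function(s) sum(sub == s), numeric(1))
  }
  flow_counts(
    n_diagnosed = nrow(assignments),
    n_linked = sum(assignments$linked),
    n_unlinked = sum(!assignments$linked),
    linked = arm(TRUE),
    unlinked = arm(FALSE)
  )
}

#' @export
print.flow_counts <- function(x, ...) {
  fmt_arm <- function(v) paste(
    sprintf("%s %s", flow_arm_names,
            ifelse(is.na(v), "?", format(v, big.mark = ","))),
    collapse = ", ")
  cat(sprintf("Diagnosed  %s\n", format(x$n_diagnosed, big.mark = ",")))
  cat(sprintf("  Linked   %s (%s)\n", format(x$n_linked, big.mark = ","),
              format_percent(x$n_linked, x$n_diagnosed)))
  cat(sprintf("    %s\n", fmt_arm(x$linked)))
  cat(sprintf("  Unlinked %s (%s)\n", format(x$n_unlinked, big.mark = ","),
              format_percent(x$n_unlinked, x$n_diagnosed)))
  cat(sprintf("    %s\n", fmt_arm(x$unlinked)))
  invisible(x)
}

stage_cols <- c("diagnosed", "linked", "unlinked",
                "controlled", "uncontrolled", "missing_a1c")

default_table_variables <- function() {
  c("sex", "race", "age_group", "promise_zone", "insurance",
    "a1c_measured_24h", "lispro_24h", "endo_consult", "any_marker")
}

#' Stratified cascade table from patient-level assignments
#'
#' Builds the published reporting layout: one row per variable category
#' (explicit `missing` rows included) and six stage columns — diagnosed,
#' linked, unlinked, and the controlled / uncontrolled / missing-HbA1c split
#' of the linked arm. Percentages in the first three columns denominate on
#' that stage's total; the three control columns denominate on their own
#' linked subpopulation totals (the published footnote convention). Binary
#' variables (Promise Zone, the care markers) contribute a single `yes` row
#' and are exempt from the partition sum check.
#'
#' @param assignments Assignment tibble with marker columns (see
#'   [classify_cascade()] and [compute_markers()]).
#' @param variables Character vector of stratum/marker column names.
#' @return A `cascade_table`: tibble of counts (`n_<stage>`) and percent
#'   strings (`pct_<stage>`) with a `totals` attribute.
#' @export
cascade_table <- function(assignments, variables = default_table_variables()) {
  stopifnot(all(variables %in% names(assignments)))
  totals <- c(
    diagnosed = nrow(assignments),
    linked = sum(assignments$linked),
    unlinked = sum(!assignments$linked),
    controlled = sum(assignments$linked & assignments$control_status == "controlled"),
    uncontrolled = sum(assignments$linked & assignments$control_status == "uncontrolled"),
    missing_a1c = sum(assignments$linked & assignments$control_status == "missing")
  )
  in_stage <- list(
    diagnosed = rep(TRUE, nrow(assignments)),
    linked = assignments$linked,
    unlinked = !assignments$linked,
    controlled = assignments$linked & assignments$control_status == "controlled",
    uncontrolled = assignments$linked & assignments$control_status == "uncontrolled",
    missing_a1c = assignments$linked & assignments$control_status == "missing"
  )
  rows <- purrr::map_dfr(variables, function(v) {
    x <- assignments[[v]]
    binary <- is.logical(x)
    cats <- if (binary) "yes" else sort(unique(as.character(x)))
    member <- if (binary) list(yes = x) else
      stats::setNames(lapply(cats, function(k) as.character(x) == k), cats)
    purrr::map_dfr(cats, function(k) {
      counts <- vapply(stage_cols,
                       function(s) sum(member[[k]] & in_stage[[s]]), numeric(1))
      tibble::tibble(variable = v, category = k, binary = binary,
                     !!!stats::setNames(as.list(counts), paste0("n_", stage_cols)))
    })
  })
  new_cascade_table(rows, totals, check_sums = TRUE)
}

#' Stratified cascade table from pre-aggregated counts
#'
#' The aggregate-input path, used with published count fixtures where
#' patient-level data are unavailable. Cells absent from the source are `NA`
#' and tolerated; the partition sum check is optional because printed tables
#' sometimes carry internal inconsistencies that the caller may want to
#' surface rather than fail on.
#'
#' @param cells Tibble with `variable`, `category`, optional logical
#'   `binary`, and count columns `n_diagnosed`, `n_linked`, `n_unlinked`,
#'   `n_controlled`, `n_uncontrolled`, `n_missing_a1c` (any may be `NA`).
#' @param totals Named numeric vector of the six stage totals.
#' @param check_sums Validate that non-binary variables partition each stage
#'   total.
#' @return A `cascade_table`.
#' @export
cascade_table_from_counts <- function(cells, totals, check_sums = FALSE) {
  if (!"binary" %in% names(cells)) cells$binary <- FALSE
  needed <- paste0("n_", stage_cols)
  missing_cols <- setdiff(needed, names(cells))
  for (m in missing_cols) cells[[m]] <- NA_real_
  new_cascade_table(
    dplyr::select(cells, "variable", "category", "binary",
                  dplyr::all_of(needed)),
    totals[stage_cols], check_sums = check_sums
  )
}

new_cascade_table <- function(rows, totals, check_sums) {
  stopifnot(all(stage_cols %in% names(totals)))
  if (check_sums) {
    for (v in unique(rows$variable[!rows$binary])) {
      sub <- rows[rows$variable == v, ]
      for (s in stage_cols) {
        col <- sub[[paste0("n_", s)]]
        if (!anyNA(col) && sum(col) != totals[[s]]) {
          stop(sprintf("cascade_table: %s categories sum to %d, not the %s total %d",
                       v, sum(col), s, totals[[s]]), call. = FALSE)
        }
      }
    }
  }
  for (s in stage_cols) {
    # an empty stage (e.g. nobody controlled yet) has no defined percents
    rows[[paste0("pct_", s)]] <- if (totals[[s]] > 0) {
      format_percent(rows[[paste0("n_", s)]], totals[[s]])
    } else {
      rep(NA_character_, nrow(rows))
    }
  }
  structure(rows, totals = totals,
            class = c("cascade_table", class(tibble::tibble())))
}

#' Stage totals of a cascade table
#' @param table A `cascade_table`.
#' @return Named numeric vector of the six stage totals.
#' @export
table_totals <- function(table) attr(table, "totals")

#' Render a cascade table as aligned text
#'
#' Human-readable rendering with `n (pct)` cells; significance marks from
#' [stage_comparison_suite()] can be appended by the caller via the
#' `marks` argument (a tibble with `variable`, `category`, `stage`,
#' `significant`).
#'
#' @param table A `cascade_table`.
#' @param marks Optional significance marks.
#' @return Character vector of lines.
#' @export
format_cascade_table <- function(table, marks = NULL) {
  totals <- table_totals(table)
  cell <- function(n, pct, star) {
    out <- ifelse(is.na(n), "-",
                  sprintf("%s (%s)%s", format(n, big.mark = ",", trim = TRUE),
                          pct, ifelse(star, "*", "")))
    out
  }
  body <- tibble::tibble(
    Variable = table$variable,
    Category = table$category
  )
  for (s in stage_cols) {
    star <- rep(FALSE, nrow(table))
    if (!is.null(marks)) {
      key <- paste(table$variable, table$category, s)
      mk <- marks[marks$significant, , drop = FALSE]
      star <- key %in% paste(mk$variable, mk$category, mk$stage)
    }
    body[[s]] <- cell(table[[paste0("n_", s)]], table[[paste0("pct_", s)]], star)
  }
  header <- sprintf("%s (N=%s)", names(totals),
                    format(unname(totals), big.mark = ",", trim = TRUE))
  names(body)[-(1:2)] <- header
  widths <- vapply(names(body), function(nm) max(nchar(c(nm, body[[nm]]))),
                   numeric(1))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  lines <- c(
    paste(mapply(pad, names(body), widths), collapse = "  "),
    paste(mapply(pad, rep("-", ncol(body)), widths), collapse = "  "),
    apply(mapply(pad, body, widths), 1, paste, collapse = "  ")
  )
  unname(lines)
}

#' @export
print.cascade_table <- function(x, ...) {
  cat(format_cascade_table(x), sep = "\n")
  invisible(x)
}
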