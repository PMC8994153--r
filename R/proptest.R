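#' Pooled two-sample test of equal proportions
#'
#' The classical two-sided z test with pooled variance:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with
#' `p = (x1 + x2)/(n1 + n2)`, and `chi2 = z^2`, which equals the Pearson
#' chi-square statistic of the equivalent 2x2 table without continuity
#' correction. The optional Yates-style correction subtracts
#' `(1/n1 + 1/n2)/2` from `|p1 - p2|`, floored at zero; it is off by
#' default. A degenerate pooled proportion of exactly 0 or 1 yields `z = 0`,
#' `p = 1`, flagged.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two samples.
#' @param continuity_correction Apply the continuity correction.
#' @return A `prop_test_result` list: `x1`, `n1`, `x2`, `n2`, `p1_hat`,
#'   `p2_hat`, `pooled_p`, `z`, `chi2`, `p_two_sided`, `p_formatted`,
#'   `degenerate`.
#' @export
#' @examples
#' two_prop_test(39880, 81633, 13814, 28716)
two_prop_test <- function(x1, n1, x2, n2, continuity_correction = FALSE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  degenerate <- pooled <= 0 || pooled >= 1
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    diff <- p1 - p2
    if (continuity_correction) {
      diff <- sign(diff) * max(0, abs(diff) - (1 / n1 + 1 / n2) / 2)
    }
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
         p1_hat = p1, p2_hat = p2, pooled_p = pooled,
         z = z, chi2 = z^2, p_two_sided = p,
         p_formatted = format_p(p), degenerate = degenerate),
    class = "prop_test_result"
  )
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("Two-sample equality of proportions (pooled z)\n"))
  cat(sprintf("  p1 = %d/%d = %.4f   p2 = %d/%d = %.4f\n",
              x$x1, x$n1, x$p1_hat, x$x2, x$n2, x$p2_hat))
  cat(sprintf("  z = %.4f   chi2 = %.4f   P = %s%s\n",
              x$z, x$chi2, x$p_formatted,
              if (x$degenerate) "   [degenerate pooled proportion]" else ""))
  invisible(x)
}

#' Format a p-value in journal style
#'
#' Below .001 prints `"<.001"`; otherwise two decimals with no leading zero
#' (`.03`, `1.00`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.0297, 0.00001, 1))
format_p <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- sub("^0", "", sprintf("%.2f", p))
  out[p < 0.001] <- "<.001"
  out
}

stage_pairs <- function() {
  list(
    diagnosed_vs_linked = c("diagnosed", "linked"),
    diagnosed_vs_unlinked = c("diagnosed", "unlinked"),
    linked_vs_controlled = c("linked", "controlled"),
    linked_vs_uncontrolled = c("linked", "uncontrolled"),
    linked_vs_missing_a1c = c("linked", "missing_a1c")
  )
}

#' Stage-to-stage comparison suite over a cascade table
#'
#' For every category and every adjacent stage pair — diagnosed vs linked,
#' diagnosed vs unlinked, and linked vs each glycemic-control column — runs
#' the pooled two-proportion test on (category count, stage total) pairs and
#' marks significance at p < .05. Cells absent from the table (`NA` counts)
#' are skipped. No multiple-testing adjustment is applied by default,
#' mirroring common reporting practice; `bonferroni = TRUE` divides the
#' significance level by the number of tests performed.
#'
#' @param table A `cascade_table`.
#' @param alpha Significance level for the `significant` mark.
#' @param continuity_correction Passed to [two_prop_test()].
#' @param bonferroni Divide `alpha` by the number of comparisons.
#' @return Tibble: `variable`, `category`, `comparison`, `stage` (the later
#'   stage of the pair), `x1`, `n1`, `x2`, `n2`, `z`, `chi2`, `p`,
#'   `p_formatted`, `significant`.
#' @export
stage_comparison_suite <- function(table, alpha = 0.05,
                                   continuity_correction = FALSE,
                                   bonferroni = FALSE) {
  totals <- table_totals(table)
  rows <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    purrr::map_dfr(names(stage_pairs()), function(cmp) {
      st <- stage_pairs()[[cmp]]
      x1 <- table[[paste0("n_", st[1])]][i]
      x2 <- table[[paste0("n_", st[2])]][i]
      n1 <- totals[[st[1]]]
      n2 <- totals[[st[2]]]
      if (is.na(x1) || is.na(x2) || n1 == 0 || n2 == 0) {
        return(tibble::tibble())
      }
      tt <- two_prop_test(x1, n1, x2, n2,
                          continuity_correction = continuity_correction)
      tibble::tibble(
        variable = table$variable[i], category = table$category[i],
        comparison = cmp, stage = st[2],
        x1 = x1, n1 = n1, x2 = x2, n2 = n2,
        z = tt$z, chi2 = tt$chi2, p = tt$p_two_sided,
        p_formatted = tt$p_formatted
      )
    })
  })
  level <- if (bonferroni && nrow(rows) > 0) alpha / nrow(rows) else alpha
  rows$significant <- rows$p < level
  rows
}
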