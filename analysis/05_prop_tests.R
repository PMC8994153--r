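#!/usr/bin/env Rscript
# Step 5 — stage-to-stage equality-of-proportions tests.
#
# Pooled two-sample z tests (equivalently 1-df chi-square) comparing each
# category's share between adjacent cascade stages; no continuity
# correction and no multiplicity adjustment, matching the reporting style
# the package reproduces.
suppressMessages(library(dmcascade))

assignments <- readr::read_csv("results/pipeline/assignments.csv",
                               show_col_types = FALSE)
suite <- stage_comparison_suite(cascade_table(assignments))
readr::write_csv(suite, "results/prop_tests.csv")

sig <- suite[suite$significant, ]
cat(sprintf("%d of %d stage comparisons significant at p < .05\n",
            nrow(sig), nrow(suite)))
if (nrow(sig) > 0) {
  print(as.data.frame(sig[, c("variable", "category", "comparison",
                              "z", "p_formatted")]), row.names = FALSE)
}
cat("wrote results/prop_tests.csv\n")
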