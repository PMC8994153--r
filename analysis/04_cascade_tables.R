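#!/usr/bin/env Rscript
# Step 4 — aggregate into the cascade reporting structures.
#
# Builds the flow counts (diagnosed -> linked/unlinked -> control arms) and
# the stratified cascade table with the published denominator conventions:
# stage columns denominate on stage totals, the control columns on the
# linked arm's subpopulations.
suppressMessages(library(dmcascade))

assignments <- readr::read_csv("results/pipeline/assignments.csv",
                               show_col_types = FALSE)
flow <- build_flow_counts(assignments)
print(flow)

tbl <- cascade_table(assignments)
marks <- stage_comparison_suite(tbl)
writeLines(format_cascade_table(tbl, marks = marks),
           "results/cascade_table.txt")
readr::write_csv(tibble::as_tibble(tbl), "results/cascade_table.csv")
cat("\nwrote results/cascade_table.{csv,txt} (asterisks mark p < .05",
    "against the previous stage)\n")
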