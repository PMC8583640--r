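#!/usr/bin/env Rscript
# Deterministic risk assessment over the synthetic cohort: per-child
# average daily doses and hazard quotients for all 15 metal x pathway
# cells, pathway contributions, and the cohort percentile grid
# (HQ / HI / HIt at P5, median, P95).

suppressPackageStartupMessages(library(metalrisk))
dir.create("results", showWarnings = FALSE)

seed <- 1104
cohort <- if (file.exists("results/cohort.csv")) {
  read_cohort("results/cohort.csv")
} else generate_cohort(cohort_config(seed = seed))

rfd <- read_rfd_table()
records <- assess_cohort(cohort, rfd)

grid <- risk_table(records)
write_risk_summary(grid, "results/risk_summary.tsv", seed = seed)

con <- cohort_pathway_contributions(records)
write.table(format(con, digits = 4), "results/contributions.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cell <- function(m, p, pc) grid$hq_2sf[grid$metal == m & grid$pathway == p &
                                         grid$percentile == pc]
cat("Cohort percentile grid written (raw + 2 s.f. columns).\n")
cat(sprintf("Median total hazard index HIt = %.2g (published study: 1.9;\n",
            cell("Total", "Sum", 50)),
    "both exceed the acceptability threshold of 1).\n")
cat(sprintf("Median Pb hazard index = %.2g; Pb is the dominant risk element.\n",
            cell("Pb", "Sum", 50)))
food <- con[con$pathway == "food", ]
cat(sprintf("Food dominates the oral dose for every metal: fractions %.1f-%.1f%%.\n",
            100 * min(food$fraction), 100 * max(food$fraction)))
cat("written: results/risk_summary.tsv, results/contributions.tsv\n")
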