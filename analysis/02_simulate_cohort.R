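#!/usr/bin/env Rscript
# Generate the default synthetic cohort: 60 children (30 aged 3-6, 30 aged
# 7-12), per-child exposure factors from the group-specific fits and
# per-child concentrations from the pooled fits with the diet Pb/Cr age
# effect, then check its marginals against the published calibration
# targets.

suppressPackageStartupMessages(library(metalrisk))
dir.create("results", showWarnings = FALSE)

seed <- 1104
cohort <- generate_cohort(cohort_config(seed = seed))
write_cohort(cohort, "results/cohort.csv")

rep <- summarize_cohort(cohort)
write.table(format(rep, digits = 4), "results/cohort_calibration.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

pooled <- rep[rep$grouping == "pooled", ]
cat(sprintf("Cohort of %d children generated (seed %d).\n",
            nrow(cohort$factors), seed))
cat(sprintf("Pooled medians within 20%% of target: %d/%d variables.\n",
            sum(abs(pooled$rel_dev) < 0.20), nrow(pooled)))
worst <- pooled[which.max(abs(pooled$rel_dev)), ]
cat(sprintf("Worst pooled deviation in this cohort: %s at %+.1f%%.\n",
            worst$variable, 100 * worst$rel_dev))
cat("(Single-cohort medians at n = 60 are noisy for the wide lognormals;\n",
    "averaged over many seeds the pooled medians sit within 20% of target,\n",
    "soil ingestion being the documented structural exception: the\n",
    "published pooled median is inconsistent with its own group medians.)\n")
nd <- subset(cohort$concentrations, nondetect)
cat(sprintf("Nondetects: %d diet-As values substituted with zero.\n", nrow(nd)))
cat("written: results/cohort.csv, results/cohort_calibration.tsv\n")
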