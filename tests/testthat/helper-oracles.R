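# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and wilcox.test/quantile) wherever they stand
# as the cross-check for one.

# Exact two-sided Mann-Whitney p value by enumeration of all possible
# assignments of the pooled ranks to the first sample (no ties assumed).
enumerate_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  # with no ties the pooled ranks are 1..(n+m); enumerate which of them
  # land in the first sample
  sets <- utils::combn(n + m, n)
  u_all <- apply(sets, 2, function(idx) sum(idx) - n * (n + 1) / 2)
  tail <- if (u_obs <= n * m / 2) mean(u_all <= u_obs) else mean(u_all >= u_obs)
  min(1, 2 * tail)
}

# Brute-force percentile grid for tiny cohorts: per-child sums first, then
# percentiles across children, computed with explicit loops.
brute_force_risk_cell <- function(records, metal, pathway, prob) {
  ids <- unique(records$child_id)
  per_child <- vapply(ids, function(id) {
    sub <- records[records$child_id == id, ]
    if (metal != "Total") sub <- sub[sub$metal == metal, ]
    if (pathway != "Sum") sub <- sub[sub$pathway == pathway, ]
    sum(sub$hq)
  }, numeric(1))
  unname(stats::quantile(per_child, prob, type = 7))
}

# A tiny deterministic cohort-like object for risk_core tests.
manual_cohort <- function(factors, concentrations) {
  structure(list(factors = factors, concentrations = concentrations),
            class = "metal_cohort")
}

# Calibration tables in which every distribution collapses to a point mass
# (median = mean, p25 = median = p75): children carry the medians exactly.
point_mass_tables <- function() {
  ef <- read_exposure_factor_table()
  ef$mean <- ef$median
  cs <- read_concentration_summary()
  cs$p25 <- cs$median
  cs$p75 <- cs$median
  list(ef = ef, cs = cs)
}
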