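test_that("identical configs generate identical cohorts", {
  c1 <- generate_cohort(cohort_config(seed = 12))
  c2 <- generate_cohort(cohort_config(seed = 12))
  expect_identical(c1$factors, c2$factors)
  expect_identical(c1$concentrations, c2$concentrations)
  c3 <- generate_cohort(cohort_config(seed = 13))
  expect_false(identical(c1$factors, c3$factors))
})

test_that("cohort structure is complete and physically bounded", {
  cohort <- generate_cohort(cohort_config(seed = 4))
  expect_equal(nrow(cohort$factors), 60)
  expect_equal(as.vector(table(cohort$factors$age_group)[c("y3_6", "y7_12")]),
               c(30L, 30L))
  expect_equal(nrow(cohort$concentrations), 60 * 15)
  # exactly one record per (child, metal, medium)
  key <- with(cohort$concentrations, paste(child_id, metal, medium))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(cohort$factors$body_weight >= 8 &
                    cohort$factors$body_weight <= 80))
  expect_true(all(cohort$concentrations$value >= 0))
  with_intake <- unlist(cohort$factors[, c("food_ingestion",
                                           "soil_ingestion", "water_intake")])
  expect_true(all(with_intake >= 0))
})

test_that("point-mass calibration yields children carrying the medians", {
  pm <- point_mass_tables()
  cfg <- cohort_config(n_per_group = c(y3_6 = 1, y7_12 = 1), seed = 1,
                       concentration_summary = pm$cs,
                       exposure_factor_table = pm$ef,
                       nondetect_prob = tibble::tibble(
                         metal = character(), medium = character(),
                         prob = numeric()))
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$factors), 2)
  expect_equal(cohort$factors$body_weight, c(17, 32))
  expect_equal(cohort$factors$soil_ingestion, c(40, 66))
  # diet Pb carries the age multiplier on top of the pooled median
  pb_food <- cohort$concentrations[cohort$concentrations$metal == "Pb" &
                                     cohort$concentrations$medium == "food", ]
  expect_equal(pb_food$value[pb_food$age_group == "y3_6"], 0.10 * 1.8)
  expect_equal(pb_food$value[pb_food$age_group == "y7_12"], 0.10 / 1.8)
  soil_mn <- cohort$concentrations[cohort$concentrations$metal == "Mn" &
                                     cohort$concentrations$medium == "soil", ]
  expect_equal(soil_mn$value, c(344.19, 344.19))
})

test_that("older children ingest more soil in nearly every cohort", {
  hits <- vapply(1:200, function(s) {
    cohort <- generate_cohort(cohort_config(seed = s))
    f <- cohort$factors
    median(f$soil_ingestion[f$age_group == "y7_12"]) >
      median(f$soil_ingestion[f$age_group == "y3_6"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pooled soil Pb median recovers the published value", {
  meds <- vapply(1:200, function(s) {
    cohort <- generate_cohort(cohort_config(seed = s))
    conc <- cohort$concentrations
    median(conc$value[conc$metal == "Pb" & conc$medium == "soil"])
  }, numeric(1))
  expect_lt(abs(mean(meds) - 72.58) / 72.58, 0.15)
  expect_true(all(abs(meds - 72.58) / 72.58 < 0.15))
})

test_that("calibration report has full structure and zero spread for clones", {
  cohort <- generate_cohort(cohort_config(seed = 2))
  rep <- summarize_cohort(cohort)
  # (15 concentrations + 4 factors) x (pooled + 2 groups)
  expect_equal(nrow(rep), 19 * 3)
  expect_true(all(c("pooled", "y3_6", "y7_12") %in% rep$grouping))
  expect_true(all(rep$p25 <= rep$median & rep$median <= rep$p75))

  pm <- point_mass_tables()
  clones <- generate_cohort(cohort_config(
    n_per_group = c(y3_6 = 5, y7_12 = 5), seed = 1,
    concentration_summary = pm$cs, exposure_factor_table = pm$ef,
    nondetect_prob = tibble::tibble(metal = character(),
                                    medium = character(), prob = numeric())))
  rep_pm <- summarize_cohort(clones)
  # children are identical within each group; pooled rows still mix the
  # two group medians, so zero spread is a per-group property
  grp <- rep_pm[rep_pm$grouping != "pooled", ]
  expect_true(all(grp$p75 - grp$p25 == 0))
  expect_true(all(abs(grp$rel_dev) < 1e-12))
})

test_that("medians converge to calibration targets at n = 600", {
  cohort <- generate_cohort(cohort_config(
    n_per_group = c(y3_6 = 300, y7_12 = 300), seed = 21))
  rep <- summarize_cohort(cohort)
  # per-group medians converge tightly to the group fits (lognormal rows
  # hit the published median; mean-below-median rows centre on the mean)
  ef <- cohort$config$exposure_factor_table
  for (g in c("y3_6", "y7_12")) {
    for (param in c("body_weight", "food_ingestion", "soil_ingestion",
                    "water_intake")) {
      row <- ef[ef$group == g & ef$parameter == param, ]
      centre <- dist_median(suppressWarnings(
        fit_median_mean(row$median, row$mean)))
      got <- rep$median[rep$grouping == g & rep$variable == param]
      expect_lt(abs(got - centre) / centre, 0.05,
                label = paste(g, param, "median rel dev"))
    }
  }
  pooled <- rep[rep$grouping == "pooled", ]
  # soil ingestion is the documented exception: the published pooled
  # median (41) is inconsistent with the published group medians (40/66),
  # so a generator calibrated per group pools to ~49 and the pooled sample
  # median wanders the density gap between the two group modes
  soil <- pooled$variable == "soil_ingestion"
  expect_true(all(abs(pooled$rel_dev[!soil]) < 0.20),
              info = paste(pooled$variable[!soil][
                abs(pooled$rel_dev[!soil]) >= 0.20], collapse = ", "))
  expect_lt(abs(pooled$rel_dev[soil]), 0.35)
})

test_that("nondetect censoring follows the configured substitution rule", {
  cfg0 <- cohort_config(seed = 31)
  cohort <- generate_cohort(cfg0)
  as_food <- cohort$concentrations[cohort$concentrations$metal == "As" &
                                     cohort$concentrations$medium == "food", ]
  expect_true(all(as_food$value[as_food$nondetect] == 0))
  other <- cohort$concentrations[!(cohort$concentrations$metal == "As" &
                                     cohort$concentrations$medium == "food"), ]
  expect_false(any(other$nondetect))

  cfg_lod <- cohort_config(seed = 31, nondetect_substitution = "half_lod")
  ch2 <- generate_cohort(cfg_lod)
  as2 <- ch2$concentrations[ch2$concentrations$metal == "As" &
                              ch2$concentrations$medium == "food", ]
  expect_true(all(as2$value[as2$nondetect] == 0.001))
})

test_that("generator reports missing calibration rows by name", {
  ef <- read_exposure_factor_table()
  broken <- ef[!(ef$group == "y3_6" & ef$parameter == "soil_ingestion"), ]
  expect_error(
    generate_cohort(cohort_config(seed = 1, exposure_factor_table = broken)),
    "y3_6, soil_ingestion")
})
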