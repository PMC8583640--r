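ef_default <- exposure_factors(25, c(food = 548, water = 1104, soil = 41))
rfd <- read_rfd_table()

test_that("average daily dose matches hand-computed values per pathway", {
  # soil: mg/kg x mg/day x 1e-6 / kg
  expect_equal(average_daily_dose(72.58, "soil", ef_default),
               72.58 * 41 * 1e-6 / 25)
  expect_equal(average_daily_dose(72.58, "soil", ef_default), 1.1903e-4,
               tolerance = 1e-4)
  # water: ng/mL x mL/day x 1e-6 / kg
  expect_equal(average_daily_dose(1.41, "water", ef_default),
               1.41e-3 * 1.104 / 25)
  # food: mg/kg x g/day / 1000 / kg
  expect_equal(average_daily_dose(0.13, "food", ef_default),
               0.13 * 0.548 / 25)
  expect_equal(average_daily_dose(0, "soil", ef_default), 0)
})

test_that("dose model rejects invalid inputs with explicit messages", {
  expect_error(average_daily_dose(1, "dust", ef_default), "unknown pathway")
  expect_error(exposure_factors(-3, c(food = 1, water = 1, soil = 1)),
               "body weight")
  expect_error(exposure_factors(25, c(food = 1, water = 1)), "soil")
  expect_error(exposure_factors(25, c(food = 1, water = 1, soil = 1),
                                exposure_frequency = 400),
               "exposure frequency")
  expect_error(average_daily_dose(-1, "soil", ef_default), ">= 0")
})

test_that("ADD is linear in concentration and intake, inverse in body weight", {
  set.seed(11)
  for (i in 1:20) {
    C <- runif(1, 0.01, 500)
    k <- runif(1, 0.5, 4)
    ingr <- runif(3, 1, 2000)
    bw <- runif(1, 10, 60)
    ef <- exposure_factors(bw, c(food = ingr[1], water = ingr[2],
                                 soil = ingr[3]))
    ef2 <- exposure_factors(bw, c(food = k * ingr[1], water = ingr[2],
                                  soil = ingr[3]))
    ef3 <- exposure_factors(k * bw, c(food = ingr[1], water = ingr[2],
                                      soil = ingr[3]))
    pw <- sample(PATHWAYS, 1)
    expect_equal(average_daily_dose(k * C, pw, ef),
                 k * average_daily_dose(C, pw, ef))
    expect_equal(average_daily_dose(C, "food", ef2),
                 k * average_daily_dose(C, "food", ef))
    expect_equal(average_daily_dose(C, pw, ef3),
                 average_daily_dose(C, pw, ef) / k)
  }
})

test_that("with EF = 365 and AT = ED x 365 the dose is independent of ED", {
  for (ed in c(1, 6, 10)) {
    ef <- exposure_factors(25, c(food = 548, water = 1104, soil = 41),
                           exposure_duration = ed)
    expect_equal(average_daily_dose(72.58, "soil", ef),
                 72.58 * 41 * 1e-6 / 25)
  }
  # with EF below 365 the dose scales by EF/365 instead
  ef_part <- exposure_factors(25, c(food = 548, water = 1104, soil = 41),
                              exposure_frequency = 180)
  expect_equal(average_daily_dose(72.58, "soil", ef_part),
               72.58 * 41 * 1e-6 / 25 * 180 / 365)
})

test_that("hazard quotient divides dose by the pathway-resolved RfD", {
  expect_equal(hazard_quotient(0.0014, "Pb", "soil", rfd), 1)
  expect_equal(hazard_quotient(1.1903e-4, "Pb", "soil", rfd), 8.502e-2,
               tolerance = 1e-3)
  add_cr <- average_daily_dose(73.65, "soil", ef_default)
  hq_cr <- hazard_quotient(add_cr, "Cr", "soil", rfd)
  expect_equal(hq_cr, 73.65 * 41 * 1e-6 / 25 / 1.5)
  # same order of magnitude as the published soil-Cr median cell (7.8e-5)
  expect_equal(hq_cr, 7.8e-5, tolerance = 0.05)
  expect_error(hazard_quotient(1, "Pb", "soil", rfd[-6, ]), "exactly one")
})

test_that("hazard indices are sums, permutation-invariant and additive", {
  expect_equal(hazard_index(c(1.2, 8.2e-3, 9.9e-2)), 1.3072)
  expect_equal(signif_half_up(hazard_index(c(1.2, 8.2e-3, 9.9e-2))), 1.3)
  expect_equal(signif_half_up(hazard_index(c(5.8e-2, 2.9e-1, 3.0e-2))),
               3.8e-1)
  expect_equal(signif_half_up(total_hazard_index(c(1.5, 3.1e-1, 1.3e-1))),
               1.9)
  expect_equal(signif_half_up(total_hazard_index(c(3.9, 4.2e-1, 4.3e-1))),
               4.8)
  expect_equal(hazard_index(c(0, 0, 0)), 0)
  expect_equal(total_hazard_index(5.2), 5.2)
  set.seed(3)
  for (i in 1:10) {
    x <- runif(sample(2:8, 1))
    expect_equal(hazard_index(sample(x)), hazard_index(x))
    y <- runif(length(x))
    expect_equal(hazard_index(x + y), hazard_index(x) + hazard_index(y))
  }
  expect_error(hazard_index(numeric(0)), "empty")
  expect_error(hazard_index(c(1, -0.1)), ">= 0")
})

test_that("contribution fractions apportion to [0, 1] and sum to one", {
  expect_equal(contribution_fractions(c(soil = 3)), c(soil = 1))
  expect_equal(contribution_fractions(c(food = 9, water = 0.5, soil = 0.5)),
               c(food = 0.9, water = 0.05, soil = 0.05))
  set.seed(5)
  for (i in 1:20) {
    v <- runif(sample(2:6, 1), 0, 10)
    f <- contribution_fractions(v)
    expect_true(all(f >= 0 & f <= 1))
    expect_lt(abs(sum(f) - 1), 1e-12)
  }
  expect_error(contribution_fractions(c(0, 0)), "all values are zero")
  expect_error(contribution_fractions(c(1, -1)), "nonnegative")
})

test_that("significant-figure rounding sends halves away from zero", {
  expect_equal(signif_half_up(4.75), 4.8)
  expect_equal(signif_half_up(-4.75), -4.8)
  expect_equal(signif_half_up(0.615), 0.62)
  expect_equal(signif_half_up(1.307), 1.3)
  expect_equal(signif_half_up(0), 0)
  expect_equal(signif_half_up(2.1e-3 + 2.7e-5 + 7.8e-5), 2.2e-3)
  expect_equal(signif_half_up(1.5 + 0.31 + 0.13), 1.9)
  expect_equal(signif_half_up(123.456, 4), 123.5)
})

make_records <- function(hq_grid) {
  # hq_grid: data.frame with child_id, metal, pathway, hq
  tibble::as_tibble(hq_grid)
}

test_that("risk_table degenerates correctly on one child", {
  recs <- make_records(expand.grid(child_id = 1, metal = METALS,
                                   pathway = PATHWAYS,
                                   stringsAsFactors = FALSE))
  recs$hq <- seq(0.01, by = 0.01, length.out = nrow(recs))
  rt <- risk_table(recs)
  # every percentile equals the child's own value
  for (p in unique(rt$percentile)) {
    sub <- rt[rt$percentile == p & rt$metal != "Total" & rt$pathway != "Sum", ]
    merged <- merge(sub, recs, by = c("metal", "pathway"))
    expect_equal(merged$hq.x, merged$hq.y)
  }
  tot <- rt[rt$metal == "Total" & rt$pathway == "Sum", ]
  expect_equal(tot$hq, rep(sum(recs$hq), 3))
})

test_that("risk_table takes percentiles after per-child summation", {
  # three children, one cell
  recs <- make_records(data.frame(child_id = 1:3, metal = "Pb",
                                  pathway = "soil", hq = c(0.1, 0.2, 0.3)))
  rt <- risk_table(recs)
  expect_equal(rt$hq[rt$metal == "Pb" & rt$pathway == "soil" &
                       rt$percentile == 50], 0.2)

  # two children, metals A,B = (1,2) and (3,4): Total-sum median is the
  # median of per-child totals {3, 7}, not the sum of medians
  recs2 <- make_records(data.frame(
    child_id = c(1, 1, 2, 2), metal = c("Mn", "Pb", "Mn", "Pb"),
    pathway = "food", hq = c(1, 2, 3, 4)))
  rt2 <- risk_table(recs2)
  expect_equal(rt2$hq[rt2$metal == "Total" & rt2$pathway == "Sum" &
                        rt2$percentile == 50],
               median(c(3, 7)))

  # randomized <= 4-child cohorts against the brute-force oracle
  set.seed(99)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    g <- expand.grid(child_id = seq_len(n), metal = METALS,
                     pathway = PATHWAYS, stringsAsFactors = FALSE)
    g$hq <- runif(nrow(g))
    rt <- risk_table(make_records(g))
    for (j in sample(nrow(rt), 12)) {
      expect_equal(rt$hq[j],
                   brute_force_risk_cell(g, rt$metal[j], rt$pathway[j],
                                         rt$percentile[j] / 100))
    }
  }
})

test_that("risk_table percentiles are monotone and structure is complete", {
  set.seed(7)
  g <- expand.grid(child_id = 1:12, metal = METALS, pathway = PATHWAYS,
                   stringsAsFactors = FALSE)
  g$hq <- rlnorm(nrow(g), -3, 1)
  rt <- risk_table(make_records(g))
  expect_equal(nrow(rt), 6 * 4 * 3)
  wide <- tidyr::pivot_wider(rt[, c("metal", "pathway", "percentile", "hq")],
                             names_from = "percentile", values_from = "hq")
  expect_true(all(wide$`5` <= wide$`50` & wide$`50` <= wide$`95`))
  expect_true(all(rt$hq >= 0))
  expect_error(risk_table(g[0, ]), "nrow")
})
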