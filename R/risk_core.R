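#' Exposure factors for a child or a group
#'
#' Bundles the dose-model parameters: body weight `BW` (kg), intake rates
#' `IngR` per pathway in their native units (food g/day, water mL/day, soil
#' mg/day), exposure frequency `EF` (days/year, default 365), exposure
#' duration `ED` (years) and averaging time `AT` (days).  For
#' non-carcinogenic assessment `AT = ED x 365` by definition, which makes
#' the factor `EF * ED / AT` exactly 1 at the default `EF`; that default is
#' therefore the one under which the average daily dose does not depend on
#' `ED` at all.
#'
#' @param body_weight Body weight in kg, `> 0`.
#' @param intake Named numeric vector or list with entries `food` (g/day),
#'   `water` (mL/day) and `soil` (mg/day), all `>= 0`.
#' @param exposure_frequency Days per year, in `(0, 365]`.
#' @param exposure_duration Years of exposure, `> 0`.
#' @param averaging_time Days; defaults to `exposure_duration * 365`.
#' @return An object of class `exposure_factors`.
#' @export
#' @examples
#' exposure_factors(25, c(food = 548, water = 1104, soil = 41))
exposure_factors <- function(body_weight, intake,
                             exposure_frequency = 365,
                             exposure_duration = 6,
                             averaging_time = NULL) {
  intake <- unlist(intake)
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("body weight must be a single positive number (kg); got ",
         deparse(body_weight))
  missing_pw <- setdiff(PATHWAYS, names(intake))
  if (length(missing_pw))
    stop("intake rates missing for pathway(s): ",
         paste(missing_pw, collapse = ", "))
  extra <- setdiff(names(intake), PATHWAYS)
  if (length(extra))
    stop("unknown pathway(s) in intake: ", paste(extra, collapse = ", "))
  if (any(!is.finite(intake)) || any(intake < 0))
    stop("all intake rates must be finite and >= 0")
  if (!(exposure_frequency > 0 && exposure_frequency <= 365))
    stop("exposure frequency must lie in (0, 365] days/year")
  stopifnot(exposure_duration > 0)
  if (is.null(averaging_time)) averaging_time <- exposure_duration * 365
  stopifnot(averaging_time > 0)
  structure(
    list(body_weight = body_weight, intake = intake[PATHWAYS],
         exposure_frequency = exposure_frequency,
         exposure_duration = exposure_duration,
         averaging_time = averaging_time),
    class = "exposure_factors"
  )
}

# Shared dose kernel: concentration (native unit) x intake (native unit)
# x pathway unit factor -> mg/day, then EF*ED/(BW*AT) -> mg/kg/day.
# Vectorized over C, IngR and BW; used by both the deterministic path and
# the Monte Carlo engine so the two can never drift apart.
.dose <- function(concentration, intake, body_weight, pathway,
                  exposure_frequency = 365, exposure_duration = 6,
                  averaging_time = exposure_duration * 365) {
  if (length(pathway) != 1 || !pathway %in% PATHWAYS)
    stop("unknown pathway: ", paste(pathway, collapse = ", "),
         " (expected one of ", paste(PATHWAYS, collapse = ", "), ")")
  concentration * intake * .dose_factor[[pathway]] *
    exposure_frequency * exposure_duration /
    (body_weight * averaging_time)
}

#' Average daily dose through one ingestion pathway
#'
#' `ADD = C x IngR x EF x ED / (BW x AT)`, with the concentration-times-
#' intake product converted to mg/day by the pathway's unit factor (soil
#' mg/kg x mg/day x 1e-6; food mg/kg x g/day / 1000; water ng/mL x mL/day
#' x 1e-6).  Vectorized over `concentration`.
#'
#' @param concentration Concentration(s) in the pathway's native unit,
#'   `>= 0`.
#' @param pathway One of `"food"`, `"water"`, `"soil"`.
#' @param factors An [exposure_factors()] object.
#' @return Dose(s) in mg per kg body weight per day.
#' @export
#' @examples
#' ef <- exposure_factors(25, c(food = 548, water = 1104, soil = 41))
#' average_daily_dose(72.58, "soil", ef)   # ~1.19e-4 mg/kg/day
average_daily_dose <- function(concentration, pathway, factors) {
  stopifnot(inherits(factors, "exposure_factors"))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentrations must be finite and >= 0")
  .dose(concentration, factors$intake[[pathway]], factors$body_weight,
        pathway, factors$exposure_frequency, factors$exposure_duration,
        factors$averaging_time)
}

# rfd_table: tibble with columns metal, pathway, rfd_mg_per_kg_day
rfd_value <- function(rfd_table, metal, pathway) {
  hit <- rfd_table$metal == metal & rfd_table$pathway == pathway
  if (sum(hit) != 1)
    stop("reference dose table has ", sum(hit), " entries for (",
         metal, ", ", pathway, "); exactly one required")
  v <- rfd_table$rfd_mg_per_kg_day[hit]
  if (!is.finite(v) || v <= 0)
    stop("reference dose for (", metal, ", ", pathway, ") must be > 0")
  v
}

#' Hazard quotient of a dose
#'
#' `HQ = ADD / RfD`, the average daily dose as a fraction of the oral
#' reference dose for that metal and pathway.  `HQ <= 1` is read as
#' unlikely to pose non-carcinogenic effects.
#'
#' @param add Average daily dose(s), mg/kg/day.
#' @param metal One of [METALS].
#' @param pathway One of [PATHWAYS].
#' @param rfd_table Reference-dose table as returned by [read_rfd_table()].
#' @return Dimensionless hazard quotient(s).
#' @export
hazard_quotient <- function(add, metal, pathway, rfd_table) {
  if (any(!is.finite(add)) || any(add < 0))
    stop("average daily dose must be finite and >= 0")
  add / rfd_value(rfd_table, metal, pathway)
}

#' Hazard index and total hazard index
#'
#' The hazard index `HI` for one metal is the plain sum of its hazard
#' quotients across exposure pathways; the total hazard index `HIt` is the
#' sum of `HI` across metals.  Both are the same arithmetic and share one
#' implementation.
#'
#' @param hqs,his Nonnegative hazard quotients (respectively indices).
#' @return The sum.
#' @export
#' @examples
#' hazard_index(c(1.2, 8.2e-3, 9.9e-2))  # 1.307 -> prints as 1.3 at 2 s.f.
hazard_index <- function(hqs) {
  hqs <- unlist(hqs)
  if (length(hqs) == 0) stop("cannot sum an empty set of hazard quotients")
  if (any(!is.finite(hqs)) || any(hqs < 0))
    stop("hazard quotients must be finite and >= 0")
  sum(hqs)
}

#' @rdname hazard_index
#' @export
total_hazard_index <- function(his) hazard_index(his)

#' Fractional contribution of each pathway (or metal) to a total
#'
#' @param values Named nonnegative numeric vector (e.g. ADD per pathway);
#'   at least one entry must be positive.
#' @return Named fractions summing to 1.
#' @export
#' @examples
#' contribution_fractions(c(food = 9, water = 0.5, soil = 0.5))
contribution_fractions <- function(values) {
  values <- unlist(values)
  if (length(values) == 0) stop("no values to apportion")
  if (any(!is.finite(values)) || any(values < 0))
    stop("contributions are defined for finite nonnegative values only")
  total <- sum(values)
  if (total == 0) stop("all values are zero; contributions undefined")
  values / total
}

#' Per-child dose and hazard records for a whole cohort
#'
#' Applies the dose model to every (child, metal, pathway) cell of a
#' synthetic or observed cohort and divides by the reference dose.
#'
#' @param cohort A `metal_cohort` from [generate_cohort()], or any list with
#'   a `factors` and a `concentrations` tibble of the same shape.
#' @param rfd_table Reference-dose table ([read_rfd_table()]).
#' @return A tibble with columns `child_id`, `age_group`, `metal`,
#'   `pathway`, `add` (mg/kg/day) and `hq`.
#' @export
assess_cohort <- function(cohort, rfd_table) {
  stopifnot(is.list(cohort), !is.null(cohort$factors),
            !is.null(cohort$concentrations))
  fac <- cohort$factors
  conc <- cohort$concentrations
  recs <- dplyr::inner_join(
    conc,
    dplyr::select(fac, "child_id", "body_weight", "food_ingestion",
                  "soil_ingestion", "water_intake"),
    by = "child_id"
  )
  intake <- dplyr::case_match(recs$pathway,
                              "food" ~ recs$food_ingestion,
                              "water" ~ recs$water_intake,
                              "soil" ~ recs$soil_ingestion)
  add <- recs$value * intake * .dose_factor[recs$pathway] / recs$body_weight
  rfd <- vapply(seq_len(nrow(recs)), function(i)
    rfd_value(rfd_table, recs$metal[i], recs$pathway[i]), numeric(1))
  tibble::tibble(
    child_id = recs$child_id, age_group = recs$age_group,
    metal = recs$metal, pathway = recs$pathway,
    add = unname(add), hq = unname(add / rfd)
  )
}

#' Pathway contributions to a cohort's oral exposure dose
#'
#' For each metal, aggregates the per-child average daily doses to one
#' summary dose per pathway and normalizes with
#' [contribution_fractions()].  The default aggregate is the cohort
#' median, matching how the study reports exposure and risk levels
#' (medians and percentiles); means are available for sensitivity.
#'
#' @param records Per-child risk records from [assess_cohort()].
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Tibble with columns `metal`, `pathway`, `fraction`.
#' @export
cohort_pathway_contributions <- function(records,
                                         statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  agg <- if (statistic == "median") stats::median else mean
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  summ <- records |>
    dplyr::summarise(dose = agg(.data$add), .by = c("metal", "pathway"))
  out <- summ |>
    dplyr::mutate(fraction = unname(contribution_fractions(
      stats::setNames(.data$dose, .data$pathway))), .by = "metal")
  tibble::as_tibble(out[, c("metal", "pathway", "fraction")])
}

#' Cohort percentile table of hazard quotients and indices
#'
#' Builds the study's summary grid: rows are the five metals plus a
#' `Total` row, columns the three pathways plus a `Sum` column, and each
#' cell is reported at the requested cohort percentiles.  Aggregation is
#' percentile-after-sum: each child's `Sum` (HI over pathways) and `Total`
#' (over metals) are formed first, and percentiles are then taken across
#' children for every cell — never by summing percentiles.
#'
#' @param records Per-child risk records from [assess_cohort()] (columns
#'   `child_id`, `metal`, `pathway`, `hq`).
#' @param percentiles Percentile levels in percent (default `c(5, 50, 95)`).
#' @return A tibble with columns `metal` (including `"Total"`), `pathway`
#'   (including `"Sum"`), `percentile`, `hq` (raw double) and `hq_2sf`
#'   ([signif_half_up()] to 2 significant figures).
#' @export
risk_table <- function(records, percentiles = c(5, 50, 95)) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("child_id", "metal", "pathway", "hq") %in% names(records)),
            all(percentiles >= 0 & percentiles <= 100))
  cells <- records[, c("child_id", "metal", "pathway", "hq")]
  # per-child aggregates first
  sums <- cells |>
    dplyr::summarise(hq = sum(.data$hq),
                     .by = c("child_id", "metal")) |>
    dplyr::mutate(pathway = "Sum")
  totals <- cells |>
    dplyr::summarise(hq = sum(.data$hq),
                     .by = c("child_id", "pathway")) |>
    dplyr::mutate(metal = "Total")
  grand <- cells |>
    dplyr::summarise(hq = sum(.data$hq), .by = "child_id") |>
    dplyr::mutate(metal = "Total", pathway = "Sum")
  full <- dplyr::bind_rows(cells, sums, totals, grand)
  out <- full |>
    dplyr::reframe(percentile = percentiles,
                   hq = risk_percentile(.data$hq, percentiles / 100),
                   .by = c("metal", "pathway")) |>
    dplyr::mutate(
      metal = factor(.data$metal, levels = c(METALS, "Total")),
      pathway = factor(.data$pathway, levels = c(PATHWAYS, "Sum"))
    ) |>
    dplyr::arrange(.data$metal, .data$pathway, .data$percentile) |>
    dplyr::mutate(metal = as.character(.data$metal),
                  pathway = as.character(.data$pathway),
                  hq_2sf = signif_half_up(.data$hq, 2))
  tibble::as_tibble(out)
}
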