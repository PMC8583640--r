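#' Parse numbers in plain or typographic scientific notation
#'
#' The source tables print values like `9.9 x 10-2` with a multiplication
#' sign and a typographic minus; delimited fixtures may carry either that
#' form or plain `9.9e-2`.  This parser accepts both (including the Unicode
#' multiplication and minus signs, an optional caret before the exponent,
#' and surrounding blanks) as well as plain decimals.
#'
#' @param x Character vector.
#' @return Numeric vector; unparseable entries raise an error naming the
#'   offending value.
#' @export
#' @examples
#' parse_table_number(c("9.9 × 10−2", "1.2", "3.4e-5"))
parse_table_number <- function(x) {
  x0 <- x
  x <- trimws(as.character(x))
  # typographic minus / multiplication sign -> ASCII
  x <- gsub("−", "-", x)
  x <- gsub("×", "x", x)
  # "a x 10^b" / "a x 10b" -> "aeb"
  x <- gsub("(?i)^\\s*([0-9.+-]+)\\s*x\\s*10\\s*\\^?\\s*([+-]?[0-9]+)\\s*$",
            "\\1e\\2", x, perl = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x0) & x0 != ""
  if (any(bad))
    stop("cannot parse numeric value(s): ",
         paste(unique(x0[bad]), collapse = ", "))
  out
}

.read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = "#", colClasses = "character",
                        strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Path to a shipped calibration fixture
#'
#' The package ships the study's published summary tables as plain CSV
#' under `extdata`: `concentration_summary.csv` (metal x medium quartiles),
#' `exposure_factors.csv` (body weight and intake rates, overall and per
#' age group), `rfd.csv` (oral reference doses) and
#' `reference_hazard_percentiles.csv` (the published cohort hazard-quotient
#' percentile grid, used as a cross-check target).
#'
#' @param name Fixture file name.
#' @return Absolute path to the installed file.
#' @export
metalrisk_fixture <- function(name) {
  p <- system.file("extdata", name, package = "metalrisk")
  if (p == "") stop("no such fixture: ", name)
  p
}

#' Read and validate a concentration-summary table
#'
#' Expects columns `metal,medium,unit,median,p25,p75`; checks the 5 x 3
#' (metal x medium) grid is complete, units match each medium's native
#' unit, and quartiles are monotone, raising row-addressed errors
#' otherwise.
#'
#' @param path CSV file path; defaults to the shipped fixture.
#' @return A tibble with numeric `median`, `p25`, `p75`.
#' @export
read_concentration_summary <- function(
    path = metalrisk_fixture("concentration_summary.csv")) {
  df <- .read_delim_checked(
    path, c("metal", "medium", "unit", "median", "p25", "p75"),
    "concentration summary")
  for (col in c("median", "p25", "p75")) df[[col]] <- parse_table_number(df[[col]])
  units <- stats::setNames(pathway_units()$concentration_unit,
                           pathway_units()$pathway)
  for (i in seq_len(nrow(df))) {
    row_id <- paste0("row ", i, " (", df$metal[i], ", ", df$medium[i], ")")
    if (!df$metal[i] %in% METALS)
      stop("unknown metal in ", row_id, ": ", df$metal[i])
    if (!df$medium[i] %in% PATHWAYS)
      stop("unknown medium in ", row_id, ": ", df$medium[i])
    if (df$unit[i] != units[[df$medium[i]]])
      stop(row_id, ": unit ", df$unit[i], " does not match the native ",
           df$medium[i], " unit ", units[[df$medium[i]]])
    if (!(df$p25[i] <= df$median[i] && df$median[i] <= df$p75[i]))
      stop(row_id, ": quartiles not monotone (p25 ", df$p25[i],
           ", median ", df$median[i], ", p75 ", df$p75[i], ")")
  }
  key <- paste(df$metal, df$medium)
  want <- as.vector(outer(METALS, PATHWAYS, paste))
  if (length(key) != length(unique(key)))
    stop("duplicated (metal, medium) rows in ", path)
  missing <- setdiff(want, key)
  if (length(missing))
    stop("concentration summary incomplete; missing: ",
         paste(missing, collapse = "; "))
  tibble::as_tibble(df)
}

.EF_PARAMS <- c("body_weight", "food_ingestion", "soil_ingestion",
                "water_intake")
.EF_GROUPS <- c("average", "y3_6", "y7_12")

#' Read and validate an exposure-factor table
#'
#' Expects columns `group,parameter,unit,median,mean` with groups
#' `average`, `y3_6`, `y7_12` and parameters `body_weight` (kg),
#' `food_ingestion` (g/day), `soil_ingestion` (mg/day), `water_intake`
#' (mL/day).
#'
#' @param path CSV file path; defaults to the shipped fixture.
#' @return A tibble with numeric `median`, `mean`.
#' @export
read_exposure_factor_table <- function(
    path = metalrisk_fixture("exposure_factors.csv")) {
  df <- .read_delim_checked(
    path, c("group", "parameter", "unit", "median", "mean"),
    "exposure factor")
  for (col in c("median", "mean")) df[[col]] <- parse_table_number(df[[col]])
  for (i in seq_len(nrow(df))) {
    row_id <- paste0("row ", i, " (", df$group[i], ", ", df$parameter[i], ")")
    if (!df$group[i] %in% .EF_GROUPS)
      stop("unknown group in ", row_id)
    if (!df$parameter[i] %in% .EF_PARAMS)
      stop("unknown parameter in ", row_id)
    if (!is.finite(df$median[i]) || df$median[i] <= 0 ||
        !is.finite(df$mean[i]) || df$mean[i] <= 0)
      stop(row_id, ": median and mean must be positive")
  }
  key <- paste(df$group, df$parameter)
  want <- as.vector(outer(.EF_GROUPS, .EF_PARAMS, paste))
  missing <- setdiff(want, key)
  if (length(missing))
    stop("exposure factor table incomplete; missing: ",
         paste(missing, collapse = "; "))
  tibble::as_tibble(df)
}

#' Read and validate a reference-dose table
#'
#' Expects columns `metal,pathway,rfd_mg_per_kg_day`; the 5 x 3 grid must
#' be complete with strictly positive doses.
#'
#' @param path CSV file path; defaults to the shipped fixture.
#' @return A tibble.
#' @export
read_rfd_table <- function(path = metalrisk_fixture("rfd.csv")) {
  df <- .read_delim_checked(
    path, c("metal", "pathway", "rfd_mg_per_kg_day"), "reference dose")
  df$rfd_mg_per_kg_day <- parse_table_number(df$rfd_mg_per_kg_day)
  for (i in seq_len(nrow(df))) {
    row_id <- paste0("row ", i, " (", df$metal[i], ", ", df$pathway[i], ")")
    if (!df$metal[i] %in% METALS) stop("unknown metal in ", row_id)
    if (!df$pathway[i] %in% PATHWAYS) stop("unknown pathway in ", row_id)
    if (!is.finite(df$rfd_mg_per_kg_day[i]) || df$rfd_mg_per_kg_day[i] <= 0)
      stop(row_id, ": reference dose must be > 0")
  }
  key <- paste(df$metal, df$pathway)
  want <- as.vector(outer(METALS, PATHWAYS, paste))
  missing <- setdiff(want, key)
  if (length(missing))
    stop("reference dose table incomplete; missing: ",
         paste(missing, collapse = "; "))
  if (length(key) != length(unique(key)))
    stop("duplicated (metal, pathway) rows in ", path)
  tibble::as_tibble(df)
}

#' Read the published hazard-quotient percentile grid
#'
#' The published summary grid (metals plus a `Total` row, percentiles 5/50/95,
#' pathway columns plus their printed `sum`) shipped as a reference fixture.
#' Values are as printed, at two significant figures.
#'
#' @param path CSV file path; defaults to the shipped fixture.
#' @return A tibble with columns `metal`, `percentile`, `food`, `water`,
#'   `soil`, `sum`.
#' @export
read_reference_hazard_percentiles <- function(
    path = metalrisk_fixture("reference_hazard_percentiles.csv")) {
  df <- .read_delim_checked(
    path, c("metal", "percentile", "food", "water", "soil", "sum"),
    "reference hazard percentiles")
  for (col in c("percentile", "food", "water", "soil", "sum"))
    df[[col]] <- parse_table_number(df[[col]])
  bad <- !df$metal %in% c(METALS, "Total")
  if (any(bad)) stop("unknown metal row(s): ",
                     paste(unique(df$metal[bad]), collapse = ", "))
  tibble::as_tibble(df)
}

.provenance_header <- function(seed = NULL) {
  c(paste0("# metalrisk ", as.character(utils::packageVersion("metalrisk"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    paste0("# written: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

#' Write a risk summary table as TSV with a provenance header
#'
#' @param x Tibble from [risk_table()].
#' @param path Output path.
#' @param seed Seed to record in the header, if any.
#' @return `path`, invisibly.
#' @export
write_risk_summary <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  utils::write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cohort as CSV (lossless round trip)
#'
#' One row per child x variable: the four exposure factors and the fifteen
#' metal-medium concentrations, with the nondetect flag.  Numbers are
#' written at full double precision (17 significant digits) so a read-back
#' reproduces the cohort exactly.
#'
#' @param cohort A `metal_cohort` from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path` invisibly (`write_cohort`); a list with `factors` and
#'   `concentrations` tibbles (`read_cohort`).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "metal_cohort"))
  fac_long <- tidyr::pivot_longer(
    cohort$factors,
    cols = c("body_weight", "food_ingestion", "soil_ingestion",
             "water_intake"),
    names_to = "variable", values_to = "value")
  fac_long$nondetect <- FALSE
  conc_long <- dplyr::mutate(
    cohort$concentrations,
    variable = paste(.data$metal, .data$medium, sep = "_"))
  out <- dplyr::bind_rows(
    dplyr::select(fac_long, "child_id", "age_group", "variable", "value",
                  "nondetect"),
    dplyr::select(conc_long, "child_id", "age_group", "variable", "value",
                  "nondetect"))
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- .read_delim_checked(
    path, c("child_id", "age_group", "variable", "value", "nondetect"),
    "cohort")
  df$value <- parse_table_number(df$value)
  df$nondetect <- df$nondetect == "TRUE"
  df$child_id <- as.integer(df$child_id)
  is_factor <- df$variable %in% .EF_PARAMS
  fac <- tidyr::pivot_wider(df[is_factor, c("child_id", "age_group",
                                            "variable", "value")],
                            names_from = "variable", values_from = "value")
  conc <- df[!is_factor, ]
  parts <- strsplit(conc$variable, "_", fixed = TRUE)
  conc$metal <- vapply(parts, `[`, "", 1)
  conc$medium <- vapply(parts, `[`, "", 2)
  conc$pathway <- conc$medium
  list(
    factors = tibble::as_tibble(fac[order(fac$child_id), ]),
    concentrations = tibble::as_tibble(
      conc[order(conc$child_id),
           c("child_id", "age_group", "metal", "medium", "pathway",
             "value", "nondetect")])
  )
}
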