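#' Sampling distributions fitted to published summary statistics
#'
#' The study tables publish only marginal summaries — quartiles for
#' concentrations, median/mean pairs for exposure factors.  Monte Carlo
#' propagation and cohort synthesis need full sampling distributions, so the
#' package turns each summary row into a parametric fit.  The default family
#' is the lognormal: all quantities are nonnegative and right-skewed, which
#' is the conventional assumption for environmental concentrations and
#' intake rates.
#'
#' A `fitted_dist` is a light list with fields `family` (`"lognormal"`,
#' `"normal"` or `"point_mass"`), `location`, `scale`, and truncation bounds
#' `lower`/`upper` (default `[0, Inf)`, enforced at sampling time by
#' rejection).  For the lognormal, `location`/`scale` are the log-scale mean
#' and standard deviation.
#'
#' @param family One of `"lognormal"`, `"normal"`, `"point_mass"`.
#' @param location Central parameter (log-median for the lognormal, mean for
#'   the normal, the value itself for a point mass).
#' @param scale Spread parameter, `>= 0` (log-sd, sd, or 0).
#' @param lower,upper Truncation bounds applied when sampling.
#' @return An object of class `fitted_dist`.
#' @export
fitted_dist <- function(family = c("lognormal", "normal", "point_mass"),
                        location, scale = 0, lower = 0, upper = Inf) {
  family <- match.arg(family)
  stopifnot(is.numeric(location), length(location) == 1, is.finite(location),
            is.numeric(scale), length(scale) == 1, scale >= 0,
            lower < upper)
  if (family == "point_mass" && scale != 0)
    stop("a point mass has zero scale")
  structure(
    list(family = family, location = location, scale = scale,
         lower = lower, upper = upper),
    class = "fitted_dist"
  )
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat(sprintf("<fitted_dist %s(location = %g, scale = %g)", x$family,
              x$location, x$scale))
  if (x$lower != 0 || is.finite(x$upper))
    cat(sprintf(", truncated to [%g, %g]", x$lower, x$upper))
  cat(">\n")
  invisible(x)
}

#' Fit a lognormal distribution to published quartiles
#'
#' Three constraints (P25, median, P75) against two lognormal parameters:
#' the median is honoured exactly (`location = log(median)`) and the two
#' log half-spreads `log(median/p25)` and `log(p75/median)` are averaged and
#' divided by the standard normal upper quartile (~0.6745) to give the
#' log-sd.  With `method = "least_squares"` the three log-quantiles are
#' instead fitted by least squares; the spread estimate is identical (the
#' half-spread average *is* the least-squares slope) but the location
#' becomes the mean of the three log-quantiles, so the median is no longer
#' honoured exactly.  Degenerate input (`p25 == p75`) yields a point mass.
#'
#' @param p25,median,p75 Published quartiles, `0 < p25 <= median <= p75`.
#' @param method `"average"` (default; median-exact) or `"least_squares"`.
#' @return A [fitted_dist()].
#' @export
#' @examples
#' fit_quartiles(56.77, 72.58, 81.48)  # soil Pb, mg/kg
#' fit_quartiles(0.01, 0.01, 0.01)     # water Cd: all quartiles at the LOD
fit_quartiles <- function(p25, median, p75,
                          method = c("average", "least_squares")) {
  method <- match.arg(method)
  stopifnot(is.numeric(p25), is.numeric(median), is.numeric(p75))
  if (!(p25 > 0 && p25 <= median && median <= p75))
    stop("quartiles must satisfy 0 < p25 <= median <= p75 (got ",
         p25, ", ", median, ", ", p75, ")")
  if (p25 == p75) return(fitted_dist("point_mass", location = median))
  z75 <- stats::qnorm(0.75)
  sdlog <- mean(c(log(median / p25), log(p75 / median))) / z75
  meanlog <- if (method == "average") log(median)
             else mean(log(c(p25, median, p75)))
  fitted_dist("lognormal", location = meanlog, scale = sdlog)
}

#' Fit a lognormal distribution to a published median/mean pair
#'
#' For a lognormal with log-median `mu` and log-sd `s`, the arithmetic mean
#' is `exp(mu + s^2/2)`, so a median/mean pair determines the fit exactly:
#' `mu = log(median)`, `s = sqrt(2 * log(mean / median))`.  The fitted
#' arithmetic mean reproduces the published mean by construction.
#'
#' When the published mean falls *below* the median the lognormal (right
#' skew) cannot hold; the fit falls back to a normal centred on the mean
#' with `sd = |mean - median|`, with a warning.  Several exposure-factor
#' rows of the calibration tables take this branch.
#'
#' @param median,mean Published median and arithmetic mean, `median > 0`.
#' @return A [fitted_dist()].
#' @export
#' @examples
#' fit_median_mean(41, 51)   # soil ingestion rate, mg/day
#' fit_median_mean(25, 25)   # degenerate: point mass
fit_median_mean <- function(median, mean) {
  stopifnot(is.numeric(median), is.numeric(mean), median > 0, mean > 0)
  if (mean == median) return(fitted_dist("point_mass", location = median))
  if (mean < median) {
    warning("mean (", mean, ") below median (", median,
            "): lognormal right skew impossible, falling back to normal(",
            mean, ", ", abs(mean - median), ")")
    return(fitted_dist("normal", location = mean,
                       scale = abs(mean - median)))
  }
  fitted_dist("lognormal", location = log(median),
              scale = sqrt(2 * log(mean / median)))
}

#' Analytic median, mean and quartiles of a fitted distribution
#'
#' Truncation bounds are ignored here: for the default `[0, Inf)` bound the
#' lognormal values are exact, and the generator's body-weight bounds clip
#' so little mass that the analytic values remain the calibration
#' reference.
#'
#' @param dist A [fitted_dist()].
#' @return A single number (`dist_median`, `dist_mean`) or a named vector
#'   `c(p25 = , median = , p75 = )` (`dist_quartiles`).
#' @export
dist_median <- function(dist) {
  stopifnot(inherits(dist, "fitted_dist"))
  switch(dist$family,
         point_mass = dist$location,
         normal = dist$location,
         lognormal = exp(dist$location))
}

#' @rdname dist_median
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "fitted_dist"))
  switch(dist$family,
         point_mass = dist$location,
         normal = dist$location,
         lognormal = exp(dist$location + dist$scale^2 / 2))
}

#' @rdname dist_median
#' @export
dist_quartiles <- function(dist) {
  stopifnot(inherits(dist, "fitted_dist"))
  z75 <- stats::qnorm(0.75)
  q <- switch(dist$family,
    point_mass = rep(dist$location, 3),
    normal = dist$location + c(-z75, 0, z75) * dist$scale,
    lognormal = exp(dist$location + c(-z75, 0, z75) * dist$scale))
  stats::setNames(q, c("p25", "median", "p75"))
}

#' Draw reproducible samples from a fitted distribution
#'
#' Truncation bounds are enforced by rejection (resampling out-of-bounds
#' draws), which preserves the distribution's shape inside the bounds.
#' When `seed` is given the draw is made under a temporary RNG state and the
#' caller's random stream is left untouched; the same seed always yields
#' the same vector.
#'
#' @param dist A [fitted_dist()].
#' @param n Number of draws, `>= 1`.
#' @param seed Optional integer seed for a self-contained reproducible draw.
#' @return Numeric vector of length `n`, all values within the truncation
#'   bounds.
#' @export
#' @examples
#' sample_dist(fit_quartiles(56.77, 72.58, 81.48), 5, seed = 1)
sample_dist <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "fitted_dist"), is.numeric(n), n >= 1)
  n <- as.integer(n)
  with_seed(seed, {
    if (dist$family == "point_mass") {
      if (dist$location < dist$lower || dist$location > dist$upper)
        stop("point mass lies outside its truncation bounds")
      return(rep(dist$location, n))
    }
    draw <- function(k) switch(dist$family,
      normal = stats::rnorm(k, dist$location, dist$scale),
      lognormal = stats::rlnorm(k, dist$location, dist$scale))
    x <- draw(n)
    bad <- which(x < dist$lower | x > dist$upper)
    tries <- 0L
    while (length(bad) > 0) {
      x[bad] <- draw(length(bad))
      bad <- bad[x[bad] < dist$lower | x[bad] > dist$upper]
      tries <- tries + 1L
      if (tries > 10000L) stop("rejection sampling failed to converge; ",
                               "truncation bounds too tight for ", dist$family)
    }
    x
  })
}

#' Serialize a fitted distribution as a JSON spec
#'
#' @param dist A [fitted_dist()].
#' @param variable Name of the quantity the fit describes.
#' @param source_row Optional provenance string (which table row was fitted).
#' @return A JSON string.
#' @export
dist_to_json <- function(dist, variable, source_row = NULL) {
  stopifnot(inherits(dist, "fitted_dist"))
  spec <- list(variable = variable, family = dist$family,
               params = list(location = dist$location, scale = dist$scale,
                             lower = dist$lower,
                             upper = if (is.finite(dist$upper)) dist$upper))
  if (!is.null(source_row)) spec$source_row <- source_row
  jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA, null = "null")
}
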