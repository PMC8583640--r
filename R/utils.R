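#' Round to significant figures, halves away from zero
#'
#' Report-style rounding used for hazard tables: 2 significant figures by
#' default, with exact halves rounded away from zero (so 4.75 prints as 4.8,
#' not the banker's 4.7).  A small relative epsilon guards against binary
#' representation error in sums such as `1.5 + 0.31 + 0.13`.
#'
#' @param x Numeric vector.
#' @param digits Significant figures to keep (default 2).
#' @return Numeric vector rounded to `digits` significant figures.
#' @export
#' @examples
#' signif_half_up(c(1.307, 4.75, 0.0022049), 2)
signif_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  ax <- abs(x[nz])
  e <- floor(log10(ax)) - digits + 1
  f <- ax / 10^e
  out[nz] <- sign(x[nz]) * floor(f + 0.5 + f * 1e-9) * 10^e
  out
}

#' Percentiles by linear interpolation between closest ranks
#'
#' Single percentile definition shared by the deterministic risk tables and
#' the Monte Carlo summaries: linear interpolation between closest ranks,
#' inclusive of the extremes (R's default type 7).
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @return Unnamed numeric vector of percentiles.
#' @export
risk_percentile <- function(x, probs) {
  stopifnot(length(x) >= 1, all(probs >= 0 & probs <= 1))
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's stream afterwards. seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
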