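## Physical constants and unit conversions used throughout the package.
## Internal convention: energies in keV (J at the dose interface), times in
## seconds, activities in Bq, volumes in ml, doses in Gy = J/kg.

#' Energy conversion: keV to joule
#'
#' Exact conversion constant (2019 SI definition of the electronvolt),
#' 1 keV = 1.602176634e-16 J.
#'
#' @return The conversion factor in J/keV.
#' @examples
#' keVToJoule() * 147.9   # J per decay for ~148 keV mean electron energy
#' @export
keVToJoule <- function() 1.602176634e-16

## hours -> seconds
hoursToSeconds <- function(h) h * 3600

#' Round half away from zero to a fixed number of decimals
#'
#' Reporting-layer rounding used when comparing computed statistics to
#' printed table cells (which use commercial half-up rounding, unlike R's
#' banker-style \code{round}). A tiny epsilon guards against binary
#' representation artefacts such as 0.275 * 100 = 27.499999....
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return \code{x} rounded half-up (half-down for negatives).
#' @examples
#' roundHalfUp(0.275, 2)  # 0.28, where round() gives 0.28 or 0.27
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## log-log linear interpolation used for range and attenuation tables
logLogInterp <- function(xTab, yTab, x) {
  exp(stats::approx(log(xTab), log(yTab), xout = log(x), rule = 2)$y)
}
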