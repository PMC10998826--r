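## Time-activity-curve fitting, effective half-life, back-extrapolation
## and time-integrated disintegration counts.
##
## Conventions: lambda_e >= 0 is the negative of the log-TAC slope (so
## Te = ln2/lambda_e > 0 and A1 = A4 * exp(+lambda_e * dt) extrapolates
## upward in time-reversal). All internal times are seconds; the public
## interface takes hours. The leading t1/2 term of the integral is the
## linear-uptake triangle from 0 to A1 over [0, t1]; the exponential tail
## is anchored at A1 at t1 (N_tail = A1/lambda_e), the reading
## dimensionally consistent with A1 being the first-acquisition activity.

#' Construct a TimeActivityCurve
#'
#' @param times hours p.i., strictly increasing.
#' @param values activity (Bq) or mean concentration (Bq/ml), >= 0.
#' @param valueKind "activity" (default) or "concentration".
#' @param censored logical vector; censored points are excluded from fits.
#' @return A \linkS4class{TimeActivityCurve}.
#' @export
timeActivityCurve <- function(times, values, valueKind = "activity",
                              censored = rep(FALSE, length(times))) {
  new("TimeActivityCurve", times = as.numeric(times),
      values = as.numeric(values), valueKind = valueKind,
      censored = censored)
}

#' Fit the effective half-life of a mono-exponential washout
#'
#' Ordinary least squares of log(value) on time over the uncensored,
#' strictly positive points. lambdaE is the negative slope converted to
#' 1/s; Te = ln(2)/lambdaE in hours. The fit is flagged unusable (and the
#' caller should fall back to trapezoid integration) when the slope is
#' >= 0, fewer than 3 positive points remain, or r-squared < 0.5.
#'
#' @param tac a \linkS4class{TimeActivityCurve}.
#' @return A \linkS4class{KineticFit}.
#' @examples
#' tac <- timeActivityCurve(c(1, 4, 24, 72), 100 * 2^(-c(1, 4, 24, 72)/10))
#' effectiveHalfLife(fitEffectiveHalfLife(tac))   # 10 h
#' @export
fitEffectiveHalfLife <- function(tac) {
  keep <- !tac@censored
  if (any(tac@values[keep] <= 0)) {
    warning("non-positive TAC values excluded from the log-linear fit")
    keep <- keep & tac@values > 0
  }
  t <- tac@times[keep]
  v <- tac@values[keep]
  if (length(t) < 2) stop("fewer than 2 usable points: cannot fit")
  fit <- stats::lm(log(v) ~ t)
  slopePerH <- unname(stats::coef(fit)[2])
  if (abs(slopePerH) < 1e-12) slopePerH <- 0   # numerically flat TAC
  alpha <- unname(stats::coef(fit)[1])
  ssTot <- sum((log(v) - mean(log(v)))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  lambdaE <- -slopePerH / 3600
  usable <- length(t) >= 3 && lambdaE > 0 && r2 >= 0.5
  new("KineticFit", alpha = alpha, lambdaE = lambdaE,
      Te = if (lambdaE > 0) log(2) / (lambdaE * 3600) else NA_real_,
      rSquared = r2, usable = usable, nPointsUsed = length(t))
}

#' @rdname effectiveHalfLife
#' @export
setMethod("effectiveHalfLife", "KineticFit", function(object) object@Te)

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit: lambdaE = %.4g 1/s, Te = %.3g h, r2 = %.3f (%s, n = %d)\n",
              object@lambdaE, object@Te, object@rSquared,
              if (object@usable) "usable" else "NOT usable",
              object@nPointsUsed))
})

#' Back-extrapolate the first-time-point activity
#'
#' A1 = A4 * exp(lambdaE * dt), with dt the time between the first and
#' fourth acquisitions: the background-corrected late activity projected
#' back along the fitted washout to the first acquisition.
#'
#' @param A4 background-corrected activity at the late time point, Bq.
#' @param fit a usable \linkS4class{KineticFit}.
#' @param deltaTh time difference in hours (>= 0).
#' @return A1 in Bq.
#' @examples
#' f <- new("KineticFit", alpha = 0, lambdaE = log(2)/(24*3600), Te = 24,
#'          rSquared = 1, usable = TRUE, nPointsUsed = 4L)
#' backExtrapolateA1(50e3, f, 71)  # 50e3 * 2^(71/24) = 388.6 kBq
#' @export
backExtrapolateA1 <- function(A4, fit, deltaTh) {
  if (!fit@usable)
    stop("kinetic fit is not usable; use the trapezoid fallback")
  if (deltaTh < 0) stop("deltaTh must be >= 0")
  A4 * exp(fit@lambdaE * hoursToSeconds(deltaTh))
}

#' Time-integrated disintegrations, closed form
#'
#' N = A1 * (t1/2 + 1/lambdaE) with t1 in seconds: a linear-uptake
#' triangle over [0, t1] plus the analytically integrated exponential
#' tail anchored at A1 at t1.
#'
#' @param A1 activity at the first acquisition, Bq.
#' @param fit a usable \linkS4class{KineticFit} (lambdaE > 0).
#' @param t1h first acquisition time in hours (> 0).
#' @return A \linkS4class{DisintegrationCount} with
#'   \code{method = "closed_form"}.
#' @export
integrateDisintegrations <- function(A1, fit, t1h) {
  if (!fit@usable || fit@lambdaE <= 0)
    stop("lambdaE <= 0 or unusable fit: trapezoid fallback required")
  if (t1h <= 0) stop("t1h must be > 0")
  if (A1 < 0) stop("A1 must be >= 0")
  N <- A1 * (hoursToSeconds(t1h) / 2 + 1 / fit@lambdaE)
  new("DisintegrationCount", N = N, method = "closed_form", A1Used = A1)
}

#' Time-integrated disintegrations, trapezoid with physical-decay tail
#'
#' Fallback when the mono-exponential fit is unusable: the same
#' linear-uptake triangle A(t1) * t1/2, plus trapezoidal integration of
#' the measured points over [t1, t4], plus an analytic tail A(t4) /
#' lambda_phys using the physical half-life of the nuclide (biological
#' retention assumed from the last time point on).
#'
#' @param tac a \linkS4class{TimeActivityCurve} (>= 2 uncensored points).
#' @param decay a \linkS4class{DecayData} supplying the physical
#'   half-life.
#' @return A \linkS4class{DisintegrationCount} with
#'   \code{method = "trapezoid_tail"}.
#' @export
integrateDisintegrationsTrapezoid <- function(tac, decay) {
  keep <- !tac@censored
  t <- hoursToSeconds(tac@times[keep])
  v <- tac@values[keep]
  if (length(t) < 2) stop("fewer than 2 points: cannot integrate")
  trap <- sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  lambdaPhys <- physicalDecayConstant(decay)
  N <- v[1] * t[1] / 2 + trap + v[length(v)] / lambdaPhys
  new("DisintegrationCount", N = N, method = "trapezoid_tail",
      A1Used = v[1])
}

setMethod("show", "DisintegrationCount", function(object) {
  cat(sprintf("DisintegrationCount: N = %.4g (%s, A1 = %.4g Bq)\n",
              object@N, object@method, object@A1Used))
})
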