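## Percent-intact-peptide quantification from radio-HPLC chromatograms and
## per-arm stability summaries.
##
## Conventions: median = midpoint (mean of central pair for even n);
## IQR = Q3 - Q1 with Tukey hinges (fivenum); reported values rounded
## half-up at the report layer only. Peaks are assigned by apex-in-window
## (no valley-to-valley deconvolution): all non-intact signal is treated
## as bulk metabolite area, appropriate when no distinct metabolite peaks
## are identifiable.

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

## Tukey-hinge interquartile range
tukeyIqr <- function(x) {
  f <- stats::fivenum(x)
  f[4] - f[2]
}

#' Percent intact peptide from a chromatogram
#'
#' Subtracts a linear baseline (between the trace endpoints, clipped at
#' zero), locates the peak whose apex lies within \code{intactRt +/-
#' tolerance}, integrates it valley-to-valley around the apex by the
#' trapezoid rule and reports its share of the total integrated area as a
#' percentage. The result is invariant under uniform rescaling of the
#' counts.
#'
#' @param chrom a \linkS4class{Chromatogram}.
#' @param intactRt retention time (min) of the intact radioligand.
#' @param tolerance apex acceptance window, min (default 0.5).
#' @return Percent intact in [0, 100].
#' @examples
#' c2 <- generateChromatogram(data.frame(rt_min = c(5, 9),
#'   area = c(750, 250), sd_min = c(0.15, 0.15)))
#' percentIntact(c2, intactRt = 5)   # 75
#' @export
percentIntact <- function(chrom, intactRt, tolerance = 0.5) {
  stopifnot(is(chrom, "Chromatogram"))
  rt <- chrom@rt
  if (intactRt < min(rt) || intactRt > max(rt))
    stop("intactRt outside the chromatogram grid")
  n <- length(rt)
  base <- chrom@counts[1] +
    (chrom@counts[n] - chrom@counts[1]) * (rt - rt[1]) / (rt[n] - rt[1])
  y <- pmax(chrom@counts - base, 0)
  total <- trapz(rt, y)
  if (total <= 0) stop("total integrated area is zero: percentage undefined")
  ## local maxima (plateau-tolerant)
  isMax <- which(diff(sign(diff(y))) < 0) + 1L
  isMax <- isMax[y[isMax] > 1e-9 * max(y)]
  inWin <- isMax[abs(rt[isMax] - intactRt) <= tolerance]
  if (!length(inWin)) {
    warning("no peak apex within the intact retention window; returning 0")
    return(0)
  }
  apex <- inWin[which.max(y[inWin])]
  lo <- apex
  while (lo > 1L && y[lo - 1L] <= y[lo] && y[lo] > 0) lo <- lo - 1L
  hi <- apex
  while (hi < n && y[hi + 1L] <= y[hi] && y[hi] > 0) hi <- hi + 1L
  100 * trapz(rt[lo:hi], y[lo:hi]) / total
}

#' Summarize a stability table by arm and time point
#'
#' Computes, per (arm, time) cell over evaluable patients only, the
#' midpoint median, the Tukey-hinge IQR and n, and per time point the
#' with/without fold change of medians. Folds are taken between medians
#' rounded half-up to \code{foldDigits} decimals (the convention of the
#' printed summary rows). Non-evaluable entries are excluded, never
#' imputed; an empty cell yields NA with n = 0.
#'
#' @param tab data.frame with columns \code{patient}, \code{arm} ("with"
#'   / "without"), \code{time_min}, \code{percent_intact},
#'   \code{evaluable} (logical).
#' @param foldDigits decimals for the fold's rounded medians (default 1).
#' @return A list with \code{cells} (arm, time_min, n, median, iqr) and
#'   \code{folds} (time_min, fold = median_with / median_without).
#' @export
stabilitySummary <- function(tab, foldDigits = 1) {
  stopifnot(all(c("patient", "arm", "time_min", "percent_intact",
                  "evaluable") %in% names(tab)))
  ev <- tab[tab$evaluable & !is.na(tab$percent_intact), ]
  times <- sort(unique(tab$time_min))
  cells <- do.call(rbind, lapply(times, function(tt) {
    do.call(rbind, lapply(c("without", "with"), function(a) {
      x <- ev$percent_intact[ev$arm == a & ev$time_min == tt]
      data.frame(arm = a, time_min = tt, n = length(x),
                 median = if (length(x)) stats::median(x) else NA_real_,
                 iqr = if (length(x)) tukeyIqr(x) else NA_real_)
    }))
  }))
  folds <- do.call(rbind, lapply(times, function(tt) {
    mw <- cells$median[cells$arm == "with" & cells$time_min == tt]
    mo <- cells$median[cells$arm == "without" & cells$time_min == tt]
    data.frame(time_min = tt,
               fold = roundHalfUp(mw, foldDigits) /
                 roundHalfUp(mo, foldDigits))
  }))
  list(cells = cells, folds = folds)
}
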