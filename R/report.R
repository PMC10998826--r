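## Report layer: the end-to-end tumor dosimetry pipeline on image data,
## and summary reports reproducing the study's stability/dose summary
## rows from the packaged fixtures (computed vs printed with match
## flags) or comparing a phantom run against its ground truth.

#' Full tumor dosimetry pipeline on a multi-time-point study
#'
#' Runs the complete estimator chain on calibrated activity volumes: on
#' the last (highest-SNR) acquisition an enclosing VOI is drawn and the
#' tumor is threshold-separated from background; the background-corrected
#' activity A4 is computed against the supplied anatomic volume; a 3-ml
#' hottest-voxel TAC is sampled independently per acquisition and fitted
#' log-linearly; A4 is back-extrapolated to the first acquisition and the
#' disintegration integral is taken in closed form (or, when the fit is
#' unusable, by trapezoid with a physical-decay tail after rescaling the
#' concentration TAC to the absolute A4 anchor); the absorbed dose is
#' N * E / (rho * Vct).
#'
#' @param volumes list of \linkS4class{ActivityVolume} covering the
#'   acquisition schedule (e.g. 1/4/24/72 h p.i.).
#' @param seedPoint voxel index (length 3) inside the tumor.
#' @param VctMl anatomic tumor volume in ml (input; not segmented here).
#' @param kernel an \linkS4class{EnergyDepositionKernel}.
#' @param decay \linkS4class{DecayData} for the trapezoid fallback tail.
#' @param dilationMm enclosing-VOI margin (default 15 mm).
#' @param step threshold-scan increment (default 0.01).
#' @param targetVolumeMl TAC sampling VOI volume (default 3 ml).
#' @param rho tissue density, g/cm3.
#' @return A list: \code{measurement} (\linkS4class{TumorMeasurement}),
#'   \code{A4}, \code{tac}, \code{fit}, \code{A1}, \code{N}
#'   (\linkS4class{DisintegrationCount}), \code{dose}
#'   (\linkS4class{DoseResult}).
#' @export
tumorDosimetry <- function(volumes, seedPoint, VctMl, kernel,
                           decay = lu177DecayData(), dilationMm = 15,
                           step = 0.01, targetVolumeMl = 3, rho = 1.0) {
  times <- vapply(volumes, function(v) v@timePostInjection, 0)
  o <- order(times)
  volumes <- volumes[o]; times <- times[o]
  late <- volumes[[length(volumes)]]
  enc <- encloseTumor(late, seedPoint, dilationMm)
  sep <- separateTumor(late, enc, step)
  m <- tumorMeasurement(A0 = voiActivity(late, enc),
                        V0 = voiVolume(enc),
                        Aspect = voiActivity(late, sep),
                        Vspect = voiVolume(sep), Vct = VctMl)
  A4 <- backgroundCorrectedActivity(m)
  tac <- sampleTac(volumes, seedPoint, targetVolumeMl)
  fit <- fitEffectiveHalfLife(tac)
  if (fit@usable) {
    A1 <- backExtrapolateA1(A4, fit, deltaTh = times[length(times)] - times[1])
    n <- integrateDisintegrations(A1, fit, t1h = times[1])
  } else {
    lastConc <- tac@values[length(tac@values)]
    if (lastConc <= 0) stop("cannot anchor trapezoid fallback: empty TAC")
    absTac <- timeActivityCurve(tac@times, tac@values * A4 / lastConc)
    n <- integrateDisintegrationsTrapezoid(absTac, decay)
    A1 <- n@A1Used
  }
  list(measurement = m, A4 = A4, tac = tac, fit = fit, A1 = A1, N = n,
       dose = tumorDose(n, kernel, VctMl, rho))
}

## decimals a printed number was typeset with (trailing zeros are lost in
## the numeric, so this is the minimal printed precision)
printedDecimals <- function(x) {
  s <- sub("0+$", "", sub(".*\\.", "", format(x, scientific = FALSE)))
  if (!grepl("\\.", format(x, scientific = FALSE))) 0L else nchar(s)
}

matchFlag <- function(computed, printed) {
  nd <- printedDecimals(printed)
  isTRUE(abs(roundHalfUp(computed, nd) - printed) < 10^(-nd) / 2)
}

#' Build the study summary report
#'
#' From the packaged fixtures: recomputes every summary statistic of the
#' stability and dosimetry tables (medians, IQRs, folds, exact Wilcoxon
#' signed-rank p-values) from the per-patient values and sets a match
#' flag against each printed cell; adds the per-lesion internal
#' consistency check of printed ratios against printed dose quotients,
#' and both per-time-point and pooled exact tests for stability. From a
#' phantom run (pass \code{study} and pipeline arguments via
#' \code{phantom}): tabulates truth-vs-estimate relative deviations.
#'
#' @param source "fixtures" or "phantom".
#' @param fixtures fixture list from \code{\link{clinicalFixtures}}
#'   (defaults to the packaged tables).
#' @param phantom for \code{source = "phantom"}: a list with elements
#'   \code{study} (result of \code{\link{generatePhantomStudy}}),
#'   \code{kernel}, \code{region} (label, default "tumor") and
#'   \code{seedPoint}.
#' @return A list of data.frames; for fixtures: \code{stability},
#'   \code{stabilityTests}, \code{doseSummary}, \code{ratioConsistency};
#'   for phantom: \code{truthVsEstimate}.
#' @export
buildReport <- function(source = c("fixtures", "phantom"),
                        fixtures = clinicalFixtures(), phantom = NULL) {
  source <- match.arg(source)
  if (source == "phantom") {
    if (is.null(phantom)) stop("phantom run inputs are missing")
    return(phantomReport(phantom))
  }
  if (is.null(fixtures$stability) || !nrow(fixtures$stability))
    stop("empty fixture input")

  ## --- stability ----------------------------------------------------
  ssum <- stabilitySummary(fixtures$stability)
  pr <- fixtures$printed
  stab <- ssum$cells
  stab$printedMedian <- mapply(function(a, tt) {
    v <- pr$printed[pr$table == "stability" & pr$arm == a &
                    pr$time_min == tt & pr$statistic == "median"]
    if (length(v)) v else NA_real_
  }, stab$arm, stab$time_min)
  stab$printedIqr <- mapply(function(a, tt) {
    v <- pr$printed[pr$table == "stability" & pr$arm == a &
                    pr$time_min == tt & pr$statistic == "iqr"]
    if (length(v)) v else NA_real_
  }, stab$arm, stab$time_min)
  stab$medianMatches <- mapply(matchFlag, stab$median, stab$printedMedian)
  stab$fold <- ssum$folds$fold[match(stab$time_min, ssum$folds$time_min)]

  ## per-time-point and pooled exact tests on evaluable pairs
  st <- fixtures$stability
  pairTab <- function(tt) {
    w <- st[st$arm == "with" & st$time_min == tt, ]
    o <- st[st$arm == "without" & st$time_min == tt, ]
    m <- merge(o[o$evaluable, c("patient", "percent_intact")],
               w[w$evaluable, c("patient", "percent_intact")],
               by = "patient", suffixes = c("_wo", "_w"))
    m
  }
  times <- sort(unique(st$time_min))
  stabilityTests <- do.call(rbind, lapply(times, function(tt) {
    m <- pairTab(tt)
    ts <- wilcoxonSignedRankExact(m$percent_intact_wo, m$percent_intact_w)
    data.frame(scope = paste0(tt, "_min"), n = ts@nEffective,
               p = ts@pTwoSided)
  }))
  allPairs <- do.call(rbind, lapply(times, pairTab))
  tsAll <- wilcoxonSignedRankExact(allPairs$percent_intact_wo,
                                   allPairs$percent_intact_w)
  stabilityTests <- rbind(stabilityTests,
    data.frame(scope = "pooled", n = tsAll@nEffective, p = tsAll@pTwoSided))

  ## --- dose endpoints ------------------------------------------------
  endpoints <- c("tumor_dose", "kidney_dose", "stomach_dose", "marrow_dose",
                 "ratio_kidney", "ratio_stomach", "ratio_marrow")
  doseSummary <- do.call(rbind, lapply(endpoints, function(ep) {
    pe <- pairedEndpoint(fixtures$doses, ep)
    digits <- if (grepl("^ratio", ep)) 1 else 2
    s <- summarizeEndpoint(pe$without, pe$with, digits = digits)
    prM <- function(a) {
      v <- pr$printed[pr$table == "dose" & pr$endpoint == ep &
                      pr$arm == a & pr$statistic == "median"]
      if (length(v)) v else NA_real_
    }
    pv <- pr$printed[pr$table == "dose" & pr$endpoint == ep &
                     pr$statistic == "p_wilcoxon"]
    data.frame(endpoint = ep, n = s$n,
               medianWithout = s$medianWithout, medianWith = s$medianWith,
               iqrWithout = s$iqrWithout, iqrWith = s$iqrWith,
               fold = s$fold, p = s$test@pTwoSided,
               printedMedianWithout = prM("without"),
               printedMedianWith = prM("with"),
               printedP = if (length(pv)) pv else NA_real_,
               medianWithoutMatches = matchFlag(s$medianWithout, prM("without")),
               medianWithMatches = matchFlag(s$medianWith, prM("with")),
               pMatches = isTRUE(roundHalfUp(s$test@pTwoSided, 2) ==
                                 if (length(pv)) pv else NA_real_))
  }))

  ## --- internal consistency of printed ratios ------------------------
  dx <- fixtures$doses
  tum <- dx[dx$endpoint == "tumor_dose", ]
  organOf <- c(ratio_kidney = "kidney_dose", ratio_stomach = "stomach_dose",
               ratio_marrow = "marrow_dose")
  ratioConsistency <- do.call(rbind, lapply(names(organOf), function(rep_) {
    rr <- dx[dx$endpoint == rep_, ]
    do.call(rbind, lapply(seq_len(nrow(rr)), function(i) {
      td <- tum$value[tum$patient == rr$patient[i] &
                      tum$lesion == rr$lesion[i] & tum$arm == rr$arm[i]]
      od <- dx$value[dx$endpoint == organOf[[rep_]] &
                     dx$patient == rr$patient[i] & dx$arm == rr$arm[i]]
      quot <- td / od
      ## both doses are printed rounded (half-ulp 0.005 at 2 dp), so the
      ## quotient carries a propagated rounding band, plus the half-ulp
      ## of the printed ratio itself
      tol <- quot * (0.005 / od + 0.005 / td) +
        0.5 * 10^(-printedDecimals(rr$value[i]))
      data.frame(endpoint = rep_, patient = rr$patient[i],
                 lesion = rr$lesion[i], arm = rr$arm[i],
                 printedRatio = rr$value[i], doseQuotient = quot,
                 consistent = abs(quot - rr$value[i]) <= tol)
    }))
  }))
  list(stability = stab, stabilityTests = stabilityTests,
       doseSummary = doseSummary, ratioConsistency = ratioConsistency)
}

phantomReport <- function(phantom) {
  study <- phantom$study
  kernel <- phantom$kernel
  region <- if (is.null(phantom$region)) "tumor" else phantom$region
  seedPoint <- phantom$seedPoint
  truth <- study$truth
  res <- tumorDosimetry(study$volumes, seedPoint,
                        VctMl = truth@vctMl[[region]], kernel = kernel)
  TeTrue <- {
    acts <- truth@activities[truth@activities$region == region, ]
    tt <- acts$time_h; aa <- acts$activity_Bq
    -log(2) / stats::coef(stats::lm(log(aa) ~ tt))[2]
  }
  dTrue <- trueDose(truth, region, kernel@ECenter)
  tab <- data.frame(
    quantity = c("Te_h", "N", "dose_Gy"),
    truth = c(unname(TeTrue), unname(truth@trueN[region]), dTrue),
    estimate = c(res$fit@Te, res$N@N, res$dose@D))
  tab$relDev <- tab$estimate / tab$truth - 1
  list(truthVsEstimate = tab, pipeline = res)
}

#' Write a report bundle to CSV files
#'
#' @param report result of \code{\link{buildReport}}.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
exportReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}
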