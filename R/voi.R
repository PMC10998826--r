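## VOI construction and the background-corrected tumor activity estimator.
## Threshold separation uses 26-connectivity; partial-volume voxels are
## assigned by voxel-center membership; spill-in/out is deliberately not
## corrected (matching the estimator this package implements).

## 26-neighbourhood offsets
neighborOffsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

## connected component (26-connectivity) of `mask` containing voxel `start`
connectedComponent <- function(mask, start) {
  d <- dim(mask)
  if (!mask[start[1], start[2], start[3]]) return(array(FALSE, d))
  comp <- array(FALSE, d)
  comp[start[1], start[2], start[3]] <- TRUE
  frontier <- matrix(start, nrow = 1)
  while (nrow(frontier)) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = 26), , drop = FALSE] +
      neighborOffsets26[rep(seq_len(26), nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- unique(cand[ok, , drop = FALSE])
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
    keep <- mask[lin] & !comp[lin]
    comp[lin[keep]] <- TRUE
    frontier <- cand[keep, , drop = FALSE]
  }
  comp
}

## binary dilation by a ball of `radiusMm`
dilateBall <- function(mask, radiusMm, voxelSize) {
  rVox <- floor(radiusMm / voxelSize + 1e-9)
  if (rVox < 1) return(mask)
  g <- as.matrix(expand.grid(-rVox:rVox, -rVox:rVox, -rVox:rVox))
  g <- g[sqrt(rowSums(g^2)) * voxelSize <= radiusMm + 1e-9, , drop = FALSE]
  d <- dim(mask)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(g))) {
    sx <- pmax(1, 1 - g[r, 1]):pmin(d[1], d[1] - g[r, 1])
    sy <- pmax(1, 1 - g[r, 2]):pmin(d[2], d[2] - g[r, 2])
    sz <- pmax(1, 1 - g[r, 3]):pmin(d[3], d[3] - g[r, 3])
    out[sx + g[r, 1], sy + g[r, 2], sz + g[r, 3]] <-
      out[sx + g[r, 1], sy + g[r, 2], sz + g[r, 3]] | mask[sx, sy, sz]
  }
  out
}

maskToVoi <- function(mask, voxelSize) {
  idx <- which(mask, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  new("VOI", indices = idx, gridDim = dim(mask), voxelSize = voxelSize)
}

voiToMask <- function(voi) {
  m <- array(FALSE, voi@gridDim)
  if (nrow(voi@indices)) m[voi@indices] <- TRUE
  m
}

#' VOI volume in ml
#'
#' @param object a \linkS4class{VOI}.
#' @return Volume in ml (voxel count times voxel volume).
#' @export
setMethod("voiVolume", "VOI", function(object)
  nrow(object@indices) * (object@voxelSize^3 / 1000))

#' VOI activity
#'
#' Sum of concentration times voxel volume over the VOI, in Bq.
#'
#' @param object an \linkS4class{ActivityVolume}.
#' @param voi a \linkS4class{VOI} on the same grid.
#' @return Activity in Bq.
#' @export
setMethod("voiActivity", signature("ActivityVolume", "VOI"),
  function(object, voi) {
    stopifnot(all(dim(object@voxels) == voi@gridDim))
    sum(object@voxels[voi@indices]) * voxelVolumeMl(object)
  })

#' VOI mean concentration
#'
#' @param object an \linkS4class{ActivityVolume}.
#' @param voi a \linkS4class{VOI} on the same grid.
#' @return Mean concentration in Bq/ml over the VOI.
#' @export
setMethod("voiMeanConcentration", signature("ActivityVolume", "VOI"),
  function(object, voi) {
    stopifnot(all(dim(object@voxels) == voi@gridDim))
    mean(object@voxels[voi@indices])
  })

setMethod("show", "VOI", function(object) {
  cat(sprintf("VOI: %d voxels, %.3g ml on a %s grid\n",
              nrow(object@indices), voiVolume(object),
              paste(object@gridDim, collapse = "x")))
})

#' Draw an enclosing VOI around a tumor
#'
#' Surrogate for the manual enclosing VOI of clinical workflows: the
#' 26-connected super-threshold blob containing the seed (threshold a
#' fraction of the seed voxel value) dilated by a ball of the given
#' margin, so that the VOI contains the tumor and a surrounding
#' background shell. Its volume/activity are the (V0, A0) of the
#' background-correction estimator.
#'
#' @param vol an \linkS4class{ActivityVolume}.
#' @param seedPoint voxel index (length 3, 1-based) inside the tumor.
#' @param dilationMm margin in mm (> 0).
#' @param relThreshold blob threshold as a fraction of the seed voxel
#'   value (default 0.5).
#' @return A \linkS4class{VOI}.
#' @export
encloseTumor <- function(vol, seedPoint, dilationMm = 10, relThreshold = 0.5) {
  stopifnot(is(vol, "ActivityVolume"), dilationMm > 0)
  d <- dim(vol@voxels)
  seedPoint <- as.integer(seedPoint)
  if (any(seedPoint < 1L) || any(seedPoint > d))
    stop("seed point outside the grid")
  v <- vol@voxels[seedPoint[1], seedPoint[2], seedPoint[3]]
  if (v <= 0) {
    warning("seed voxel has zero activity")
    stop("cannot grow an enclosing VOI from a zero-activity seed")
  }
  blob <- connectedComponent(vol@voxels >= relThreshold * v, seedPoint)
  maskToVoi(dilateBall(blob, dilationMm, vol@voxelSize), vol@voxelSize)
}

#' Separate tumor activity from background by threshold scanning
#'
#' Scans a relative threshold upward in steps of \code{step} times the
#' enclosing-VOI maximum. At each threshold the 26-connected component
#' containing the hottest voxel is formed; the first (lowest) threshold
#' whose component contains no voxel 26-adjacent to the outside of the
#' enclosing VOI is accepted. Its volume/activity are (Vspect, Aspect).
#' When no threshold separates the tumor from the VOI edge (e.g. a tumor
#' abutting a vessel running through the VOI face) a separation-failure
#' error is raised - the non-evaluable case of clinical practice.
#'
#' @param vol an \linkS4class{ActivityVolume}.
#' @param enclosing the enclosing \linkS4class{VOI} from
#'   \code{\link{encloseTumor}}.
#' @param step relative threshold increment (default 0.01 of the VOI max).
#' @return A \linkS4class{VOI}.
#' @export
separateTumor <- function(vol, enclosing, step = 0.01) {
  stopifnot(is(vol, "ActivityVolume"), is(enclosing, "VOI"))
  if (!nrow(enclosing@indices)) stop("enclosing VOI is empty")
  encMask <- voiToMask(enclosing)
  vals <- vol@voxels
  vmax <- max(vals[encMask])
  if (vmax <= 0) stop("enclosing VOI contains no activity")
  hot <- which(encMask & vals == vmax, arr.ind = TRUE)[1, ]
  d <- dim(vals)
  touchesEdge <- function(comp) {
    idx <- which(comp, arr.ind = TRUE)
    for (r in seq_len(26)) {
      nb <- sweep(idx, 2, neighborOffsets26[r, ], "+")
      out <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
             nb[, 3] < 1 | nb[, 3] > d[3]
      if (any(out)) return(TRUE)
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      if (any(!encMask[lin])) return(TRUE)
    }
    FALSE
  }
  for (f in seq(step, 1 - step, by = step)) {
    mask <- encMask & vals > f * vmax
    if (!mask[hot[1], hot[2], hot[3]]) break
    comp <- connectedComponent(mask, hot)
    if (!touchesEdge(comp)) return(maskToVoi(comp, vol@voxelSize))
  }
  stop("separation failure: tumor component touches the enclosing VOI ",
       "boundary at every threshold")
}

#' Construct a TumorMeasurement
#'
#' @param A0,V0 enclosing VOI activity (Bq) and volume (ml).
#' @param Aspect,Vspect separated tumor VOI activity (Bq) and volume (ml).
#' @param Vct anatomic tumor volume (ml), e.g. from contrast CT.
#' @return A \linkS4class{TumorMeasurement}.
#' @export
tumorMeasurement <- function(A0, V0, Aspect, Vspect, Vct) {
  if (Vct <= 0) stop("Vct must be > 0")
  ## tolerate last-ulp noise when Vspect and Vct come from the same grid
  if (Vspect < Vct * (1 - 1e-12)) stop("invalid geometry: Vspect < Vct")
  Vspect <- max(Vspect, Vct)
  if (V0 == Vspect) stop("V0 equals Vspect: background term undefined")
  new("TumorMeasurement", A0 = A0, V0 = V0, Aspect = Aspect,
      Vspect = Vspect, Vct = Vct)
}

#' Background-corrected tumor activity
#'
#' The estimator
#' \deqn{A_4 = A_{spect} - \frac{A_0 - A_{spect}}{V_0 - V_{spect}}
#'       (V_{spect} - V_{CT})}
#' where the second term removes the background contribution inside the
#' separated VOI: the bracketed ratio is the background concentration
#' estimated from the shell between the enclosing and separated VOIs, and
#' (Vspect - Vct) is the background volume mixed into the separated VOI.
#' Negative results are clipped to zero with a warning.
#'
#' @param object a \linkS4class{TumorMeasurement}.
#' @param ... ignored.
#' @return A4 in Bq.
#' @examples
#' m <- tumorMeasurement(A0 = 120e3, V0 = 100, Aspect = 100e3,
#'                       Vspect = 30, Vct = 20)
#' backgroundCorrectedActivity(m)   # 97142.9 Bq
#' @export
setMethod("backgroundCorrectedActivity", "TumorMeasurement",
  function(object, ...) {
    bg <- (object@A0 - object@Aspect) / (object@V0 - object@Vspect)
    a4 <- object@Aspect - bg * (object@Vspect - object@Vct)
    if (a4 < 0) {
      warning("background correction produced a negative activity; ",
              "clipping to 0")
      a4 <- 0
    }
    a4
  })

setMethod("show", "TumorMeasurement", function(object) {
  cat(sprintf(paste0("TumorMeasurement: A0 = %.4g Bq, V0 = %.3g ml, ",
                     "Aspect = %.4g Bq, Vspect = %.3g ml, Vct = %.3g ml\n"),
              object@A0, object@V0, object@Aspect, object@Vspect,
              object@Vct))
  cat(sprintf("  A4 (background-corrected) = %.4g Bq\n",
              suppressWarnings(backgroundCorrectedActivity(object))))
})

#' Fixed-volume hottest-voxel sampling VOI
#'
#' Grows a 26-connected set of hottest voxels around the seed until its
#' volume is nearest the target (default 3 ml): seeded at the hottest
#' voxel of the seed's 3x3x3 neighbourhood, then repeatedly adding the
#' hottest neighbouring voxel. The mean concentration over this VOI is
#' the time-activity-curve sample for that acquisition.
#'
#' @param vol an \linkS4class{ActivityVolume}.
#' @param seedPoint voxel index (length 3, 1-based).
#' @param targetVolumeMl target VOI volume in ml (default 3).
#' @return A \linkS4class{VOI}.
#' @export
tacVoi <- function(vol, seedPoint, targetVolumeMl = 3) {
  stopifnot(is(vol, "ActivityVolume"))
  d <- dim(vol@voxels)
  voxMl <- voxelVolumeMl(vol)
  if (targetVolumeMl < voxMl)
    stop("target volume is smaller than one voxel")
  nTarget <- max(1L, round(targetVolumeMl / voxMl))
  if (nTarget > prod(d)) stop("grid too small for the requested volume")
  seedPoint <- as.integer(seedPoint)
  if (any(seedPoint < 1L) || any(seedPoint > d))
    stop("seed point outside the grid")
  ## start at the hottest voxel of the seed's immediate neighbourhood
  nb <- rbind(seedPoint, sweep(neighborOffsets26, 2, seedPoint, "+"))
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb <- nb[ok, , drop = FALSE]
  lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
  cur <- nb[which.max(vol@voxels[lin]), ]
  inVoi <- array(FALSE, d)
  inVoi[cur[1], cur[2], cur[3]] <- TRUE
  members <- matrix(cur, nrow = 1)
  while (nrow(members) < nTarget) {
    cand <- members[rep(seq_len(nrow(members)), each = 26), , drop = FALSE] +
      neighborOffsets26[rep(seq_len(26), nrow(members)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
          cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- unique(cand[ok, , drop = FALSE])
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
    cand <- cand[!inVoi[lin], , drop = FALSE]
    if (!nrow(cand)) break
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
    best <- which.max(vol@voxels[lin])
    inVoi[lin[best]] <- TRUE
    members <- rbind(members, cand[best, ])
  }
  maskToVoi(inVoi, vol@voxelSize)
}

#' Sample a time-activity curve across a phantom/patient study
#'
#' Draws an independent fixed-volume hottest-voxel VOI
#' (\code{\link{tacVoi}}) in each acquisition and records its mean
#' concentration, producing a shape-only concentration TAC.
#'
#' @param volumes list of \linkS4class{ActivityVolume} (any order; sorted
#'   by acquisition time).
#' @param seedPoint voxel index (length 3).
#' @param targetVolumeMl sampling VOI volume in ml (default 3).
#' @return A \linkS4class{TimeActivityCurve} with
#'   \code{valueKind = "concentration"}.
#' @export
sampleTac <- function(volumes, seedPoint, targetVolumeMl = 3) {
  times <- vapply(volumes, function(v) v@timePostInjection, 0)
  o <- order(times)
  vals <- vapply(volumes[o], function(v)
    voiMeanConcentration(v, tacVoi(v, seedPoint, targetVolumeMl)), 0)
  timeActivityCurve(times[o], vals, valueKind = "concentration")
}
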