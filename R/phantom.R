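## Synthetic-data stage: digital phantoms emulating post-reconstruction
## quantitative SPECT (activity map -> Gaussian PSF -> voxelwise Poisson
## noise -> rescale to Bq/ml), plus synthetic radio-HPLC chromatograms.
## Every stochastic step is driven by one integer seed; the global RNG
## state is restored afterwards.

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct a phantom region
#'
#' @param label region label ("tumor", "stomach_wall", "kidney",
#'   "background", or free text).
#' @param center ellipsoid center in mm (world coordinates).
#' @param semiAxes ellipsoid semi-axes in mm (length 1 is recycled).
#' @param Aref activity (Bq) at reference time \code{tRef}.
#' @param Te effective half-life in hours (may be \code{Inf}).
#' @param tRef reference time (h p.i.) at which the region holds
#'   \code{Aref}; default 0.
#' @param uptake "instantaneous" (default; exponential from t = 0) or
#'   "linear_rise" (linear from 0 to the first acquisition time).
#' @return A \linkS4class{PhantomRegion}.
#' @export
phantomRegion <- function(label, center, semiAxes, Aref, Te,
                          tRef = 0, uptake = "instantaneous") {
  if (length(semiAxes) == 1) semiAxes <- rep(semiAxes, 3)
  new("PhantomRegion", label = label, center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), Aref = Aref, TeRef = Te,
      tRef = tRef, uptake = uptake)
}

#' Construct a phantom study specification
#'
#' Defaults mirror a clinical Lu-177 protocol: acquisitions at 1, 4, 24
#' and 72 h p.i. on an isotropic grid.
#'
#' @param gridShape voxels per axis (length 1 recycled to 3).
#' @param voxelSize isotropic voxel size, mm.
#' @param regions list of \code{\link{phantomRegion}} objects.
#' @param acquisitionTimes hours p.i., strictly increasing.
#' @param psfFwhm Gaussian PSF FWHM in mm (0 disables blurring).
#' @param noiseModel "none" or "poisson".
#' @param countsPerBq Poisson scale (expected counts per Bq per voxel).
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = 48L, voxelSize = 5.08, regions = list(),
                        acquisitionTimes = c(1, 4, 24, 72), psfFwhm = 0,
                        noiseModel = c("none", "poisson"),
                        countsPerBq = 20, seed = 1L) {
  if (length(gridShape) == 1) gridShape <- rep(gridShape, 3)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, regions = regions,
      acquisitionTimes = acquisitionTimes, psfFwhm = psfFwhm,
      noiseModel = match.arg(noiseModel), countsPerBq = countsPerBq,
      seed = as.integer(seed))
}

## voxel-center membership rasterization of one ellipsoid -> logical array
rasterizeRegion <- function(region, gridShape, voxelSize) {
  cx <- (seq_len(gridShape[1]) - 0.5) * voxelSize
  cy <- (seq_len(gridShape[2]) - 0.5) * voxelSize
  cz <- (seq_len(gridShape[3]) - 0.5) * voxelSize
  dx2 <- ((cx - region@center[1]) / region@semiAxes[1])^2
  dy2 <- ((cy - region@center[2]) / region@semiAxes[2])^2
  dz2 <- ((cz - region@center[3]) / region@semiAxes[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

## true region activity (Bq) at time t hours under the region's kinetics
regionActivityAt <- function(region, t, t1 = NULL) {
  A0 <- region@Aref * 2^(region@tRef / region@TeRef)   # value at t = 0
  inst <- A0 * 2^(-t / region@TeRef)
  if (region@uptake == "linear_rise" && !is.null(t1)) {
    at1 <- A0 * 2^(-t1 / region@TeRef)
    ifelse(t < t1, at1 * t / t1, inst)
  } else inst
}

## separable zero-padded Gaussian convolution of a 3-D array
gaussianBlur3d <- function(arr, sigmaVox) {
  if (sigmaVox <= 0) return(arr)
  half <- max(1L, ceiling(4 * sigmaVox))
  k <- stats::dnorm(seq(-half, half), sd = sigmaVox)
  k <- k / sum(k)
  convAxis <- function(a, axis) {
    out <- array(0, dim(a))
    n <- dim(a)[axis]
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      idxTo <- which(ok); idxFrom <- src[ok]
      if (axis == 1) out[idxTo, , ] <- out[idxTo, , ] + k[j] * a[idxFrom, , ]
      else if (axis == 2) out[, idxTo, ] <- out[, idxTo, ] + k[j] * a[, idxFrom, ]
      else out[, , idxTo] <- out[, , idxTo] + k[j] * a[, , idxFrom]
    }
    out
  }
  convAxis(convAxis(convAxis(arr, 1), 2), 3)
}

#' PhantomGroundTruth accessors are plain slots; see generatePhantomStudy.
#'
#' @slot activities data.frame (region, time_h, activity_Bq): closed-form
#'   regional truth at each acquisition time.
#' @slot vctMl named numeric, rasterized region volumes in ml.
#' @slot trueN named numeric, analytically integrated disintegrations per
#'   region (0 to infinity under the region's kinetic model).
#' @slot regionLabels character vector.
#' @export
setClass("PhantomGroundTruth",
  representation(activities = "data.frame", vctMl = "numeric",
                 trueN = "numeric", regionLabels = "character"))

#' True absorbed dose of a phantom region
#'
#' Closed-form dose D = N * E / (rho * V) with rho = 1 g/cm3, for checking
#' pipeline estimates against ground truth.
#'
#' @param truth a \linkS4class{PhantomGroundTruth}.
#' @param region region label.
#' @param EJoule energy per decay deposited in the target, J (e.g. the
#'   center-voxel kernel energy).
#' @return Dose in Gy.
#' @export
trueDose <- function(truth, region, EJoule) {
  stopifnot(region %in% truth@regionLabels)
  massKg <- truth@vctMl[region] * 1e-3
  unname(truth@trueN[region] * EJoule / massKg)
}

#' Generate a synthetic multi-time-point SPECT study
#'
#' Builds one calibrated activity volume per acquisition time from the
#' regional mono-exponential kinetics, then applies (optionally) a
#' Gaussian PSF and voxelwise Poisson noise on a counts scale, rescaled
#' back to Bq/ml. Before degradation, the voxel sum over each region
#' equals the region's closed-form activity exactly (uniform fill over
#' the rasterized mask). Ground truth is returned alongside.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A list with elements \code{volumes} (list of
#'   \linkS4class{ActivityVolume}, one per acquisition time),
#'   \code{truth} (\linkS4class{PhantomGroundTruth}) and \code{masks}
#'   (named list of logical arrays, the rasterized region masks).
#' @examples
#' sp <- phantomSpec(gridShape = 24L, voxelSize = 5.08,
#'   regions = list(phantomRegion("tumor", center = rep(60, 3),
#'                                semiAxes = 12, Aref = 1e6, Te = 30)))
#' study <- generatePhantomStudy(sp)
#' sapply(study$volumes, function(v) sum(v@voxels) * 5.08^3 / 1000)
#' @export
generatePhantomStudy <- function(spec) {
  validObject(spec)
  if (!length(spec@regions)) stop("spec contains no regions")
  if (any(vapply(spec@regions, function(r) r@Aref, 0) < 0))
    stop("negative region activity")
  vs <- spec@voxelSize
  voxMl <- vs^3 / 1000
  masks <- lapply(spec@regions, rasterizeRegion,
                  gridShape = spec@gridShape, voxelSize = vs)
  labels <- vapply(spec@regions, function(r) r@label, "")
  names(masks) <- labels
  if (anyDuplicated(labels)) stop("duplicate region labels")
  nvox <- vapply(masks, sum, 0)
  if (any(nvox == 0)) stop("region rasterizes to zero voxels: ",
                           paste(labels[nvox == 0], collapse = ", "))
  cover <- Reduce(`+`, masks)
  if (any(cover > 1)) stop("regions overlap after rasterization")

  t1 <- spec@acquisitionTimes[1]
  lambdaS <- log(2) / hoursToSeconds(
    vapply(spec@regions, function(r) r@TeRef, 0))
  trueN <- vapply(seq_along(spec@regions), function(i) {
    r <- spec@regions[[i]]
    if (r@Aref == 0) return(0)
    if (!is.finite(r@TeRef)) return(Inf)
    if (r@uptake == "linear_rise") {
      at1 <- regionActivityAt(r, t1, t1)
      at1 * (hoursToSeconds(t1) / 2 + 1 / lambdaS[i])
    } else {
      regionActivityAt(r, 0) / lambdaS[i]
    }
  }, 0)
  names(trueN) <- labels
  acts <- do.call(rbind, lapply(spec@acquisitionTimes, function(tt) {
    data.frame(region = labels, time_h = tt,
               activity_Bq = vapply(spec@regions, regionActivityAt, 0,
                                    t = tt, t1 = t1))
  }))
  truth <- new("PhantomGroundTruth", activities = acts,
               vctMl = stats::setNames(nvox * voxMl, labels),
               trueN = trueN, regionLabels = labels)

  sigmaVox <- spec@psfFwhm / (2 * sqrt(2 * log(2))) / vs
  volumes <- withLocalSeed(spec@seed, {
    lapply(spec@acquisitionTimes, function(tt) {
      img <- array(0, spec@gridShape)
      for (i in seq_along(spec@regions)) {
        a <- regionActivityAt(spec@regions[[i]], tt, t1)
        img[masks[[i]]] <- a / (nvox[i] * voxMl)      # Bq/ml, sums exactly
      }
      img <- gaussianBlur3d(img, sigmaVox)
      if (spec@noiseModel == "poisson") {
        lam <- img * voxMl * spec@countsPerBq
        img <- array(stats::rpois(length(lam), lam), dim(lam)) /
          (voxMl * spec@countsPerBq)
      }
      new("ActivityVolume", voxels = img, voxelSize = vs,
          origin = c(0, 0, 0), timePostInjection = tt)
    })
  })
  list(volumes = volumes, truth = truth, masks = masks)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid @ %.3g mm, %d region(s), t = %s h\n",
              paste(object@gridShape, collapse = "x"), object@voxelSize,
              length(object@regions),
              paste(object@acquisitionTimes, collapse = "/")))
  cat(sprintf("  PSF FWHM %.1f mm, noise %s, seed %d\n", object@psfFwhm,
              object@noiseModel, object@seed))
})

#' Generate a synthetic radio-HPLC chromatogram
#'
#' Sampled trace = baseline + sum of Gaussian peaks + optional white
#' noise. Peak areas are in signal*min units; the noiseless integral of
#' each peak reproduces its specified area to < 0.1% provided the peak
#' lies well inside the retention window.
#'
#' @param peaks data.frame with columns \code{rt_min} (apex), \code{area}
#'   and \code{sd_min} (Gaussian sigma); may have zero rows.
#' @param baseline constant baseline level.
#' @param noiseSd standard deviation of additive Gaussian noise (0 = none).
#' @param rtRange retention window in minutes.
#' @param dt sampling interval, minutes.
#' @param seed integer seed (used only when noiseSd > 0).
#' @param metadata list attached to the object.
#' @return A \linkS4class{Chromatogram}.
#' @export
generateChromatogram <- function(peaks = data.frame(rt_min = numeric(),
                                                    area = numeric(),
                                                    sd_min = numeric()),
                                 baseline = 0, noiseSd = 0,
                                 rtRange = c(0, 15), dt = 0.01, seed = 1L,
                                 metadata = list()) {
  if (nrow(peaks)) {
    stopifnot(all(peaks$area >= 0), all(peaks$sd_min > 0))
    if (any(peaks$rt_min < rtRange[1] | peaks$rt_min > rtRange[2]))
      stop("peak retention times must lie within rtRange")
  }
  rt <- seq(rtRange[1], rtRange[2], by = dt)
  counts <- rep(baseline, length(rt))
  for (i in seq_len(nrow(peaks)))
    counts <- counts + peaks$area[i] *
      stats::dnorm(rt, peaks$rt_min[i], peaks$sd_min[i])
  if (noiseSd > 0)
    counts <- withLocalSeed(seed,
      counts + stats::rnorm(length(rt), sd = noiseSd))
  new("Chromatogram", rt = rt, counts = counts, metadata = metadata)
}

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram: %d points, rt %.2f-%.2f min, max %.4g\n",
              length(object@rt), min(object@rt), max(object@rt),
              max(object@counts)))
})
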