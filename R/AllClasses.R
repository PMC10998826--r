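## S4 class definitions for the dosimetry pipeline.

#' @import methods
NULL

#' DecayData: radionuclide decay data
#'
#' Physical half-life plus discrete electron and photon emission lines
#' (energy in keV, yield per decay). Beta branches may be represented as
#' mean-energy lines or as a sampled/binned spectrum; the packaged Lu-177
#' table uses mean-energy branch lines.
#'
#' @slot nuclide character, e.g. "Lu-177".
#' @slot halfLifeS physical half-life in seconds.
#' @slot electrons data.frame with columns \code{E_keV}, \code{yield}.
#' @slot photons data.frame with columns \code{E_keV}, \code{yield}.
#' @slot source character, provenance note of the data file.
#' @export
setClass("DecayData",
  representation(nuclide = "character", halfLifeS = "numeric",
                 electrons = "data.frame", photons = "data.frame",
                 source = "character"),
  prototype(nuclide = NA_character_, halfLifeS = NA_real_,
            electrons = data.frame(E_keV = numeric(), yield = numeric()),
            photons = data.frame(E_keV = numeric(), yield = numeric()),
            source = ""))

setValidity("DecayData", function(object) {
  msg <- character()
  if (!is.na(object@halfLifeS) && object@halfLifeS <= 0)
    msg <- c(msg, "halfLifeS must be > 0")
  for (nm in c("electrons", "photons")) {
    tab <- slot(object, nm)
    if (!all(c("E_keV", "yield") %in% names(tab)))
      msg <- c(msg, sprintf("%s needs columns E_keV, yield", nm))
    else {
      if (any(tab$E_keV <= 0)) msg <- c(msg, sprintf("%s energies must be > 0", nm))
      if (any(tab$yield < 0)) msg <- c(msg, sprintf("%s yields must be >= 0", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ActivityVolume: calibrated 3-D activity-concentration image
#'
#' A single quantitative (post-reconstruction) emission-tomography volume:
#' voxel values are activity concentrations in Bq/ml on an isotropic grid.
#' Negative reconstruction values are disallowed (clip-at-zero policy is
#' applied by the constructors that produce these objects).
#'
#' @slot voxels 3-D numeric array, Bq/ml.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot origin world position (mm) of the corner of voxel (1,1,1);
#'   world = origin + (index - 0.5) * voxelSize for voxel centers.
#' @slot timePostInjection acquisition time, hours post injection.
#' @export
setClass("ActivityVolume",
  representation(voxels = "array", voxelSize = "numeric",
                 origin = "numeric", timePostInjection = "numeric"),
  prototype(voxels = array(0, c(1, 1, 1)), voxelSize = 1,
            origin = c(0, 0, 0), timePostInjection = 0))

setValidity("ActivityVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3-D array")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (any(object@voxels < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' VOI: volume of interest on an ActivityVolume grid
#'
#' A set of voxel indices (rows of an n x 3 integer matrix, 1-based) on a
#' named grid. Derived volume and activity are obtained with
#' \code{\link{voiVolume}} and \code{\link{voiActivity}}.
#'
#' @slot indices integer matrix, n x 3, 1-based voxel indices.
#' @slot gridDim integer vector of the host grid dimensions.
#' @slot voxelSize voxel edge length in mm (copied from the host volume).
#' @export
setClass("VOI",
  representation(indices = "matrix", gridDim = "integer", voxelSize = "numeric"),
  prototype(indices = matrix(integer(), ncol = 3), gridDim = c(1L, 1L, 1L),
            voxelSize = 1))

setValidity("VOI", function(object) {
  msg <- character()
  if (ncol(object@indices) != 3L) msg <- c(msg, "indices must be n x 3")
  if (nrow(object@indices)) {
    if (any(object@indices < 1L) ||
        any(t(object@indices) > object@gridDim))
      msg <- c(msg, "indices out of grid bounds")
  }
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' TumorMeasurement: the five measured tumor quantities
#'
#' Holds the enclosing-VOI activity/volume (A0, V0), the threshold-separated
#' tumor VOI activity/volume (Aspect, Vspect), the anatomic (CT) tumor
#' volume Vct, and makes the background-corrected activity A4 available via
#' \code{\link{backgroundCorrectedActivity}}.
#'
#' @slot A0 Bq, enclosing VOI activity.
#' @slot V0 ml, enclosing VOI volume.
#' @slot Aspect Bq, separated tumor VOI activity.
#' @slot Vspect ml, separated tumor VOI volume.
#' @slot Vct ml, anatomic tumor volume (input, e.g. from CT).
#' @export
setClass("TumorMeasurement",
  representation(A0 = "numeric", V0 = "numeric", Aspect = "numeric",
                 Vspect = "numeric", Vct = "numeric"))

setValidity("TumorMeasurement", function(object) {
  msg <- character()
  if (object@Vct <= 0) msg <- c(msg, "Vct must be > 0")
  if (object@Vspect < object@Vct) msg <- c(msg, "need Vspect >= Vct")
  if (object@V0 <= object@Vspect) msg <- c(msg, "need V0 > Vspect")
  if (object@Aspect < 0 || object@A0 < object@Aspect)
    msg <- c(msg, "need A0 >= Aspect >= 0")
  if (length(msg)) msg else TRUE
})

#' TimeActivityCurve: sampled regional activity over time
#'
#' @slot times hours post injection, strictly increasing.
#' @slot values activity (Bq) or mean concentration (Bq/ml), >= 0.
#' @slot valueKind "activity" or "concentration".
#' @slot censored logical per point; censored points are excluded from fits.
#' @export
setClass("TimeActivityCurve",
  representation(times = "numeric", values = "numeric",
                 valueKind = "character", censored = "logical"),
  prototype(valueKind = "activity"))

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values) ||
      length(object@times) != length(object@censored))
    msg <- c(msg, "times, values, censored must have equal length")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@values < 0)) msg <- c(msg, "values must be >= 0")
  if (!object@valueKind %in% c("activity", "concentration"))
    msg <- c(msg, "valueKind must be 'activity' or 'concentration'")
  if (length(msg)) msg else TRUE
})

#' KineticFit: mono-exponential washout fit on the log scale
#'
#' Result of regressing log activity on time. \code{lambdaE} is defined
#' as the negative of the log-linear slope (so lambdaE > 0 for washout) in
#' 1/s; \code{Te} = ln(2)/lambdaE in hours when lambdaE > 0.
#'
#' @slot alpha intercept of the log-linear model (log Bq at t = 0).
#' @slot lambdaE effective decay constant, 1/s (negative slope).
#' @slot Te effective half-life in hours (NA when not usable).
#' @slot rSquared coefficient of determination of the log-linear fit.
#' @slot usable logical; FALSE triggers the trapezoid fallback.
#' @slot nPointsUsed number of points entering the fit.
#' @export
setClass("KineticFit",
  representation(alpha = "numeric", lambdaE = "numeric", Te = "numeric",
                 rSquared = "numeric", usable = "logical",
                 nPointsUsed = "integer"))

#' DisintegrationCount: time-integrated activity
#'
#' @slot N total number of disintegrations (dimensionless).
#' @slot method "closed_form" or "trapezoid_tail".
#' @slot A1Used the first-time-point activity (Bq) anchoring the integral.
#' @export
setClass("DisintegrationCount",
  representation(N = "numeric", method = "character", A1Used = "numeric"))

setValidity("DisintegrationCount", function(object) {
  if (object@N < 0) "N must be >= 0" else TRUE
})

#' EnergyDepositionKernel: per-decay voxel energy deposition
#'
#' Monte-Carlo estimate of the mean energy (J) deposited per decay in the
#' voxel containing a point source, with the surrounding scored voxels kept
#' for energy-conservation checks.
#'
#' @slot voxelSize scoring voxel edge length, mm.
#' @slot ECenter mean energy per decay in the center voxel, J.
#' @slot se Monte-Carlo standard error of ECenter, J.
#' @slot neighborEnergy 3-D array (J/decay) of the scored kernel, center
#'   voxel at the middle; energy escaping the scored extent is dropped.
#' @slot nDecays number of simulated decays.
#' @slot seed RNG seed used.
#' @export
setClass("EnergyDepositionKernel",
  representation(voxelSize = "numeric", ECenter = "numeric", se = "numeric",
                 neighborEnergy = "array", nDecays = "numeric",
                 seed = "integer"))

setValidity("EnergyDepositionKernel", function(object) {
  if (object@ECenter <= 0) "ECenter must be > 0" else TRUE
})

#' DoseResult: absorbed dose for one target
#'
#' @slot targetId character label (e.g. "tumor", "stomach_wall").
#' @slot NUsed disintegrations used.
#' @slot D absorbed dose, Gy.
#' @slot DPerGBq dose normalized by injected activity, Gy/GBq (NA until
#'   \code{\link{normalizeDose}} is applied).
#' @slot massKg target mass in kg used for the conversion.
#' @export
setClass("DoseResult",
  representation(targetId = "character", NUsed = "numeric", D = "numeric",
                 DPerGBq = "numeric", massKg = "numeric"),
  prototype(DPerGBq = NA_real_))

setValidity("DoseResult", function(object) {
  msg <- character()
  if (object@D < 0) msg <- c(msg, "D must be >= 0")
  if (object@massKg <= 0) msg <- c(msg, "massKg must be > 0")
  if (length(msg)) msg else TRUE
})

#' Chromatogram: radio-HPLC trace
#'
#' @slot rt retention time grid, minutes, strictly increasing.
#' @slot counts radioactivity detector signal per grid point.
#' @slot metadata list (patient, arm, minutes p.i., ...).
#' @export
setClass("Chromatogram",
  representation(rt = "numeric", counts = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("Chromatogram", function(object) {
  msg <- character()
  if (length(object@rt) != length(object@counts))
    msg <- c(msg, "rt and counts must have equal length")
  if (is.unsorted(object@rt, strictly = TRUE))
    msg <- c(msg, "rt grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' PhantomRegion: one kinetic region of the digital phantom
#'
#' An ellipsoidal region with mono-exponential effective washout:
#' A(t) = Aref * 2^(-(t - tRef)/Te). With \code{uptake = "linear_rise"},
#' activity rises linearly from 0 to A(t1) over [0, t1] (t1 = first
#' acquisition); the default "instantaneous" applies the exponential from
#' t = 0, which keeps the closed-form ground truth exact.
#'
#' @slot label region label ("tumor", "stomach_wall", "kidney",
#'   "background", or free text).
#' @slot center ellipsoid center, mm (world coordinates).
#' @slot semiAxes ellipsoid semi-axes, mm.
#' @slot Aref activity in Bq at the reference time.
#' @slot TeRef effective half-life in hours (> 0; may be Inf).
#' @slot tRef reference time in hours for Aref (default 0).
#' @slot uptake "instantaneous" or "linear_rise".
#' @export
setClass("PhantomRegion",
  representation(label = "character", center = "numeric",
                 semiAxes = "numeric", Aref = "numeric", TeRef = "numeric",
                 tRef = "numeric", uptake = "character"),
  prototype(tRef = 0, uptake = "instantaneous"))

setValidity("PhantomRegion", function(object) {
  msg <- character()
  if (object@Aref < 0) msg <- c(msg, "Aref must be >= 0")
  if (object@TeRef <= 0) msg <- c(msg, "TeRef must be > 0")
  if (length(object@center) != 3 || length(object@semiAxes) != 3)
    msg <- c(msg, "center and semiAxes must have length 3")
  if (any(object@semiAxes <= 0)) msg <- c(msg, "semiAxes must be > 0")
  if (!object@uptake %in% c("instantaneous", "linear_rise"))
    msg <- c(msg, "uptake must be 'instantaneous' or 'linear_rise'")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: full specification of a synthetic SPECT study
#'
#' @slot gridShape integer vector, voxels per axis.
#' @slot voxelSize isotropic voxel size, mm.
#' @slot regions list of \linkS4class{PhantomRegion}; must not overlap
#'   after rasterization.
#' @slot acquisitionTimes hours p.i., strictly increasing.
#' @slot psfFwhm Gaussian PSF full width at half maximum, mm (0 = none).
#' @slot noiseModel "none" or "poisson".
#' @slot countsPerBq Poisson scale: expected counts per Bq of voxel
#'   activity (absorbs acquisition duration and sensitivity).
#' @slot seed integer seed driving all stochastic steps.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 regions = "list", acquisitionTimes = "numeric",
                 psfFwhm = "numeric", noiseModel = "character",
                 countsPerBq = "numeric", seed = "integer"),
  prototype(acquisitionTimes = c(1, 4, 24, 72), psfFwhm = 0,
            noiseModel = "none", countsPerBq = 20, seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (is.unsorted(object@acquisitionTimes, strictly = TRUE))
    msg <- c(msg, "acquisitionTimes must be strictly increasing")
  if (!object@noiseModel %in% c("none", "poisson"))
    msg <- c(msg, "noiseModel must be 'none' or 'poisson'")
  if (object@noiseModel == "poisson" && object@countsPerBq <= 0)
    msg <- c(msg, "countsPerBq must be > 0 for poisson noise")
  if (!all(vapply(object@regions, is, TRUE, class2 = "PhantomRegion")))
    msg <- c(msg, "regions must be a list of PhantomRegion")
  if (length(msg)) msg else TRUE
})
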