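## Nuclear data: packaged Lu-177 decay table, physical constants derived
## from it, and the auxiliary range/attenuation tables used by the
## Monte-Carlo kernel.

#' Packaged Lu-177 decay data
#'
#' Loads the versioned Lu-177 decay-data file shipped with the package
#' (half-life 6.647 d; beta branches as mean-energy lines; conversion and
#' Auger electrons; principal gammas at ~113 and ~208 keV plus Hf
#' fluorescence X-rays). Values are rounded from published open
#' nuclear-data compilations; the provenance note is kept in the
#' \code{source} slot.
#'
#' @param file optional path to an alternative decay-data JSON with the
#'   same schema (\code{half_life_s}, \code{electrons}, \code{photons}).
#' @return A \linkS4class{DecayData} object.
#' @examples
#' d <- lu177DecayData()
#' physicalDecayConstant(d)     # ~1.21e-6 1/s
#' meanElectronEnergy(d)        # ~146 keV per decay
#' @export
lu177DecayData <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "lu177_decay.json", package = "LuDosim",
                        mustWork = TRUE)
  raw <- jsonlite::fromJSON(file)
  new("DecayData",
      nuclide = raw$nuclide,
      halfLifeS = raw$half_life_s,
      electrons = raw$electrons[, c("E_keV", "yield")],
      photons = raw$photons[, c("E_keV", "yield")],
      source = paste(raw[["_comment"]], collapse = " "))
}

#' Physical decay constant
#'
#' lambda_phys = ln(2) / T_1/2(physical), in 1/s.
#'
#' @param object a \linkS4class{DecayData}.
#' @return Decay constant in 1/s.
#' @examples
#' physicalDecayConstant(lu177DecayData())
#' @export
setMethod("physicalDecayConstant", "DecayData", function(object) {
  if (is.na(object@halfLifeS) || object@halfLifeS <= 0)
    stop("physical half-life must be > 0")
  log(2) / object@halfLifeS
})

#' Mean electron energy per decay
#'
#' Yield-weighted sum of the electron emission table (betas as mean-energy
#' lines plus conversion/Auger electrons), in keV per decay. For Lu-177
#' this lands near 146 keV, the energy that dominates the center-voxel
#' dose kernel because beta ranges are small against SPECT voxel sizes.
#'
#' @param object a \linkS4class{DecayData}.
#' @return keV per decay.
#' @export
setMethod("meanElectronEnergy", "DecayData", function(object) {
  tab <- object@electrons
  if (!nrow(tab)) stop("electron emission table is empty")
  sum(tab$E_keV * tab$yield)
})

#' Mean photon energy per decay
#'
#' Yield-weighted sum of the photon emission table, keV per decay.
#'
#' @param object a \linkS4class{DecayData}.
#' @return keV per decay.
#' @export
setMethod("meanPhotonEnergy", "DecayData", function(object) {
  tab <- object@photons
  if (!nrow(tab)) stop("photon emission table is empty")
  sum(tab$E_keV * tab$yield)
})

setMethod("show", "DecayData", function(object) {
  cat(sprintf("DecayData: %s (T1/2 = %.4f d, source v. packaged)\n",
              object@nuclide, object@halfLifeS / 86400))
  cat(sprintf("  %d electron lines (%.1f keV/decay), %d photon lines (%.1f keV/decay)\n",
              nrow(object@electrons), meanElectronEnergy(object),
              nrow(object@photons), meanPhotonEnergy(object)))
})

## --- auxiliary transport tables ------------------------------------------

csdaRangeTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "electron_csda_range_water.csv",
                       package = "LuDosim", mustWork = TRUE)
      cache <<- utils::read.csv(f, comment.char = "#")
    }
    cache
  }
})

photonAttenuationTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "photon_attenuation_water.csv",
                       package = "LuDosim", mustWork = TRUE)
      cache <<- utils::read.csv(f, comment.char = "#")
    }
    cache
  }
})

#' Electron CSDA range in unit-density soft tissue
#'
#' Continuous-slowing-down-approximation range, interpolated log-log from
#' the packaged water range table (density 1 g/cm3, so g/cm2 equals cm).
#'
#' @param E_keV electron energies in keV.
#' @return Range in mm.
#' @export
csdaRangeMm <- function(E_keV) {
  tab <- csdaRangeTable()
  10 * logLogInterp(tab$E_keV, tab$range_g_cm2, E_keV)
}

#' Photon interaction coefficients in unit-density soft tissue
#'
#' Linear attenuation and energy-absorption coefficients (1/mm),
#' interpolated log-log from the packaged water table.
#'
#' @param E_keV photon energies in keV.
#' @return data.frame with columns \code{mu} and \code{muEn}, both 1/mm.
#' @export
photonMuMm <- function(E_keV) {
  tab <- photonAttenuationTable()
  data.frame(mu = logLogInterp(tab$E_keV, tab$mu_rho, E_keV) / 10,
             muEn = logLogInterp(tab$E_keV, tab$mu_en_rho, E_keV) / 10)
}
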