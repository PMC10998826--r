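## Generics. Most pipeline operations are ordinary functions; generics are
## defined where dispatch on the data object is the natural interface.

#' @rdname physicalDecayConstant
#' @export
setGeneric("physicalDecayConstant",
           function(object) standardGeneric("physicalDecayConstant"))

#' @rdname meanElectronEnergy
#' @export
setGeneric("meanElectronEnergy",
           function(object) standardGeneric("meanElectronEnergy"))

#' @rdname meanPhotonEnergy
#' @export
setGeneric("meanPhotonEnergy",
           function(object) standardGeneric("meanPhotonEnergy"))

#' @rdname voiVolume
#' @export
setGeneric("voiVolume", function(object) standardGeneric("voiVolume"))

#' @rdname voiActivity
#' @export
setGeneric("voiActivity",
           function(object, voi) standardGeneric("voiActivity"))

#' @rdname voiMeanConcentration
#' @export
setGeneric("voiMeanConcentration",
           function(object, voi) standardGeneric("voiMeanConcentration"))

#' @rdname backgroundCorrectedActivity
#' @export
setGeneric("backgroundCorrectedActivity",
           function(object, ...) standardGeneric("backgroundCorrectedActivity"))

#' Effective half-life accessor
#'
#' @param object a \linkS4class{KineticFit}.
#' @return Effective half-life in hours (NA when the fit is unusable).
#' @export
setGeneric("effectiveHalfLife",
           function(object) standardGeneric("effectiveHalfLife"))
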