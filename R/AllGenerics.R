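# Generics for the accessor functions.  Slot access from user code goes
# through these, never through @.

#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @export
setGeneric("binTime", function(object) standardGeneric("binTime"))

#' @export
setGeneric("traceDuration", function(object) standardGeneric("traceDuration"))

#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))

#' @export
setGeneric("lagTimes", function(object) standardGeneric("lagTimes"))

#' @export
setGeneric("corrValues", function(object) standardGeneric("corrValues"))

#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @export
setGeneric("meanRate", function(object) standardGeneric("meanRate"))

#' @export
setGeneric("beamWaist", function(object) standardGeneric("beamWaist"))

#' @export
setGeneric("structureParameter",
           function(object) standardGeneric("structureParameter"))

#' @export
setGeneric("beamArea", function(object) standardGeneric("beamArea"))

#' @export
setGeneric("nTotal", function(object) standardGeneric("nTotal"))

#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @export
setGeneric("chiSquared", function(object) standardGeneric("chiSquared"))

#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @export
setGeneric("dwellTime", function(object) standardGeneric("dwellTime"))

#' @export
setGeneric("correctionF", function(object) standardGeneric("correctionF"))

#' @export
setGeneric("brightnessValues",
           function(object) standardGeneric("brightnessValues"))

#' @export
setGeneric("emax", function(object) standardGeneric("emax"))

#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @export
setGeneric("pec50", function(object) standardGeneric("pec50"))

#' @export
setGeneric("noResponse", function(object) standardGeneric("noResponse"))
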