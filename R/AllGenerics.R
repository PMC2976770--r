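#' @include AllClasses.R
NULL

#' @export
setGeneric("checkMendelian", function(x, marker) standardGeneric("checkMendelian"))

#' @export
setGeneric("classifyTetrad",
           function(x, interval, inferDead = TRUE) standardGeneric("classifyTetrad"))

#' @export
setGeneric("inferDeadSpore", function(x) standardGeneric("inferDeadSpore"))

#' @export
setGeneric("detectMINondisjunction",
           function(x) standardGeneric("detectMINondisjunction"))

#' @export
setGeneric("classifySisterhood", function(x) standardGeneric("classifySisterhood"))

#' @export
setGeneric("perkinsMapDistance",
           function(x, se = TRUE) standardGeneric("perkinsMapDistance"))

#' @export
setGeneric("mapDistanceSE", function(x) standardGeneric("mapDistanceSE"))

#' @export
setGeneric("segregationPattern", function(x) standardGeneric("segregationPattern"))

#' @export
setGeneric("callEvent",
           function(x, config = reporterConfig()) standardGeneric("callEvent"))

#' @export
setGeneric("simulateTetrads",
           function(params, map = yeastChrIIIMap()) standardGeneric("simulateTetrads"))

## accessors ---------------------------------------------------------------

#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @export
setGeneric("centromereMarker", function(x) standardGeneric("centromereMarker"))

#' @export
setGeneric("sporeData", function(x) standardGeneric("sporeData"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("simProvenance", function(x) standardGeneric("simProvenance"))

#' @export
setGeneric("viability", function(x) standardGeneric("viability"))

#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
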