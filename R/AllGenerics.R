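#' @include AllClasses.R
NULL

#' @rdname divisionTimes
#' @export
setGeneric("divisionTimes", function(x, ...) standardGeneric("divisionTimes"))

#' @rdname groundTruth
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname alignToMitosis
#' @export
setGeneric("alignToMitosis", function(x, event = 1L, ...)
  standardGeneric("alignToMitosis"))

#' @rdname classifyFate
#' @export
setGeneric("classifyFate", function(x, config = classifierConfig(), ...)
  standardGeneric("classifyFate"))

#' @rdname calibration
#' @export
setGeneric("dynamicRange", function(p) standardGeneric("dynamicRange"))

#' @rdname calibration
#' @export
setGeneric("fractionalSaturation", function(p)
  standardGeneric("fractionalSaturation"))

#' @rdname calibration
#' @export
setGeneric("znConcentration", function(p) standardGeneric("znConcentration"))

#' @rdname LabelMask-accessors
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname LabelMask-accessors
#' @export
setGeneric("maskFeatures", function(x, ...) standardGeneric("maskFeatures"))

#' @rdname LabelMask-accessors
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))
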