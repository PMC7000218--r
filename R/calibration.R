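#' @include AllClasses.R AllGenerics.R
NULL

#' Construct FRET sensor calibration parameters
#'
#' @param rRest resting FRET ratio of the cell population.
#' @param rMin ratio under exhaustive chelation (sensor fully unbound).
#' @param rMax ratio under saturating Zn2+ (sensor fully bound).
#' @param kd apparent dissociation constant, pM.
#' @param hillN Hill coefficient.
#' @return a validated [CalibrationParams-class].
#' @examples
#' p <- calibrationParams(rRest = 2, rMin = 1, rMax = 3)
#' znConcentration(p)   # 5300 pM: midpoint ratio makes the Hill argument 1
#' @export
calibrationParams <- function(rRest, rMin, rMax, kd = 5300, hillN = 0.29) {
  new("CalibrationParams", rRest = rRest, rMin = rMin, rMax = rMax,
      kd = kd, hillN = hillN)
}

#' Zinc sensor calibration quantities
#'
#' `dynamicRange()` returns \eqn{DR = R_{max}/R_{min}};
#' `fractionalSaturation()` returns
#' \eqn{FS = (R_{rest}-R_{min})/(R_{max}-R_{min})}, the occupied fraction of
#' the sensor; `znConcentration()` inverts the Hill binding model,
#' \deqn{[Zn^{2+}] = K_D \left(\frac{R_{rest}-R_{min}}{R_{max}-R_{rest}}\right)^{1/n},}
#' in pM. The inverse is strictly increasing in \eqn{R_{rest}} on
#' \eqn{(R_{min}, R_{max})}; \eqn{R_{rest} = R_{max}} is an
#' infinite-concentration error and \eqn{R_{rest} = R_{min}} maps to 0 pM.
#'
#' @param p a [CalibrationParams-class].
#' @name calibration
NULL

#' @rdname calibration
#' @export
setMethod("dynamicRange", "CalibrationParams", function(p) {
  validObject(p)
  p@rMax / p@rMin
})

#' @rdname calibration
#' @export
setMethod("fractionalSaturation", "CalibrationParams", function(p) {
  validObject(p)
  (p@rRest - p@rMin) / (p@rMax - p@rMin)
})

#' @rdname calibration
#' @export
setMethod("znConcentration", "CalibrationParams", function(p) {
  validObject(p)
  if (p@rRest >= p@rMax)
    stop("rRest = rMax: concentration diverges (sensor saturated)")
  if (p@rRest < p@rMin)
    stop("rRest below rMin: negative Hill argument")
  p@kd * ((p@rRest - p@rMin) / (p@rMax - p@rRest))^(1 / p@hillN)
})

#' Forward Hill response of the sensor
#'
#' The FRET ratio a sensor with parameters `p` reports at free zinc
#' concentration `zn` (pM):
#' \eqn{R = (R_{min} + R_{max}\,x)/(1 + x)} with
#' \eqn{x = (zn/K_D)^n}. Exact inverse of [znConcentration()].
#'
#' @param p a [CalibrationParams-class] (its `rRest` is ignored).
#' @param zn zinc concentration(s), pM.
#' @return FRET ratio(s).
#' @export
hillResponse <- function(p, zn) {
  stopifnot(is(p, "CalibrationParams"), all(zn >= 0))
  x <- (zn / p@kd)^p@hillN
  (p@rMin + p@rMax * x) / (1 + x)
}
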