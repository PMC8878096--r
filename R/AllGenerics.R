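#' @rdname timeToPercentile
#' @export
setGeneric("timeToPercentile", function(curve, g, ...)
  standardGeneric("timeToPercentile"))

#' @rdname germinationRate
#' @export
setGeneric("germinationRate", function(curve, g, ...)
  standardGeneric("germinationRate"))

#' Accessors for fitted threshold-model objects
#'
#' \code{psiB50} returns the median base water potential (MPa);
#' \code{sigmaPsiB} the standard deviation of the threshold distribution
#' (MPa); \code{theta} the fitted time constant; \code{thetaHalo} and
#' \code{thetaHaloTT} the halotime (MPa h) and halothermal (MPa degC h)
#' constants; \code{kT} the supra-optimal threshold shift (MPa per degC);
#' \code{r2} the coefficient of determination of the probit regression;
#' \code{cardinalTemperatures} the named vector c(Tb, To, Tc) in degC.
#'
#' @param object a \linkS4class{ProbitFit} or \linkS4class{HaloTTParams}
#' @return a numeric scalar (or named length-3 vector for
#'   \code{cardinalTemperatures})
#' @name threshold-accessors
NULL

#' @rdname threshold-accessors
#' @export
setGeneric("psiB50", function(object) standardGeneric("psiB50"))

#' @rdname threshold-accessors
#' @export
setGeneric("sigmaPsiB", function(object) standardGeneric("sigmaPsiB"))

#' @rdname threshold-accessors
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))

#' @rdname threshold-accessors
#' @export
setGeneric("thetaHalo", function(object) standardGeneric("thetaHalo"))

#' @rdname threshold-accessors
#' @export
setGeneric("thetaHaloTT", function(object) standardGeneric("thetaHaloTT"))

#' @rdname threshold-accessors
#' @export
setGeneric("kT", function(object) standardGeneric("kT"))

#' @rdname threshold-accessors
#' @export
setGeneric("r2", function(object) standardGeneric("r2"))

#' @rdname threshold-accessors
#' @export
setGeneric("cardinalTemperatures", function(object)
  standardGeneric("cardinalTemperatures"))
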