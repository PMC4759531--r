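#' @include AllClasses.R
NULL

#' Accessors for ForceCurve objects
#'
#' @param object a [ForceCurve-class].
#' @return \code{piezoZ} and \code{deflection} return the numeric sample
#'   vectors (nm); \code{springConstant} the spring constant (N/m);
#'   \code{halfAngle} the tip half-opening angle (degrees);
#'   \code{poissonRatio} the Poisson ratio; \code{glassPosition} the
#'   bare-glass contact position (nm, \code{NA} if absent);
#'   \code{curveLabel} the identifier.
#' @name ForceCurve-accessors
#' @aliases piezoZ deflection springConstant halfAngle poissonRatio
#'   glassPosition curveLabel
NULL

#' @rdname ForceCurve-accessors
#' @export
setGeneric("piezoZ", function(object) standardGeneric("piezoZ"))
#' @rdname ForceCurve-accessors
#' @export
setGeneric("deflection", function(object) standardGeneric("deflection"))
#' @rdname ForceCurve-accessors
#' @export
setGeneric("springConstant", function(object) standardGeneric("springConstant"))
#' @rdname ForceCurve-accessors
#' @export
setGeneric("halfAngle", function(object) standardGeneric("halfAngle"))
#' @rdname ForceCurve-accessors
#' @export
setGeneric("poissonRatio", function(object) standardGeneric("poissonRatio"))
#' @rdname ForceCurve-accessors
#' @export
setGeneric("glassPosition", function(object) standardGeneric("glassPosition"))
#' @rdname ForceCurve-accessors
#' @export
setGeneric("curveLabel", function(object) standardGeneric("curveLabel"))

#' Accessors for CPResult objects
#'
#' @param object a [CPResult-class].
#' @return \code{cpIndex} returns the chosen contact index,
#'   \code{combinedTrace} the product trace over candidates,
#'   \code{traceMatrix} the per-component normalised traces as a matrix
#'   (one column per component), \code{nPeaks} the number of local maxima
#'   of the combined trace, and \code{isLowConfidence} the low-confidence
#'   flag.
#' @name CPResult-accessors
#' @aliases cpIndex combinedTrace traceMatrix nPeaks isLowConfidence
NULL

#' @rdname CPResult-accessors
#' @export
setGeneric("cpIndex", function(object) standardGeneric("cpIndex"))
#' @rdname CPResult-accessors
#' @export
setGeneric("combinedTrace", function(object) standardGeneric("combinedTrace"))
#' @rdname CPResult-accessors
#' @export
setGeneric("traceMatrix", function(object) standardGeneric("traceMatrix"))
#' @rdname CPResult-accessors
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))
#' @rdname CPResult-accessors
#' @export
setGeneric("isLowConfidence", function(object) standardGeneric("isLowConfidence"))

#' Accessors for EFit objects
#'
#' @param object an [EFit-class].
#' @return \code{youngsModulus} returns the fitted modulus (kPa),
#'   \code{rSquared} the coefficient of determination,
#'   \code{powerLawExponent} the exponent of a power-law fit,
#'   \code{modelName} the model identifier, and \code{isConverged} the
#'   convergence flag.
#' @name EFit-accessors
#' @aliases youngsModulus rSquared powerLawExponent modelName isConverged
NULL

#' @rdname EFit-accessors
#' @export
setGeneric("youngsModulus", function(object) standardGeneric("youngsModulus"))
#' @rdname EFit-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname EFit-accessors
#' @export
setGeneric("powerLawExponent", function(object) standardGeneric("powerLawExponent"))
#' @rdname EFit-accessors
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))
#' @rdname EFit-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
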