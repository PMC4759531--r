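#' @import methods
NULL

#' Force-displacement curve
#'
#' Container for one AFM force-displacement record: piezo displacement
#' \code{Z} and cantilever deflection \code{d} (both nm), with the
#' acquisition metadata needed for contact-mechanics analysis.
#'
#' Internally the approach direction is normalised so that \code{Z}
#' increases towards the sample; curves recorded with a decreasing-Z
#' approach are flipped (sign-inverted) on construction, and all reported
#' indices refer to the normalised frame.
#'
#' @slot Z numeric, piezo displacement samples (nm).
#' @slot d numeric, cantilever deflection samples (nm), same length as Z.
#' @slot k numeric(1), cantilever spring constant (N/m, equal to nN/nm).
#' @slot theta numeric(1), tip half-opening angle (degrees).
#' @slot nu numeric(1), Poisson ratio of the sample.
#' @slot Zglass numeric(1), piezo position of contact on bare glass (nm);
#'   \code{NA} when no glass reference was recorded.
#' @slot label character(1), free-text curve identifier.
#' @slot flipped logical(1), whether Z was sign-inverted on construction.
#'
#' @seealso [forceCurve()], [readForceCurve()], [splitApproachWithdraw()]
#' @export
setClass("ForceCurve",
  representation(
    Z = "numeric", d = "numeric",
    k = "numeric", theta = "numeric", nu = "numeric",
    Zglass = "numeric", label = "character", flipped = "logical"
  ),
  prototype(
    Zglass = NA_real_, label = "", flipped = FALSE
  )
)

setValidity("ForceCurve", function(object) {
  msg <- character()
  if (length(object@Z) != length(object@d))
    msg <- c(msg, "Z and d must have the same length")
  if (length(object@Z) < 16L)
    msg <- c(msg, "curve must have at least 16 samples")
  if (!all(is.finite(object@Z)) || !all(is.finite(object@d)))
    msg <- c(msg, "Z and d must be finite")
  if (length(object@k) != 1L || !is.finite(object@k) || object@k <= 0)
    msg <- c(msg, "spring constant k must be a single positive number")
  if (length(object@theta) != 1L || !is.finite(object@theta) ||
      object@theta <= 0 || object@theta >= 90)
    msg <- c(msg, "half-opening angle theta must be in (0, 90) degrees")
  if (length(object@nu) != 1L || !is.finite(object@nu) ||
      object@nu < 0 || object@nu > 0.5)
    msg <- c(msg, "Poisson ratio nu must be in [0, 0.5]")
  if (length(msg) == 0L) {
    apex <- which.max(object@Z)
    if (apex > 1L && any(diff(object@Z[seq_len(apex)]) <= 0))
      msg <- c(msg, "approach segment must be strictly monotone in Z")
  }
  if (length(msg)) msg else TRUE
})

#' Curve segment
#'
#' A contiguous index range of a [ForceCurve-class], tagged with its ramp
#' direction. Index 1 of the approach is the sample furthest from the
#' surface.
#'
#' @slot indices integer, contiguous indices into the parent curve.
#' @slot direction character(1), \code{"approach"} or \code{"withdraw"}.
#' @export
setClass("CurveSegment",
  representation(indices = "integer", direction = "character")
)

setValidity("CurveSegment", function(object) {
  msg <- character()
  if (!object@direction %in% c("approach", "withdraw"))
    msg <- c(msg, "direction must be 'approach' or 'withdraw'")
  if (length(object@indices) &&
      !identical(object@indices, seq(object@indices[1L],
                                     length.out = length(object@indices))))
    msg <- c(msg, "indices must be contiguous and increasing")
  if (length(msg)) msg else TRUE
})

#' Contact-point search strategy specification
#'
#' Describes which sequential-search test parameters to evaluate and with
#' what window settings. Components are combined multiplicatively after
#' min-max normalisation of each trace.
#'
#' @slot components character, subset of \code{"gof_whole"},
#'   \code{"gof_low"}, \code{"rov"}, \code{"delta_e"}, \code{"ple"}.
#' @slot rovWindow numeric(1), width (nm) of each variance window for the
#'   ratio-of-variances test.
#' @slot pleVicinity numeric(1), length (nm) of travel ahead of the trial
#'   point fitted by the power-law-exponent test.
#' @slot gofLowFraction numeric(1), fraction of contact points fitted by
#'   the low-indentation goodness-of-fit test.
#' @slot gofModel character(1), contact model used by fit-based tests:
#'   \code{"becc"} or \code{"sneddon"}.
#' @slot searchRange either \code{"auto"} (restrict candidates to a
#'   pre-search vicinity of a coarse deflection-threshold contact
#'   estimate), \code{"full"} (every structurally valid candidate), or an
#'   integer \code{c(lo, hi)} window of approach indices.
#' @slot step integer(1), candidate stride in samples.
#' @seealso [strategySpec()], [findContactPoint()]
#' @export
setClass("StrategySpec",
  representation(
    components = "character",
    rovWindow = "numeric",
    pleVicinity = "numeric",
    gofLowFraction = "numeric",
    gofModel = "character",
    searchRange = "ANY",
    step = "integer"
  ),
  prototype(
    components = c("gof_low", "rov", "delta_e"),
    rovWindow = 50, pleVicinity = 250, gofLowFraction = 1 / 3,
    gofModel = "becc", searchRange = "auto", step = 1L
  )
)

setValidity("StrategySpec", function(object) {
  msg <- character()
  known <- c("gof_whole", "gof_low", "rov", "delta_e", "ple")
  if (length(object@components) == 0L)
    msg <- c(msg, "at least one component is required")
  if (!all(object@components %in% known))
    msg <- c(msg, paste0("unknown component(s): ",
                         paste(setdiff(object@components, known), collapse = ", ")))
  if (anyDuplicated(object@components))
    msg <- c(msg, "components must be unique")
  if (object@rovWindow <= 0) msg <- c(msg, "rovWindow must be positive")
  if (object@pleVicinity <= 0) msg <- c(msg, "pleVicinity must be positive")
  if (object@gofLowFraction <= 0 || object@gofLowFraction > 1)
    msg <- c(msg, "gofLowFraction must be in (0, 1]")
  if (!object@gofModel %in% c("becc", "sneddon"))
    msg <- c(msg, "gofModel must be 'becc' or 'sneddon'")
  if (is.character(object@searchRange)) {
    if (!object@searchRange %in% c("auto", "full"))
      msg <- c(msg, "searchRange must be 'auto', 'full' or c(lo, hi)")
  } else if (!(is.numeric(object@searchRange) && length(object@searchRange) == 2L))
    msg <- c(msg, "searchRange must be 'auto', 'full' or c(lo, hi)")
  if (object@step < 1L) msg <- c(msg, "step must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Contact-point detection result
#'
#' The chosen contact point together with the full per-component
#' test-parameter traces over the candidate grid, for diagnostics and
#' plotting.
#'
#' @slot cpIndex integer(1), chosen contact index (approach frame).
#' @slot Zcp,dcp numeric(1), piezo position and deflection at the CP.
#' @slot candidates integer, candidate indices that were evaluated.
#' @slot traces list of numeric, per-component normalised traces on the
#'   candidate grid (\code{NA} marks invalid entries).
#' @slot rawTraces list of numeric, the un-normalised test parameters.
#' @slot combined numeric, product trace actually maximised.
#' @slot nPeaks integer(1), number of local maxima of the combined trace.
#' @slot lowConfidence logical(1), set when no component showed a
#'   convincing contact signature (see [findContactPoint()]).
#' @slot notes character, machine-readable warnings collected during the
#'   search.
#' @export
setClass("CPResult",
  representation(
    cpIndex = "integer", Zcp = "numeric", dcp = "numeric",
    candidates = "integer", traces = "list", rawTraces = "list",
    combined = "numeric", nPeaks = "integer",
    lowConfidence = "logical", notes = "character"
  )
)

setValidity("CPResult", function(object) {
  msg <- character()
  if (length(object@cpIndex) != 1L || is.na(object@cpIndex))
    msg <- c(msg, "cpIndex must be a single index")
  if (length(object@combined) != length(object@candidates))
    msg <- c(msg, "combined trace must align with candidates")
  for (nm in names(object@traces))
    if (length(object@traces[[nm]]) != length(object@candidates))
      msg <- c(msg, paste0("trace '", nm, "' must align with candidates"))
  if (!object@cpIndex %in% object@candidates)
    msg <- c(msg, "cpIndex must be one of the evaluated candidates")
  if (length(msg)) msg else TRUE
})

#' Young's modulus fit
#'
#' Result of a least-squares fit of a contact-mechanics model to
#' indentation-force data.
#'
#' @slot E numeric(1), Young's modulus (kPa); \code{NA} for power-law fits.
#' @slot model character(1), \code{"sneddon"}, \code{"becc"} or
#'   \code{"power_law"}.
#' @slot x numeric(1), power-law exponent (power-law fits only).
#' @slot A numeric(1), power-law prefactor (nN/nm^x, power-law fits only).
#' @slot r2 numeric(1), coefficient of determination on the fitted points.
#' @slot residualNorm numeric(1), root of the residual sum of squares (nN).
#' @slot fitRange integer, index interval of the input vectors that was
#'   requested for fitting.
#' @slot nPoints integer(1), number of points actually used.
#' @slot h numeric(1), sample thickness used (nm; BECC fits only).
#' @slot converged logical(1).
#' @export
setClass("EFit",
  representation(
    E = "numeric", model = "character", x = "numeric", A = "numeric",
    r2 = "numeric", residualNorm = "numeric",
    fitRange = "integer", nPoints = "integer",
    h = "numeric", converged = "logical"
  ),
  prototype(x = NA_real_, A = NA_real_, h = NA_real_)
)

setValidity("EFit", function(object) {
  msg <- character()
  if (!object@model %in% c("sneddon", "becc", "power_law"))
    msg <- c(msg, "model must be 'sneddon', 'becc' or 'power_law'")
  if (isTRUE(object@converged) && object@model != "power_law" &&
      (!is.finite(object@E) || object@E <= 0))
    msg <- c(msg, "converged fits must have E > 0")
  if (is.finite(object@r2) && object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 cannot exceed 1")
  if (length(object@fitRange) == 0L)
    msg <- c(msg, "fitRange must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Synthetic sample profile
#'
#' Parameters of the synthetic force-curve generator. Defaults emulate
#' soft-gel measurements: 5-um triangular ramps sampled at 2048 points,
#' 0.03 N/m cantilever, 35-degree conical tip, incompressible sample of
#' 10 kPa with thickness drawn uniformly from 2-8 um, 1 nm iid Gaussian
#' deflection noise, and a contact point in the last quarter of the ramp
#' so that peak forces stay in the few-nN regime of gentle indentation.
#'
#' @slot ETrue numeric(1), true Young's modulus (kPa).
#' @slot hRange numeric(2), thickness interval sampled per curve (nm).
#' @slot noiseSd numeric(1), deflection noise standard deviation (nm).
#' @slot k numeric(1), spring constant (N/m).
#' @slot theta numeric(1), half-opening angle (degrees).
#' @slot nu numeric(1), Poisson ratio.
#' @slot rampSize numeric(1), ramp length (nm).
#' @slot nPoints integer(1), samples per approach segment.
#' @slot cpPositionRange numeric(2), fraction interval of the ramp where
#'   the true contact point falls.
#' @slot maxIndentationFactor numeric(1), generation fails if the solved
#'   indentation exceeds this fraction of the thickness (model validity).
#' @slot withdrawStiffening numeric(1), factor applied to E on the
#'   withdraw segment (1 = purely elastic, no hysteresis).
#' @slot baselineDrift numeric(1), linear deflection drift (nm per nm of
#'   Z travel) added to the whole curve; 0 by default.
#' @seealso [sampleProfile()], [generateCurve()], [generateDataset()]
#' @export
setClass("SampleProfile",
  representation(
    ETrue = "numeric", hRange = "numeric", noiseSd = "numeric",
    k = "numeric", theta = "numeric", nu = "numeric",
    rampSize = "numeric", nPoints = "integer",
    cpPositionRange = "numeric", maxIndentationFactor = "numeric",
    withdrawStiffening = "numeric", baselineDrift = "numeric"
  ),
  prototype(
    ETrue = 10, hRange = c(2000, 8000), noiseSd = 1,
    k = 0.03, theta = 35, nu = 0.5,
    rampSize = 5000, nPoints = 2048L,
    cpPositionRange = c(0.75, 0.9), maxIndentationFactor = 0.8,
    withdrawStiffening = 1, baselineDrift = 0
  )
)

setValidity("SampleProfile", function(object) {
  msg <- character()
  if (object@ETrue <= 0) msg <- c(msg, "ETrue must be positive")
  if (length(object@hRange) != 2L || any(object@hRange <= 0) ||
      object@hRange[1L] > object@hRange[2L])
    msg <- c(msg, "hRange must be positive with low <= high")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@k <= 0) msg <- c(msg, "k must be positive")
  if (object@theta <= 0 || object@theta >= 90)
    msg <- c(msg, "theta must be in (0, 90)")
  if (object@nu < 0 || object@nu > 0.5) msg <- c(msg, "nu must be in [0, 0.5]")
  if (object@rampSize <= 0) msg <- c(msg, "rampSize must be positive")
  if (object@nPoints < 64L) msg <- c(msg, "nPoints must be >= 64")
  if (length(object@cpPositionRange) != 2L ||
      any(object@cpPositionRange <= 0) || any(object@cpPositionRange >= 1) ||
      object@cpPositionRange[1L] > object@cpPositionRange[2L])
    msg <- c(msg, "cpPositionRange must be an increasing interval in (0, 1)")
  if (object@maxIndentationFactor <= 0 || object@maxIndentationFactor >= 1)
    msg <- c(msg, "maxIndentationFactor must be in (0, 1)")
  if (object@withdrawStiffening <= 0)
    msg <- c(msg, "withdrawStiffening must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-curve analysis record
#'
#' Everything the batch pipeline derives from one curve: the detected
#' contact point, the thickness, and the modulus fits (approach; and
#' optionally withdraw and a low/high indentation-depth pair).
#'
#' @slot label character(1), curve identifier.
#' @slot cp the [CPResult-class], or \code{NULL} when detection failed.
#' @slot h numeric(1), sample thickness used (nm; may be \code{NA}).
#' @slot fitApproach the approach-segment [EFit-class], or \code{NULL}.
#' @slot fitWithdraw optional withdraw-segment [EFit-class].
#' @slot fitLow,fitHigh optional depth-resolved [EFit-class] pair
#'   (first and second half of the contact points).
#' @slot failed logical(1), whether the analysis failed.
#' @slot flags character, warnings collected during the analysis.
#' @export
setClass("CurveAnalysis",
  representation(
    label = "character", cp = "ANY", h = "numeric",
    fitApproach = "ANY", fitWithdraw = "ANY",
    fitLow = "ANY", fitHigh = "ANY",
    failed = "logical", flags = "character"
  ),
  prototype(cp = NULL, fitApproach = NULL, fitWithdraw = NULL,
            fitLow = NULL, fitHigh = NULL, failed = FALSE,
            flags = character())
)
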