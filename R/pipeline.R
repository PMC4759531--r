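#' @include synthetic.R
NULL

# delta/force arrays for a segment of samples relative to the CP reference
.deltaForce <- function(curve, j, cpi) {
  delta <- (curve@Z[j] - curve@Z[cpi]) - (curve@d[j] - curve@d[cpi])
  force <- curve@k * (curve@d[j] - curve@d[cpi])
  list(delta = delta, force = force)
}

# fit the spec model on prepared delta/force; NULL on failure
.tryFit <- function(delta, force, model, theta, nu, h, maxIndentation = NULL) {
  if (!is.null(maxIndentation)) {
    keep <- delta <= maxIndentation
    delta <- delta[keep]; force <- force[keep]
  }
  tryCatch(
    fitModulus(delta, force, model = model, theta = theta, nu = nu,
               h = if (model == "becc") h else NULL),
    error = function(e) NULL)
}

#' Analyse one force curve
#'
#' Detects the contact point on the approach segment, derives the local
#' sample thickness from the glass reference (or uses the supplied one),
#' and fits the Young's modulus over the contact region. In \code{"gel"}
#' mode the whole contact part is fitted; in \code{"cell"} mode only
#' indentations up to \code{maxIndentation} are used, to stay within the
#' linear-elastic regime of living cells. Optionally also fits the
#' withdraw segment (reusing the approach contact point, since detection
#' is defined on the approach direction only) and a depth-resolved pair
#' of fits on the first and second half of the contact points.
#'
#' @param curve a [ForceCurve-class].
#' @param spec a [StrategySpec-class].
#' @param h optional thickness (nm); default derived from
#'   \code{sampleHeight(Zcp, Zglass)}.
#' @param mode \code{"gel"} (fit everything) or \code{"cell"} (cap the
#'   fitted indentation).
#' @param maxIndentation indentation cap (nm) for \code{"cell"} mode.
#' @param withdraw also fit the withdraw segment.
#' @param depthSplit also fit the low/high indentation halves.
#' @return a [CurveAnalysis-class]; detection failure yields
#'   \code{failed = TRUE} rather than an error, so batches continue.
#' @export
analyzeCurve <- function(curve, spec = strategySpec(), h = NULL,
                         mode = c("gel", "cell"), maxIndentation = 600,
                         withdraw = FALSE, depthSplit = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(curve, "ForceCurve"))
  flags <- character()
  cp <- tryCatch(findContactPoint(curve, spec, h = h),
                 error = function(e) {
                   flags <<- c(flags, paste0("detection: ",
                                             conditionMessage(e)))
                   NULL
                 })
  if (is.null(cp))
    return(new("CurveAnalysis", label = curveLabel(curve), cp = NULL,
               h = NA_real_, failed = TRUE, flags = flags))
  if (isLowConfidence(cp)) flags <- c(flags, "low_confidence_cp")
  cpi <- cpIndex(cp)
  hUsed <- if (!is.null(h)) h
  else if (!is.na(curve@Zglass)) sampleHeight(cp@Zcp, curve@Zglass)
  else NA_real_
  model <- spec@gofModel
  if (model == "becc" && (!is.finite(hUsed) || hUsed <= 0)) {
    flags <- c(flags, "no_thickness_fell_back_to_sneddon")
    model <- "sneddon"
  }
  apex <- .apexIndex(curve)
  df <- .deltaForce(curve, cpi:apex, cpi)
  cap <- if (mode == "cell") maxIndentation else NULL
  fitA <- .tryFit(df$delta, df$force, model, curve@theta, curve@nu, hUsed, cap)
  if (is.null(fitA)) flags <- c(flags, "approach_fit_failed")

  fitW <- NULL
  if (withdraw) {
    n <- length(curve@Z)
    if (apex < n) {
      wd <- .deltaForce(curve, (apex + 1L):n, cpi)
      fitW <- .tryFit(wd$delta, wd$force, model, curve@theta, curve@nu,
                      hUsed, cap)
      if (is.null(fitW)) flags <- c(flags, "withdraw_fit_failed")
    } else flags <- c(flags, "no_withdraw_segment")
  }

  fitL <- fitH <- NULL
  if (depthSplit) {
    contact <- which(df$delta >= 0)
    N <- length(contact)
    half <- N %/% 2L
    if (half >= 5L) {
      fitL <- .tryFit(df$delta[contact[seq_len(half)]],
                      df$force[contact[seq_len(half)]],
                      model, curve@theta, curve@nu, hUsed, NULL)
      fitH <- .tryFit(df$delta[contact[(half + 1L):N]],
                      df$force[contact[(half + 1L):N]],
                      model, curve@theta, curve@nu, hUsed, NULL)
    } else flags <- c(flags, "too_few_points_for_depth_split")
  }

  new("CurveAnalysis", label = curveLabel(curve), cp = cp, h = hUsed,
      fitApproach = fitA, fitWithdraw = fitW, fitLow = fitL, fitHigh = fitH,
      failed = is.null(fitA), flags = flags)
}

setMethod("show", "CurveAnalysis", function(object) {
  cat("CurveAnalysis", sQuote(object@label),
      if (object@failed) "[FAILED]" else "", "\n")
  if (!is.null(object@cp))
    cat(sprintf("  CP index %d, h = %.4g nm\n", cpIndex(object@cp), object@h))
  if (!is.null(object@fitApproach)) {
    cat("  approach: "); show(object@fitApproach)
  }
  if (!is.null(object@fitWithdraw)) {
    cat("  withdraw: "); show(object@fitWithdraw)
  }
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})

# one result row per analysis
.analysisRow <- function(an) {
  fa <- an@fitApproach
  data.frame(
    label = an@label,
    failed = an@failed,
    cpIndex = if (!is.null(an@cp)) cpIndex(an@cp) else NA_integer_,
    Zcp = if (!is.null(an@cp)) an@cp@Zcp else NA_real_,
    h = an@h,
    E = if (!is.null(fa)) fa@E else NA_real_,
    r2 = if (!is.null(fa)) fa@r2 else NA_real_,
    EWithdraw = if (!is.null(an@fitWithdraw)) an@fitWithdraw@E else NA_real_,
    ELow = if (!is.null(an@fitLow)) an@fitLow@E else NA_real_,
    EHigh = if (!is.null(an@fitHigh)) an@fitHigh@E else NA_real_,
    nPeaks = if (!is.null(an@cp)) nPeaks(an@cp) else NA_integer_,
    lowConfidence = if (!is.null(an@cp)) isLowConfidence(an@cp) else NA,
    flags = paste(an@flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Analyse a batch of force curves
#'
#' Applies [analyzeCurve()] to every curve of a list or directory, in
#' deterministic (name) order. Unreadable or failing curves are reported
#' in the result table and do not interrupt the batch.
#'
#' @param curves a named list of [ForceCurve-class] objects, or a
#'   directory path for [readBatch()].
#' @param spec a [StrategySpec-class].
#' @param srRange optional acceptance range (kPa): when given, a summary
#'   row of assessment metrics (see [assessStrategy()]) is attached.
#' @param verbose print one status line per curve.
#' @param ... forwarded to [analyzeCurve()].
#' @return \code{data.frame} with one row per curve; attributes
#'   \code{"analyses"} (the [CurveAnalysis-class] list) and, when
#'   \code{srRange} is given, \code{"summary"}.
#' @export
analyzeBatch <- function(curves, spec = strategySpec(), srRange = NULL,
                         verbose = FALSE, ...) {
  if (is.character(curves)) curves <- readBatch(curves)
  stopifnot(is.list(curves), length(curves) >= 1L)
  analyses <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    an <- analyzeCurve(curves[[i]], spec = spec, ...)
    analyses[[i]] <- an
    if (verbose)
      message(sprintf("[%d/%d] %s: %s", i, length(curves), an@label,
                      if (an@failed) "FAILED"
                      else sprintf("E = %.4g kPa", an@fitApproach@E)))
  }
  res <- do.call(rbind, lapply(analyses, .analysisRow))
  attr(res, "analyses") <- analyses
  if (!is.null(srRange)) {
    ok <- sum(!res$failed)
    if (ok >= 2L)
      attr(res, "summary") <- assessStrategy(
        ifelse(res$failed, NA_real_, res$E), res$h, srRange,
        strategy = paste(spec@components, collapse = "*"))
  }
  res
}

#' Compare approach and withdraw moduli
#'
#' Per-curve ratio of the withdraw-segment to the approach-segment
#' modulus and its median. On purely elastic samples (and on the default
#' synthetic curves) the median is 1 within noise; viscoelastic samples
#' such as living cells show withdraw moduli about two-fold larger.
#'
#' @param results batch result table from [analyzeBatch()] (run with
#'   \code{withdraw = TRUE}).
#' @return list with \code{ratios} (per-curve) and \code{median}; empty
#'   with a warning when no withdraw fits are present.
#' @export
compareApproachWithdraw <- function(results) {
  if (!"EWithdraw" %in% names(results) || all(is.na(results$EWithdraw))) {
    warning("no withdraw fits in the result table")
    return(list(ratios = numeric(), median = NA_real_))
  }
  ok <- !is.na(results$EWithdraw) & !is.na(results$E)
  ratios <- results$EWithdraw[ok] / results$E[ok]
  names(ratios) <- results$label[ok]
  list(ratios = ratios, median = stats::median(ratios))
}
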