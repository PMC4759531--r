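#' @include contact_models.R
NULL

.cpError <- function(msg, class = "cpDetectionError") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Create a contact-point search specification
#'
#' @param components character vector naming the test parameters to
#'   combine: any of \code{"gof_whole"}, \code{"gof_low"}, \code{"rov"},
#'   \code{"delta_e"}, \code{"ple"}. The default is the combination that
#'   performs best on thin soft samples (low-indentation goodness of fit,
#'   ratio of variances, log-modulus derivative).
#' @param rovWindow variance window width (nm) for the RoV test.
#' @param pleVicinity fitted travel (nm) ahead of the trial point for the
#'   power-law-exponent test.
#' @param gofLowFraction fraction of contact points fitted in
#'   \code{"gof_low"} mode.
#' @param gofModel contact model used by the fit-based tests.
#' @param searchRange \code{"auto"}, \code{"full"}, or integer
#'   \code{c(lo, hi)}; see [StrategySpec-class].
#' @param step candidate stride in samples.
#' @return a [StrategySpec-class].
#' @examples
#' strategySpec("gof_whole")
#' strategySpec(c("gof_low", "rov", "delta_e"), searchRange = "full")
#' @export
strategySpec <- function(components = c("gof_low", "rov", "delta_e"),
                         rovWindow = 50, pleVicinity = 250,
                         gofLowFraction = 1 / 3,
                         gofModel = c("becc", "sneddon"),
                         searchRange = "auto", step = 1L) {
  gofModel <- match.arg(gofModel)
  new("StrategySpec", components = components, rovWindow = rovWindow,
      pleVicinity = pleVicinity, gofLowFraction = gofLowFraction,
      gofModel = gofModel, searchRange = searchRange,
      step = as.integer(step))
}

setMethod("show", "StrategySpec", function(object) {
  cat("StrategySpec:", paste(object@components, collapse = " * "), "\n")
  cat(sprintf("  rovWindow = %g nm, pleVicinity = %g nm, gofLowFraction = %.3g\n",
              object@rovWindow, object@pleVicinity, object@gofLowFraction))
  cat(sprintf("  model = %s, searchRange = %s, step = %d\n", object@gofModel,
              if (is.character(object@searchRange)) object@searchRange
              else paste0("[", object@searchRange[1L], ", ",
                          object@searchRange[2L], "]"),
              object@step))
  invisible(NULL)
})

# median approach sampling interval (nm)
.dzApproach <- function(curve) {
  apex <- .apexIndex(curve)
  stats::median(diff(curve@Z[seq_len(apex)]))
}

#' Pre-search vicinity window around a coarse contact estimate
#'
#' Locates the first deflection sample exceeding the baseline level
#' (median of the first \code{baselineFraction} of the approach) by
#' \code{nSd} noise standard deviations (MAD-based, floored at
#' \code{sdFloor} so the rule also works on noiseless data), and returns
#' an index window extending \code{back} nm before and \code{fwd} nm
#' after that crossing. Because deflection grows quadratically from
#' contact, the crossing lags the true contact point by up to a few
#' hundred nm on soft samples; the default margins are chosen so the true
#' contact point is safely inside the window.
#'
#' @param curve a [ForceCurve-class].
#' @param back,fwd window margins (nm) before/after the crossing.
#' @param baselineFraction fraction of the approach treated as baseline.
#' @param nSd threshold in noise standard deviations.
#' @param sdFloor minimum noise scale (nm).
#' @return integer \code{c(lo, hi)} of approach indices, or \code{NULL}
#'   when the deflection never crosses the threshold (no contact
#'   evidence).
#' @export
presearchWindow <- function(curve, back = 750, fwd = 250,
                            baselineFraction = 0.25, nSd = 5,
                            sdFloor = 0.05) {
  stopifnot(is(curve, "ForceCurve"))
  apex <- .apexIndex(curve)
  nb <- max(32L, floor(baselineFraction * apex))
  base <- curve@d[seq_len(min(nb, apex))]
  thr <- stats::median(base) + nSd * max(stats::mad(base), sdFloor)
  beyond <- which(curve@d[seq_len(apex)] > thr)
  beyond <- beyond[beyond > nb]
  # require the crossing to be sustained, not a lone noise spike
  cross <- NA_integer_
  for (i in beyond) {
    upper <- min(i + 4L, apex)
    if (mean(curve@d[i:upper] > thr) >= 0.8) { cross <- i; break }
  }
  if (is.na(cross)) return(NULL)
  dz <- .dzApproach(curve)
  c(max(1L, cross - as.integer(round(back / dz))),
    min(apex, cross + as.integer(round(fwd / dz))))
}

#' Candidate range for a sequential contact-point search
#'
#' Intersects the structural validity margins of every requested
#' component (RoV needs a full variance window on each side; the
#' log-modulus derivative needs 3 candidates on each side for its
#' 6th-order stencil; the power-law test needs its vicinity of travel
#' ahead; goodness-of-fit needs at least 10 points ahead) with the
#' strategy's search range.
#'
#' @param curve a [ForceCurve-class].
#' @param spec a [StrategySpec-class].
#' @return list with \code{candidates} (integer vector, strided by
#'   \code{spec@step}) and \code{window} (the \code{c(lo, hi)} interval).
#' @export
candidateRange <- function(curve, spec) {
  stopifnot(is(curve, "ForceCurve"), is(spec, "StrategySpec"))
  apex <- .apexIndex(curve)
  dz <- .dzApproach(curve)
  lo <- 1L; hi <- apex
  comp <- spec@components
  if (any(c("gof_whole", "gof_low", "delta_e") %in% comp))
    hi <- min(hi, apex - 9L)
  if ("rov" %in% comp) {
    w <- as.integer(round(spec@rovWindow / dz))
    if (w < 5L)
      .cpError(sprintf("rovWindow of %g nm spans only %d samples (>= 5 required)",
                       spec@rovWindow, w), "searchRangeError")
    lo <- max(lo, w + 1L); hi <- min(hi, apex - w)
  }
  if ("delta_e" %in% comp) {
    # own mask: the 6th-order stencil needs 3 modulus values on each side,
    # which in turn must be computable (>= 10 points ahead for the fit)
    lo <- max(lo, 1L + 3L * spec@step)
    hi <- min(hi, apex - 9L - 3L * spec@step)
  }
  if ("ple" %in% comp) {
    zmax <- curve@Z[apex] - spec@pleVicinity
    ok <- which(curve@Z[seq_len(apex)] <= zmax)
    if (length(ok) == 0L)
      .cpError("pleVicinity exceeds the approach travel", "searchRangeError")
    hi <- min(hi, max(ok))
  }
  if (is.character(spec@searchRange)) {
    if (spec@searchRange == "auto") {
      win <- presearchWindow(curve)
      if (is.null(win))
        .cpError("no contact evidence: deflection never leaves the baseline",
                 "cpDetectionError")
      lo <- max(lo, win[1L]); hi <- min(hi, win[2L])
    }
  } else {
    lo <- max(lo, as.integer(spec@searchRange[1L]))
    hi <- min(hi, as.integer(spec@searchRange[2L]))
  }
  if (lo > hi)
    .cpError("empty candidate range: component margins leave no valid trial points",
             "searchRangeError")
  list(candidates = seq.int(lo, hi, by = spec@step), window = c(lo, hi))
}

# per-candidate thickness vector for BECC-based scans
.candidateH <- function(curve, candidates, h) {
  if (!is.null(h)) {
    if (length(h) == 1L) rep(as.numeric(h), length(candidates))
    else if (length(h) == length(candidates)) as.numeric(h)
    else stop("h must be a scalar or one value per candidate")
  } else if (!is.na(curve@Zglass)) {
    curve@Zglass - curve@Z[candidates]
  } else {
    stop("BECC-based search needs a thickness: supply h or a curve with Zglass")
  }
}

# sequential goodness-of-fit scan; one closed-form fit per candidate
.gofScan <- function(curve, candidates, fraction, model, hvec, minAhead = 10L) {
  apex <- .apexIndex(curve)
  Z <- curve@Z; d <- curve@d; k <- curve@k
  theta <- curve@theta; nu <- curve@nu
  m <- length(candidates)
  r2 <- rep(NA_real_, m); E <- rep(NA_real_, m)
  for (ci in seq_len(m)) {
    i <- candidates[ci]
    if (apex - i + 1L < minAhead) next
    hi <- if (model == "becc") hvec[ci] else NA_real_
    if (model == "becc" && (!is.finite(hi) || hi <= 0)) next
    j <- i:apex
    if (fraction < 1) {
      nc <- length(j)
      j <- j[seq_len(min(nc, max(10L, as.integer(ceiling(fraction * nc)))))]
    }
    delta <- (Z[j] - Z[i]) - (d[j] - d[i])
    force <- k * (d[j] - d[i])
    ok <- delta >= 0
    if (model == "becc") ok <- ok & delta < hi
    if (sum(ok) < 5L) next
    fit <- .fitE(delta[ok], force[ok], model, theta, nu, hi)
    if (!fit$converged || !is.finite(fit$r2)) next
    r2[ci] <- fit$r2
    E[ci] <- fit$E
  }
  list(r2 = r2, E = E)
}

#' Goodness-of-fit test parameter
#'
#' For each trial contact point the curve is re-referenced so that
#' indentation and force are zero there, the contact model is fitted to
#' the contact part (all points ahead of the trial point, or only the
#' first \code{fraction} of them in \code{"low"} mode), and the r-squared
#' of the fit is the test parameter. One fit per candidate.
#'
#' @param curve a [ForceCurve-class].
#' @param candidates integer vector of trial indices (see
#'   [candidateRange()]).
#' @param mode \code{"whole"} or \code{"low"}.
#' @param model \code{"becc"} or \code{"sneddon"}.
#' @param h thickness (nm): a scalar, one value per candidate, or
#'   \code{NULL} to derive per-candidate thickness from the curve's glass
#'   reference. Required (directly or via Zglass) for \code{"becc"}.
#' @param fraction fraction of contact points fitted in \code{"low"} mode.
#' @return numeric trace of r-squared values over the candidates
#'   (\code{NA} = invalid), with the per-candidate modulus series in
#'   attribute \code{"E"}.
#' @export
testparamGoF <- function(curve, candidates, mode = c("whole", "low"),
                         model = c("becc", "sneddon"), h = NULL,
                         fraction = 1 / 3) {
  mode <- match.arg(mode); model <- match.arg(model)
  stopifnot(is(curve, "ForceCurve"))
  candidates <- as.integer(candidates)
  hvec <- if (model == "becc") .candidateH(curve, candidates, h) else NULL
  scan <- .gofScan(curve, candidates, if (mode == "low") fraction else 1,
                   model, hvec)
  structure(scan$r2, E = scan$E)
}

# running variance over fixed-width windows via cumulative sums
.windowVar <- function(x, a, b) {
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x * x))
  n <- b - a + 1
  S1 <- s1[b + 1L] - s1[a]
  S2 <- s2[b + 1L] - s2[a]
  (S2 - S1^2 / n) / (n - 1)
}

.ROV_VAR_FLOOR <- 1e-6  # (1e-3 nm)^2 guard against noiseless flat windows

#' Ratio-of-variances test parameter
#'
#' The deflection variance in a window just ahead of the trial point
#' (contact side) divided by the variance in a window just behind it
#' (non-contact side); the trial point itself belongs to neither window.
#' Far from contact both windows see only instrument noise and the ratio
#' is close to 1; near the contact point the ahead-window picks up the
#' contact rise while the behind-window is still flat, producing a peak.
#'
#' @param curve a [ForceCurve-class].
#' @param candidates integer vector of trial indices.
#' @param window window width (nm); must span at least 5 samples.
#' @return numeric trace over the candidates, with attribute
#'   \code{"floored"} flagging entries whose denominator was clamped at
#'   the variance floor (noiseless flat regions).
#' @export
testparamRoV <- function(curve, candidates, window = 50) {
  stopifnot(is(curve, "ForceCurve"))
  candidates <- as.integer(candidates)
  apex <- .apexIndex(curve)
  dz <- .dzApproach(curve)
  w <- as.integer(round(window / dz))
  if (w < 5L)
    stop(sprintf("window of %g nm spans only %d samples (>= 5 required)",
                 window, w))
  d <- curve@d[seq_len(apex)]
  ok <- candidates - w >= 1L & candidates + w <= apex
  rov <- rep(NA_real_, length(candidates))
  floored <- rep(FALSE, length(candidates))
  if (any(ok)) {
    cc <- candidates[ok]
    num <- .windowVar(d, cc + 1L, cc + w)
    den <- .windowVar(d, cc - w, cc - 1L)
    floored[ok] <- den < .ROV_VAR_FLOOR
    rov[ok] <- num / pmax(den, .ROV_VAR_FLOOR)
  }
  structure(rov, floored = floored)
}

# 6th-order central first-derivative stencil (unit spacing)
.D6_STENCIL <- c(-1, 9, -45, 0, 45, -9, 1) / 60

#' Log-modulus derivative test parameter
#'
#' Given the per-candidate modulus series E(i) from a sequential
#' goodness-of-fit scan, computes \eqn{\Delta E_i = -d(\ln E)/di} with a
#' 6th-order central finite-difference stencil. The sign is chosen so
#' that an inflection of ln E(i) (a local minimum of its derivative) in
#' the vicinity of the contact point appears as a local maximum of the
#' trace. The three candidates at each edge, and any candidate whose
#' stencil touches an invalid or non-positive modulus, are invalid.
#'
#' @param Eseries numeric, modulus (kPa) per candidate (\code{NA} =
#'   invalid); at least 7 consecutive valid entries are required.
#' @return numeric trace over the same grid.
#' @export
testparamDeltaE <- function(Eseries) {
  m <- length(Eseries)
  valid <- is.finite(Eseries) & Eseries > 0
  runs <- rle(valid)
  if (!any(runs$lengths[runs$values] >= 7L))
    stop("delta_e needs at least 7 consecutive valid modulus values")
  lnE <- ifelse(valid, log(Eseries), NA_real_)
  out <- rep(NA_real_, m)
  if (m >= 7L) {
    idx <- 4L:(m - 3L)
    acc <- rep(0, length(idx)); bad <- rep(FALSE, length(idx))
    for (s in -3:3) {
      v <- lnE[idx + s]
      bad <- bad | !is.finite(v)
      acc <- acc + .D6_STENCIL[s + 4L] * ifelse(is.finite(v), v, 0)
    }
    out[idx] <- ifelse(bad, NA_real_, -acc)
  }
  out
}

#' Power-law-exponent test parameter
#'
#' For each trial point, fits \eqn{F = A\delta^x} to the small region of
#' travel just ahead of it (piezo positions within \code{vicinity} nm).
#' At the true contact point the response of a conical tip is purely
#' quadratic, so the raw score \eqn{-|x - 2|} peaks there; restricting
#' the fit to a small vicinity keeps the thin-film higher-order terms
#' from dominating.
#'
#' @param curve a [ForceCurve-class].
#' @param candidates integer vector of trial indices.
#' @param vicinity fitted travel ahead of the trial point (nm).
#' @return numeric trace of \eqn{-|x-2|} over the candidates, with the
#'   fitted exponent series in attribute \code{"x"}.
#' @export
testparamPLE <- function(curve, candidates, vicinity = 250) {
  stopifnot(is(curve, "ForceCurve"))
  candidates <- as.integer(candidates)
  apex <- .apexIndex(curve)
  Z <- curve@Z; d <- curve@d; k <- curve@k
  m <- length(candidates)
  score <- rep(NA_real_, m); xs <- rep(NA_real_, m)
  for (ci in seq_len(m)) {
    i <- candidates[ci]
    if (i >= apex) next
    j <- (i + 1L):apex
    j <- j[Z[j] <= Z[i] + vicinity]
    if (length(j) < 5L) next
    delta <- (Z[j] - Z[i]) - (d[j] - d[i])
    force <- k * (d[j] - d[i])
    keep <- is.finite(delta) & is.finite(force) & delta > 0 & force > 0
    if (sum(keep) < 5L) next
    fit <- .powerFit(delta[keep], force[keep])
    if (is.null(fit) || !is.finite(fit$x)) next
    xs[ci] <- fit$x
    score[ci] <- -abs(fit$x - 2)
  }
  structure(score, x = xs)
}

#' Min-max normalise a test-parameter trace
#'
#' Affine map of the valid entries onto [0, 1]; the argmax is preserved
#' and invalid entries stay invalid. Normalising to a non-negative range
#' is what makes traces with negative raw scores usable as factors of a
#' multiplicative combination. A constant trace carries no peak: it is
#' mapped to all zeros and a \code{"noPeakWarning"} is raised.
#'
#' @param trace numeric trace (\code{NA} = invalid).
#' @return normalised trace of the same length.
#' @examples
#' normalizeTrace(c(1, 3, 2))
#' @export
normalizeTrace <- function(trace) {
  valid <- is.finite(trace)
  if (sum(valid) < 2L)
    stop("cannot normalise: fewer than 2 valid trace entries")
  rng <- range(trace[valid])
  out <- rep(NA_real_, length(trace))
  if (rng[1L] == rng[2L]) {
    warning(structure(
      class = c("noPeakWarning", "warning", "condition"),
      list(message = "constant trace: no peak to normalise", call = NULL)))
    out[valid] <- 0
  } else {
    out[valid] <- (trace[valid] - rng[1L]) / (rng[2L] - rng[1L])
  }
  attributes(out) <- attributes(trace)
  out
}

#' Combine normalised traces by elementwise product
#'
#' Entries invalid in any component are invalid in the product. The
#' combined trace may have several peaks; the contact point is taken at
#' the highest one.
#'
#' @param traces list of numeric traces on the same candidate grid.
#' @return numeric product trace.
#' @export
combineTraces <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  len <- unique(vapply(traces, length, 0L))
  if (length(len) != 1L)
    stop("traces must share the candidate grid")
  out <- rep(1, len)
  for (tr in traces) out <- out * as.numeric(tr)
  if (!any(is.finite(out)))
    .cpError("trace combination failed: no candidate valid in every component",
             "combinationError")
  out
}

# count local maxima of a trace (NA-tolerant)
.countPeaks <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) < 3L) return(as.integer(length(v) > 0L))
  up <- diff(v) > 0
  sum(head(up, -1L) & !tail(up, -1L)) +
    as.integer(v[1L] > v[2L]) + as.integer(v[length(v)] > v[length(v) - 1L])
}

#' Detect the contact point of a force curve
#'
#' Runs the sequential search: every candidate trial point in the search
#' range is scored by each component of the strategy, each trace is
#' min-max normalised, the traces are multiplied, and the contact point
#' is the candidate with the highest combined value (ties towards the
#' earlier index). When the strategy contains both a goodness-of-fit
#' component and the log-modulus derivative, the derivative consumes the
#' modulus series of the goodness-of-fit scan, so a single fit per
#' candidate suffices; a standalone \code{"delta_e"} uses whole-contact
#' fits.
#'
#' The result is flagged low-confidence when no fit-based component shows
#' a convincing contact signature (all goodness-of-fit r-squared below
#' 0.5, power-law exponents far from 2). A curve with no contact evidence
#' at all raises an error of class \code{"cpDetectionError"} rather than
#' returning a silent index.
#'
#' @param curve a [ForceCurve-class].
#' @param spec a [StrategySpec-class].
#' @param h optional thickness (nm) forwarded to the fit-based components
#'   (default: derived per candidate from the curve's glass reference).
#' @return a [CPResult-class].
#' @examples
#' prof <- sampleProfile(nPoints = 512L, noiseSd = 0.5)
#' sim <- generateCurve(prof, seed = 7)
#' cp <- findContactPoint(sim$curve, strategySpec())
#' cpIndex(cp) - sim$truth$cpIndex
#' @export
findContactPoint <- function(curve, spec = strategySpec(), h = NULL) {
  stopifnot(is(curve, "ForceCurve"), is(spec, "StrategySpec"))
  cr <- candidateRange(curve, spec)
  cand <- cr$candidates
  comp <- spec@components
  notes <- character()
  raw <- list()

  # the stencil of delta_e needs modulus values 3 candidate steps beyond
  # the reported range, so fit-based scans run on an extended grid
  s <- spec@step
  ext <- cand
  if ("delta_e" %in% comp) {
    apex <- .apexIndex(curve)
    ext <- seq.int(cand[1L] - 3L * s, cand[length(cand)] + 3L * s, by = s)
    ext <- ext[ext >= 1L & ext <= apex - 9L]
  }
  sub <- match(cand, ext)

  for (cm in intersect(c("gof_whole", "gof_low"), comp)) {
    tr <- testparamGoF(curve, ext,
                       mode = if (cm == "gof_low") "low" else "whole",
                       model = spec@gofModel, h = h,
                       fraction = spec@gofLowFraction)
    raw[[cm]] <- structure(as.numeric(tr)[sub], E = attr(tr, "E"))
  }
  # modulus series feeding delta_e: reuse a GoF scan when available
  if ("delta_e" %in% comp) {
    src <- if ("gof_low" %in% comp) "gof_low"
           else if ("gof_whole" %in% comp) "gof_whole"
           else NA_character_
    Eseries <- if (!is.na(src)) attr(raw[[src]], "E")
    else attr(testparamGoF(curve, ext, mode = "whole",
                           model = spec@gofModel, h = h), "E")
    raw[["delta_e"]] <- tryCatch(testparamDeltaE(Eseries)[sub],
                                 error = function(e) .cpError(conditionMessage(e)))
  }
  if ("rov" %in% comp)
    raw[["rov"]] <- testparamRoV(curve, cand, window = spec@rovWindow)
  if ("ple" %in% comp)
    raw[["ple"]] <- testparamPLE(curve, cand, vicinity = spec@pleVicinity)
  raw <- raw[intersect(comp, names(raw))]

  norm <- withCallingHandlers(
    lapply(raw, normalizeTrace),
    noPeakWarning = function(w) {
      notes <<- c(notes, "constant_component_trace")
      invokeRestart("muffleWarning")
    })
  combined <- combineTraces(norm)
  finiteIdx <- which(is.finite(combined))
  if (max(combined[finiteIdx]) <= 0)
    .cpError("detection failed: combined trace has no peak")
  best <- finiteIdx[which.max(combined[finiteIdx])]
  cpi <- cand[best]

  weak <- logical(0)
  for (cm in intersect(c("gof_whole", "gof_low"), names(raw)))
    weak <- c(weak, max(raw[[cm]], na.rm = TRUE) < 0.5)
  if ("ple" %in% names(raw))
    weak <- c(weak, max(raw[["ple"]], na.rm = TRUE) < -0.5)
  lowConf <- length(weak) > 0L && all(weak)
  if (lowConf) notes <- c(notes, "weak_contact_signature")

  new("CPResult", cpIndex = cpi, Zcp = curve@Z[cpi], dcp = curve@d[cpi],
      candidates = cand, traces = norm, rawTraces = raw,
      combined = combined, nPeaks = .countPeaks(combined),
      lowConfidence = lowConf, notes = notes)
}

#' @rdname CPResult-accessors
setMethod("cpIndex", "CPResult", function(object) object@cpIndex)
#' @rdname CPResult-accessors
setMethod("combinedTrace", "CPResult", function(object) object@combined)
#' @rdname CPResult-accessors
setMethod("traceMatrix", "CPResult", function(object) {
  m <- do.call(cbind, lapply(object@traces, as.numeric))
  rownames(m) <- object@candidates
  m
})
#' @rdname CPResult-accessors
setMethod("nPeaks", "CPResult", function(object) object@nPeaks)
#' @rdname CPResult-accessors
setMethod("isLowConfidence", "CPResult", function(object) object@lowConfidence)

setMethod("show", "CPResult", function(object) {
  cat(sprintf("CPResult: contact at index %d (Z = %.1f nm, d = %.2f nm)\n",
              object@cpIndex, object@Zcp, object@dcp))
  cat(sprintf("  %d candidates in [%d, %d], components: %s\n",
              length(object@candidates), min(object@candidates),
              max(object@candidates),
              paste(names(object@traces), collapse = " * ")))
  cat(sprintf("  combined trace has %d peak(s)%s\n", object@nPeaks,
              if (object@lowConfidence) "; LOW CONFIDENCE" else ""))
  invisible(NULL)
})

#' Dump detection traces to a TSV file
#'
#' Writes the candidate grid with the raw and normalised traces and the
#' combined product, for external plotting of the sequential-search
#' diagnostics.
#'
#' @param cp a [CPResult-class].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(cp, path) {
  stopifnot(is(cp, "CPResult"))
  df <- data.frame(candidate = cp@candidates)
  for (nm in names(cp@rawTraces))
    df[[paste0(nm, "_raw")]] <- as.numeric(cp@rawTraces[[nm]])
  for (nm in names(cp@traces))
    df[[paste0(nm, "_norm")]] <- as.numeric(cp@traces[[nm]])
  df$combined <- cp@combined
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
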