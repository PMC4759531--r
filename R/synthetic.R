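#' @include assessment.R
NULL

#' Create a synthetic sample profile
#'
#' See [SampleProfile-class] for the meaning and the rationale of the
#' defaults.
#'
#' @param ETrue true Young's modulus (kPa).
#' @param hRange thickness sampling interval (nm).
#' @param noiseSd deflection noise sd (nm).
#' @param k spring constant (N/m).
#' @param theta tip half-opening angle (degrees).
#' @param nu Poisson ratio.
#' @param rampSize ramp length (nm).
#' @param nPoints samples per approach.
#' @param cpPositionRange fraction interval of the ramp where the true
#'   contact point falls.
#' @param maxIndentationFactor model-validity cap on indentation as a
#'   fraction of thickness.
#' @param withdrawStiffening modulus factor for the withdraw segment.
#' @param baselineDrift linear deflection drift (nm per nm of Z).
#' @return a [SampleProfile-class].
#' @export
sampleProfile <- function(ETrue = 10, hRange = c(2000, 8000), noiseSd = 1,
                          k = 0.03, theta = 35, nu = 0.5,
                          rampSize = 5000, nPoints = 2048L,
                          cpPositionRange = c(0.75, 0.9),
                          maxIndentationFactor = 0.8,
                          withdrawStiffening = 1, baselineDrift = 0) {
  new("SampleProfile", ETrue = ETrue, hRange = as.numeric(hRange),
      noiseSd = noiseSd, k = k, theta = theta, nu = nu,
      rampSize = rampSize, nPoints = as.integer(nPoints),
      cpPositionRange = as.numeric(cpPositionRange),
      maxIndentationFactor = maxIndentationFactor,
      withdrawStiffening = withdrawStiffening,
      baselineDrift = baselineDrift)
}

setMethod("show", "SampleProfile", function(object) {
  cat(sprintf("SampleProfile: E = %g kPa, h ~ U(%g, %g) nm, noise = %g nm\n",
              object@ETrue, object@hRange[1L], object@hRange[2L],
              object@noiseSd))
  cat(sprintf("  ramp %g nm x %d points, k = %g N/m, theta = %g deg, nu = %g\n",
              object@rampSize, object@nPoints, object@k, object@theta,
              object@nu))
  cat(sprintf("  CP in (%.2f, %.2f) of ramp, delta capped at %.2f h\n",
              object@cpPositionRange[1L], object@cpPositionRange[2L],
              object@maxIndentationFactor))
  invisible(NULL)
})

# solve the implicit force balance k d = F_becc((z - d)) for each contact
# sample by vectorised bisection; z is travel past the contact point.
# F_becc is strictly increasing in indentation, so k d - F(z - d) is
# strictly increasing in d and the root in [0, z] is unique.
.solveDeflection <- function(z, E, theta, nu, h, k, iter = 60L) {
  lo <- rep(0, length(z)); hi <- z
  cf <- beccCoefficients()
  tt <- .tanDeg(theta)
  c0 <- (2 / pi) * (E * 1e-6 / (1 - nu^2)) * tt
  for (it in seq_len(iter)) {
    mid <- (lo + hi) / 2
    delta <- z - mid
    w <- delta * tt / h
    g <- k * mid - c0 * delta^2 * (1 + cf[["b1"]] * w + cf[["b2"]] * w^2)
    up <- g > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Generate one ground-truthed synthetic force curve
#'
#' Draws a thickness and a contact position, then constructs a triangular
#' ramp whose contact-side deflection solves the implicit cantilever
#' force balance \eqn{k d = F_{BECC}(\delta)} with
#' \eqn{\delta = (Z - Z_{CP}) - (d - d_{CP})}, by bracketed bisection
#' (the corrected cone force is strictly increasing in indentation, so
#' the root is unique). Before contact the noiseless deflection is zero.
#' iid Gaussian noise of sd \code{noiseSd} is then added to the
#' deflection, and the glass reference is set consistently with the true
#' thickness (\code{Zglass = Zcp + h}). The curve contains the approach
#' and a mirrored withdraw segment (identical elastic response unless
#' \code{withdrawStiffening != 1}).
#'
#' @param profile a [SampleProfile-class].
#' @param seed integer seed; the same profile and seed reproduce the
#'   curve bit for bit.
#' @return list with \code{curve} (a [ForceCurve-class]) and \code{truth}
#'   (one-row \code{data.frame}: \code{label}, \code{cpIndex} — the
#'   approach sample at the true contact point, which is snapped onto the
#'   sampling grid —, \code{Zcp}, \code{ETrue}, \code{hTrue},
#'   \code{noiseSd}, \code{seed}).
#' @export
generateCurve <- function(profile, seed) {
  stopifnot(is(profile, "SampleProfile"))
  seed <- as.integer(seed)
  set.seed(seed)
  h <- stats::runif(1, profile@hRange[1L], profile@hRange[2L])
  cpfrac <- stats::runif(1, profile@cpPositionRange[1L],
                         profile@cpPositionRange[2L])
  n <- profile@nPoints
  Zapp <- seq(0, profile@rampSize, length.out = n)
  # snap the true contact point onto the sampling grid so that the
  # ground-truth index is exact (no sub-sample origin offset)
  cpi <- which.min(abs(Zapp - cpfrac * profile@rampSize))
  Zcp <- Zapp[cpi]
  contact <- Zapp > Zcp
  dApp <- numeric(n)
  z <- Zapp[contact] - Zcp
  dApp[contact] <- .solveDeflection(z, profile@ETrue, profile@theta,
                                    profile@nu, h, profile@k)
  deltaMax <- max(z - dApp[contact])
  if (deltaMax > profile@maxIndentationFactor * h)
    stop(sprintf(paste0("generation error: indentation %.0f nm exceeds %.2f x",
                        " thickness (%.0f nm); shorten the contact travel or",
                        " thicken the sample"),
                 deltaMax, profile@maxIndentationFactor, h))
  # withdraw mirrors the approach (apex not duplicated)
  Zwd <- Zapp[(n - 1L):1L]
  contactWd <- Zwd > Zcp
  dWd <- numeric(n - 1L)
  if (any(contactWd))
    dWd[contactWd] <- .solveDeflection(
      Zwd[contactWd] - Zcp, profile@ETrue * profile@withdrawStiffening,
      profile@theta, profile@nu, h, profile@k)
  Z <- c(Zapp, Zwd)
  d <- c(dApp, dWd)
  if (profile@baselineDrift != 0) d <- d + profile@baselineDrift * Z
  if (profile@noiseSd > 0) d <- d + stats::rnorm(length(d), 0, profile@noiseSd)
  label <- sprintf("sim-%d", seed)
  curve <- forceCurve(Z, d, k = profile@k, theta = profile@theta,
                      nu = profile@nu, Zglass = Zcp + h, label = label)
  truth <- data.frame(label = label,
                      cpIndex = cpi,
                      Zcp = Zcp, ETrue = profile@ETrue, hTrue = h,
                      noiseSd = profile@noiseSd, seed = seed,
                      stringsAsFactors = FALSE)
  list(curve = curve, truth = truth)
}

#' Generate a ground-truthed synthetic curve batch
#'
#' Per-curve seeds are derived deterministically from the master seed, so
#' batches are reproducible and different master seeds give disjoint
#' noise realisations.
#'
#' @param profile a [SampleProfile-class].
#' @param nCurves number of curves.
#' @param seed master seed (kept small; derived seeds stay below 2^31).
#' @param dir optional directory: when given, each curve is written in
#'   the TSV dialect of [writeForceCurve()] together with a
#'   \code{truth.tsv} table and a \code{config.yaml} of shared metadata.
#' @return list with \code{curves} (named list of [ForceCurve-class]) and
#'   \code{truth} (\code{data.frame}, one row per curve).
#' @export
generateDataset <- function(profile, nCurves, seed, dir = NULL) {
  stopifnot(is(profile, "SampleProfile"), nCurves >= 1L)
  seeds <- as.integer(seed) + 7919L * seq_len(nCurves)
  curves <- vector("list", nCurves)
  truths <- vector("list", nCurves)
  for (i in seq_len(nCurves)) {
    g <- generateCurve(profile, seeds[i])
    curves[[i]] <- g$curve
    truths[[i]] <- g$truth
  }
  names(curves) <- vapply(curves, curveLabel, "")
  truth <- do.call(rbind, truths)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (fc in curves)
      writeForceCurve(fc, file.path(dir, paste0(curveLabel(fc), ".tsv")))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(k = profile@k, theta = profile@theta,
                          nu = profile@nu),
                     file.path(dir, "config.yaml"))
  }
  list(curves = curves, truth = truth)
}
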