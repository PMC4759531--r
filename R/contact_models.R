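#' @include curves.R
NULL

## Unit conventions throughout: delta, h in nm; E in kPa; F in nN;
## 1 kPa = 1e-6 nN/nm^2, hence the 1e-6 prefactor.

.tanDeg <- function(theta) tan(theta * pi / 180)

#' Bottom-effect cone correction coefficients
#'
#' Coefficients of the multiplicative thin-film correction polynomial
#' \eqn{B(w) = 1 + b_1 w + b_2 w^2} with \eqn{w = \delta \tan\theta / h},
#' applied to Sneddon's cone force for a soft layer bonded to a rigid
#' substrate. They derive from the bonded-layer image-charge constant
#' \eqn{\alpha_0 = 1.7795} (incompressible limit):
#' \eqn{b_1 = 2\alpha_0/\pi^2}, \eqn{b_2 = 16\alpha_0^2}.
#' Kept in one place so the transcription is isolated and testable; the
#' Sneddon limit \eqn{B(0) = 1} is pinned by a unit test.
#'
#' @return named numeric vector with elements \code{b1} and \code{b2}.
#' @seealso [beccForce()]
#' @export
beccCoefficients <- function() {
  c(b1 = 2 * 1.7795 / pi^2, b2 = 16 * 1.7795^2)
}

#' Sneddon cone force
#'
#' Force on a rigid cone indenting an elastic half-space:
#' \deqn{F = \frac{2}{\pi}\,\frac{E}{1-\nu^2}\,\tan\theta\,\delta^2}
#'
#' @param delta numeric, indentation (nm), must be non-negative.
#' @param E numeric(1), Young's modulus (kPa).
#' @param theta numeric(1), half-opening angle (degrees).
#' @param nu numeric(1), Poisson ratio.
#' @return numeric, force (nN).
#' @examples
#' sneddonForce(500, E = 10)  # about 1.486 nN
#' @export
sneddonForce <- function(delta, E, theta = 35, nu = 0.5) {
  if (any(delta < 0, na.rm = TRUE))
    stop("indentation must be non-negative")
  (2 / pi) * (E * 1e-6 / (1 - nu^2)) * .tanDeg(theta) * delta^2
}

#' Bottom-effect-corrected cone force (BECC)
#'
#' Sneddon's cone force multiplied by the thin-film correction
#' \eqn{B(\delta\tan\theta/h)} (see [beccCoefficients()]), which accounts
#' for the rigid substrate under a bonded sample of finite thickness
#' \code{h}. \eqn{B} is monotone increasing with \eqn{B(0)=1}, so the
#' corrected force is always at least the Sneddon force and grows as the
#' layer gets thinner.
#'
#' @inheritParams sneddonForce
#' @param h numeric(1) or numeric, sample thickness (nm); must exceed the
#'   indentation.
#' @return numeric, force (nN).
#' @export
beccForce <- function(delta, E, theta = 35, nu = 0.5, h) {
  if (any(h <= 0, na.rm = TRUE))
    stop("thickness h must be positive")
  if (any(delta >= h, na.rm = TRUE))
    stop("indentation exceeds thickness: BECC requires delta < h")
  cf <- beccCoefficients()
  w <- delta * .tanDeg(theta) / h
  sneddonForce(delta, E, theta, nu) * (1 + cf[["b1"]] * w + cf[["b2"]] * w^2)
}

# model force at E = 1 kPa (both models are linear in E)
.modelShape <- function(delta, model, theta, nu, h = NULL) {
  base <- (2 / pi) * (1e-6 / (1 - nu^2)) * .tanDeg(theta) * delta^2
  if (model == "becc") {
    cf <- beccCoefficients()
    w <- delta * .tanDeg(theta) / h
    base * (1 + cf[["b1"]] * w + cf[["b2"]] * w^2)
  } else base
}

.E_BOUNDS <- c(1e-3, 1e4)  # admissible modulus range, kPa

# core 1-parameter least-squares modulus estimate on prepared vectors;
# returns list(E, r2, rss, converged)
.fitE <- function(delta, force, model, theta, nu, h) {
  g <- .modelShape(delta, model, theta, nu, h)
  sg2 <- sum(g * g)
  if (!is.finite(sg2) || sg2 <= 0)
    return(list(E = NA_real_, r2 = NA_real_, rss = NA_real_, converged = FALSE))
  E <- sum(force * g) / sg2
  converged <- is.finite(E) && E > .E_BOUNDS[1L] && E <= .E_BOUNDS[2L]
  E <- min(max(E, .E_BOUNDS[1L]), .E_BOUNDS[2L])
  res <- force - E * g
  rss <- sum(res^2)
  sst <- sum((force - mean(force))^2)
  r2 <- if (sst > 0) 1 - rss / sst else NA_real_
  list(E = E, r2 = r2, rss = rss, converged = converged)
}

#' Fit a Young's modulus to indentation-force data
#'
#' Least-squares fit of the Sneddon or BECC force model with the modulus
#' E as the only free parameter. Both models are linear in E, so the
#' minimiser is computed in closed form (\eqn{\hat E = \sum F g / \sum
#' g^2} with \eqn{g} the model force at E = 1) and constrained to the
#' admissible range (1e-3, 1e4] kPa; estimates falling outside are
#' clamped and flagged as non-converged. Points with negative indentation
#' are excluded (the models describe contact only), as are points with
#' \eqn{\delta \ge h} for the BECC model. The coefficient of
#' determination is computed on the fitted range only.
#'
#' @param delta numeric, indentation samples (nm).
#' @param force numeric, force samples (nN), same length.
#' @param model \code{"sneddon"} or \code{"becc"}.
#' @param theta,nu tip half-angle (degrees) and Poisson ratio.
#' @param h numeric(1), thickness (nm); required for \code{"becc"}.
#' @param fitRange optional integer \code{c(lo, hi)} index interval of the
#'   input vectors to fit; default all.
#' @return an [EFit-class].
#' @examples
#' delta <- seq(0, 800, by = 4)
#' f <- sneddonForce(delta, E = 10)
#' youngsModulus(fitModulus(delta, f, "sneddon"))
#' @export
fitModulus <- function(delta, force, model = c("sneddon", "becc"),
                       theta = 35, nu = 0.5, h = NULL, fitRange = NULL) {
  model <- match.arg(model)
  stopifnot(length(delta) == length(force))
  if (model == "becc") {
    if (is.null(h) || length(h) != 1L || !is.finite(h) || h <= 0)
      stop("model 'becc' requires a single positive thickness h")
  }
  if (is.null(fitRange)) fitRange <- c(1L, length(delta))
  fitRange <- as.integer(fitRange)
  if (length(fitRange) != 2L || fitRange[1L] < 1L ||
      fitRange[2L] > length(delta) || fitRange[1L] > fitRange[2L])
    stop("invalid fitRange")
  sel <- seq.int(fitRange[1L], fitRange[2L])
  keep <- is.finite(delta[sel]) & is.finite(force[sel]) & delta[sel] >= 0
  if (model == "becc") keep <- keep & delta[sel] < h
  sel <- sel[keep]
  if (length(sel) < 5L)
    stop("insufficient data: fewer than 5 usable points in fitRange")
  if (all(force[sel] == 0))
    stop("degenerate fit: all forces are zero")
  fit <- .fitE(delta[sel], force[sel], model, theta, nu, h)
  new("EFit", E = fit$E, model = model, r2 = fit$r2,
      residualNorm = sqrt(fit$rss), fitRange = fitRange,
      nPoints = length(sel), h = if (model == "becc") h else NA_real_,
      converged = fit$converged)
}

# damped Gauss-Newton for F = A * delta^x on log-positive data;
# init from the log-log regression. Written out (rather than nls) because
# the PLE trace calls this hundreds of times per curve.
.powerFit <- function(delta, force, maxit = 50L, tol = 1e-12) {
  ld <- log(delta); lf <- log(force)
  vx <- stats::var(ld)
  if (!is.finite(vx) || vx == 0) return(NULL)
  x <- stats::cov(ld, lf) / vx
  la <- mean(lf) - x * mean(ld)
  lambda <- 1e-8
  obj <- function(la, x) {
    r <- force - exp(la) * delta^x
    sum(r * r)
  }
  S <- obj(la, x)
  for (it in seq_len(maxit)) {
    Fm <- exp(la) * delta^x
    r <- force - Fm
    # Jacobian wrt (la, x)
    j1 <- Fm
    j2 <- Fm * ld
    a11 <- sum(j1 * j1); a12 <- sum(j1 * j2); a22 <- sum(j2 * j2)
    g1 <- sum(j1 * r); g2 <- sum(j2 * r)
    step <- NULL
    for (tries in 1:8) {
      d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
      det <- d11 * d22 - a12 * a12
      if (!is.finite(det) || abs(det) < 1e-300) { lambda <- lambda * 10; next }
      s1 <- (g1 * d22 - g2 * a12) / det
      s2 <- (g2 * d11 - g1 * a12) / det
      Snew <- obj(la + s1, x + s2)
      if (is.finite(Snew) && Snew <= S) { step <- c(s1, s2); break }
      lambda <- lambda * 10
    }
    if (is.null(step)) break
    la <- la + step[1L]; x <- x + step[2L]
    lambda <- max(lambda / 10, 1e-12)
    if (S - obj(la, x) <= tol * (S + tol)) { S <- obj(la, x); break }
    S <- obj(la, x)
  }
  list(A = exp(la), x = x, rss = S)
}

#' Fit a power law to indentation-force data
#'
#' Fits \eqn{F = A \delta^x} with both the prefactor and the exponent
#' free, initialised from the log-log linear regression and refined by
#' damped Gauss-Newton. For an ideal cone on a half-space the exponent is
#' exactly 2; thin-film corrections push it above 2 at larger
#' indentations. Points with non-positive indentation or force are
#' dropped before fitting.
#'
#' @param delta numeric, indentation samples (nm).
#' @param force numeric, force samples (nN).
#' @return an [EFit-class] with \code{model = "power_law"}; the exponent is
#'   available via [powerLawExponent()].
#' @examples
#' delta <- seq(1, 500, by = 2.5)
#' fit <- fitPowerLaw(delta, 2e-6 * delta^2)
#' powerLawExponent(fit)
#' @export
fitPowerLaw <- function(delta, force) {
  stopifnot(length(delta) == length(force))
  keep <- is.finite(delta) & is.finite(force) & delta > 0 & force > 0
  if (sum(keep) < 5L)
    stop("insufficient data: fewer than 5 points with positive delta and force")
  dd <- delta[keep]; ff <- force[keep]
  fit <- .powerFit(dd, ff)
  if (is.null(fit))
    stop("degenerate fit: indentation values carry no spread")
  sst <- sum((ff - mean(ff))^2)
  r2 <- if (sst > 0) 1 - fit$rss / sst else NA_real_
  new("EFit", E = NA_real_, model = "power_law", x = fit$x, A = fit$A,
      r2 = r2, residualNorm = sqrt(fit$rss),
      fitRange = c(1L, length(delta)), nPoints = sum(keep),
      converged = is.finite(fit$x))
}

#' @rdname EFit-accessors
setMethod("youngsModulus", "EFit", function(object) object@E)
#' @rdname EFit-accessors
setMethod("rSquared", "EFit", function(object) object@r2)
#' @rdname EFit-accessors
setMethod("powerLawExponent", "EFit", function(object) object@x)
#' @rdname EFit-accessors
setMethod("modelName", "EFit", function(object) object@model)
#' @rdname EFit-accessors
setMethod("isConverged", "EFit", function(object) object@converged)

setMethod("show", "EFit", function(object) {
  if (object@model == "power_law")
    cat(sprintf("EFit (power law): x = %.4g, A = %.4g nN/nm^x", object@x,
                object@A))
  else
    cat(sprintf("EFit (%s): E = %.4g kPa", object@model, object@E))
  cat(sprintf(", r2 = %.6g, n = %d%s%s\n", object@r2, object@nPoints,
              if (!is.na(object@h)) sprintf(", h = %.4g nm", object@h) else "",
              if (object@converged) "" else " [not converged]"))
  invisible(NULL)
})

# serialisable record of a fit
.efitRecord <- function(fit) {
  if (is.null(fit)) return(list())
  list(E = fit@E, model = fit@model, x = fit@x, A = fit@A, r2 = fit@r2,
       nPoints = fit@nPoints, h = fit@h, converged = fit@converged)
}
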