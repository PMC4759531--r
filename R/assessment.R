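#' @include cp_detect.R
NULL

#' Success rate of a curve collection
#'
#' Fraction of curves whose modulus falls inside a predefined acceptance
#' range (bounds inclusive). Failed analyses enter as \code{NA} and count
#' in the denominator: a strategy is not rewarded for failing quietly.
#'
#' @param E numeric, modulus per curve (kPa); \code{NA} = failed.
#' @param range numeric \code{c(min, max)} acceptance interval (kPa).
#' @return fraction in [0, 1].
#' @examples
#' successRate(c(5, 70, 0.2), c(0.3, 60))   # 1/3
#' successRate(c(5, NA), c(0.3, 60))        # 0.5
#' @export
successRate <- function(E, range) {
  if (length(E) == 0L) stop("undefined metric: empty modulus list")
  if (length(range) != 2L || range[1L] >= range[2L])
    stop("range must be c(min, max) with min < max")
  mean(!is.na(E) & E >= range[1L] & E <= range[2L])
}

#' Covariance between modulus and thickness
#'
#' Sample covariance (denominator n-1) between the per-curve modulus and
#' the local sample thickness. After a correct thin-film analysis of a
#' homogeneous sample the modulus carries no thickness dependence, so a
#' low covariance indicates that the substrate effect was properly
#' corrected; a negative value is the signature of overcorrection
#' (thin spots appearing stiffer after the contact point is placed too
#' deep).
#'
#' @param E numeric, modulus per curve (kPa); \code{NA} pairs dropped.
#' @param h numeric, thickness per curve (nm).
#' @return covariance (kPa nm).
#' @export
covarianceEh <- function(E, h) {
  stopifnot(length(E) == length(h))
  ok <- !is.na(E) & !is.na(h)
  if (sum(ok) < 2L) stop("undefined metric: fewer than 2 valid (E, h) pairs")
  stats::cov(E[ok], h[ok])
}

#' Skewness of the modulus distribution
#'
#' Fisher-Pearson moment coefficient \eqn{g_1 = m_3 / m_2^{3/2}}. A
#' homogeneous gel should give a symmetric (normal) modulus distribution;
#' systematic contact-point misplacement produces the log-normal-like
#' positive skew.
#'
#' @param E numeric, modulus values; \code{NA} dropped.
#' @return dimensionless skewness.
#' @export
skewnessE <- function(E) {
  E <- E[!is.na(E)]
  if (length(E) < 3L) stop("undefined metric: fewer than 3 valid values")
  m <- mean(E)
  m2 <- mean((E - m)^2)
  if (m2 == 0) stop("undefined metric: zero variance")
  mean((E - m)^3) / m2^1.5
}

#' Global strategy-ranking metric
#'
#' Combines the four distribution metrics into
#' \deqn{M = \frac{\sigma^2(E)\,|\sigma(E,h)|\,|s(E)|}{SR}}
#' The numerator collects the quantities a good contact-point strategy
#' should minimise; the success rate, the only quantity to maximise, sits
#' in the denominator. Lower M means better performance. Units are
#' kPa^3 nm.
#'
#' @param varE modulus variance (kPa^2).
#' @param SR success rate in (0, 1].
#' @param covEh modulus-thickness covariance (kPa nm).
#' @param skewE modulus skewness.
#' @return M (kPa^3 nm); \code{Inf} with a warning when \code{SR} is 0.
#' @examples
#' globalMetric(145, 0.87, 13300, -0.51)  # about 1.13e6
#' @export
globalMetric <- function(varE, SR, covEh, skewE) {
  if (is.na(SR) || SR < 0 || SR > 1) stop("SR must be in [0, 1]")
  if (SR == 0) {
    warning("success rate is zero: M is infinite")
    return(Inf)
  }
  varE * abs(covEh) * abs(skewE) / SR
}

#' Assess one strategy over a curve collection
#'
#' Computes the modulus-distribution metrics (mean, variance, success
#' rate, modulus-thickness covariance, skewness) and the global metric M
#' for one detection strategy applied to a collection of curves. All
#' metrics other than the success rate are computed on the identical
#' valid-curve subset; failed curves (NA modulus) only lower the success
#' rate.
#'
#' @param E numeric, modulus per curve (kPa); \code{NA} = failed.
#' @param h numeric, thickness per curve (nm), or \code{NULL} when no
#'   thickness is available (covariance and M become \code{NA}).
#' @param srRange acceptance range \code{c(min, max)} for the success
#'   rate (kPa).
#' @param strategy character(1), label for the report row.
#' @return one-row \code{data.frame} with columns \code{strategy},
#'   \code{nCurves}, \code{meanE}, \code{varE}, \code{SR}, \code{covEh},
#'   \code{skewE}, \code{M}.
#' @export
assessStrategy <- function(E, h = NULL, srRange, strategy = "strategy") {
  valid <- !is.na(E)
  if (sum(valid) < 2L) stop("undefined metrics: fewer than 2 valid curves")
  covEh <- if (!is.null(h)) covarianceEh(E, h) else NA_real_
  varE <- stats::var(E[valid])
  SR <- successRate(E, srRange)
  skew <- skewnessE(E)
  data.frame(strategy = strategy, nCurves = length(E),
             meanE = mean(E[valid]), varE = varE, SR = SR,
             covEh = covEh, skewE = skew,
             M = if (is.na(covEh)) NA_real_
                 else globalMetric(varE, SR, covEh, skew),
             stringsAsFactors = FALSE)
}

#' Rank strategies by the global metric
#'
#' @param results a list of one-row assessment frames (from
#'   [assessStrategy()]) or a single \code{data.frame} with an \code{M}
#'   column.
#' @return \code{data.frame} sorted by increasing M (best first).
#' @export
rankStrategies <- function(results) {
  if (is.data.frame(results)) df <- results
  else df <- do.call(rbind, results)
  if (nrow(df) == 0L) stop("no strategy results to rank")
  df <- df[order(df$M), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a strategy ranking as TSV
#'
#' Columns mirror the standard benchmark layout: mean modulus, variance,
#' success rate, modulus-thickness covariance, skewness, global metric.
#'
#' @param ranking data.frame from [rankStrategies()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published benchmark metrics for contact-point strategies
#'
#' Component metrics reported for five single and three combined
#' sequential-search contact-point strategies, as measured on a published
#' benchmark of more than one thousand force-indentation curves acquired
#' on thin polyacrylamide gels of about 10 kPa with thickness graded
#' between 2 and 8 um. Useful as reference input for the global-metric
#' arithmetic and for comparing rankings.
#'
#' @return \code{data.frame} with columns \code{strategy}, \code{meanE}
#'   (kPa), \code{varE} (kPa^2), \code{SR}, \code{covEh} (kPa nm),
#'   \code{skewE}, \code{M} (kPa^3 nm, as printed in the benchmark).
#' @export
strategyBenchmark <- function() {
  data.frame(
    strategy = c("gof_whole", "gof_low", "rov", "delta_e", "ple",
                 "gof_low*rov", "gof_low*rov*delta_e",
                 "gof_low*rov*delta_e*ple"),
    meanE = c(48.8, 5.53, 10.41, 3.96, 25.4, 7.95, 7.90, 12.2),
    varE = c(145, 61, 170, 118, 158, 38, 46, 165),
    SR = c(0.87, 0.95, 0.99, 0.89, 0.98, 0.97, 0.99, 0.95),
    covEh = c(13300, 727, -4780, -429, 4960, 1020, 825, 2490),
    skewE = c(-0.51, 1.54, 1.78, 1.51, 0.52, 0.98, 0.83, 2.05),
    M = c(1.13e6, 7.12e4, 1.47e6, 8.63e4, 4.14e5, 3.95e4, 3.54e4, 8.89e5),
    stringsAsFactors = FALSE
  )
}
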