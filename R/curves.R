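#' @include AllGenerics.R
NULL

#' Construct a force-displacement curve
#'
#' Builds a validated [ForceCurve-class] from raw piezo displacement and
#' deflection samples. If the record was acquired with Z decreasing
#' towards the sample (approach going "down"), the Z axis (and the glass
#' reference, if given) is sign-inverted so that, internally, approach Z
#' always increases towards the sample.
#'
#' @param Z numeric, piezo displacement samples (nm).
#' @param d numeric, cantilever deflection samples (nm).
#' @param k numeric(1), cantilever spring constant (N/m).
#' @param theta numeric(1), tip half-opening angle (degrees). Default 35,
#'   the nominal value for common pyramidal silicon-nitride probes.
#' @param nu numeric(1), Poisson ratio; 0.5 for incompressible soft
#'   matter.
#' @param Zglass numeric(1), piezo position of contact on bare glass (nm),
#'   in the same frame as \code{Z}; \code{NA} if not recorded.
#' @param label character(1), curve identifier.
#' @return a [ForceCurve-class].
#' @examples
#' Z <- seq(0, 5000, length.out = 64)
#' fc <- forceCurve(Z, numeric(64), k = 0.03)
#' fc
#' @export
forceCurve <- function(Z, d, k, theta = 35, nu = 0.5,
                       Zglass = NA_real_, label = "") {
  Z <- as.numeric(Z); d <- as.numeric(d)
  flipped <- FALSE
  if (length(Z) > 1L && which.max(Z) < which.min(Z)) {
    # approach heads towards smaller Z: flip so that it increases
    Z <- -Z
    if (!is.na(Zglass)) Zglass <- -Zglass
    flipped <- TRUE
  }
  new("ForceCurve", Z = Z, d = d, k = as.numeric(k),
      theta = as.numeric(theta), nu = as.numeric(nu),
      Zglass = as.numeric(Zglass), label = as.character(label),
      flipped = flipped)
}

#' @rdname ForceCurve-accessors
setMethod("piezoZ", "ForceCurve", function(object) object@Z)
#' @rdname ForceCurve-accessors
setMethod("deflection", "ForceCurve", function(object) object@d)
#' @rdname ForceCurve-accessors
setMethod("springConstant", "ForceCurve", function(object) object@k)
#' @rdname ForceCurve-accessors
setMethod("halfAngle", "ForceCurve", function(object) object@theta)
#' @rdname ForceCurve-accessors
setMethod("poissonRatio", "ForceCurve", function(object) object@nu)
#' @rdname ForceCurve-accessors
setMethod("glassPosition", "ForceCurve", function(object) object@Zglass)
#' @rdname ForceCurve-accessors
setMethod("curveLabel", "ForceCurve", function(object) object@label)

setMethod("show", "ForceCurve", function(object) {
  apex <- which.max(object@Z)
  cat("ForceCurve", if (nzchar(object@label)) sQuote(object@label) else "",
      "\n")
  cat(sprintf("  %d samples (%d approach, %d withdraw), Z in [%.1f, %.1f] nm\n",
              length(object@Z), apex, length(object@Z) - apex,
              min(object@Z), max(object@Z)))
  cat(sprintf("  k = %g N/m, theta = %g deg, nu = %g", object@k,
              object@theta, object@nu))
  if (!is.na(object@Zglass))
    cat(sprintf(", Zglass = %.1f nm", object@Zglass))
  cat("\n")
  if (object@flipped)
    cat("  (Z axis flipped on input to normalise the approach direction)\n")
  invisible(NULL)
})

#' @describeIn forceCurve number of samples in the curve.
#' @param x a [ForceCurve-class].
#' @export
setMethod("length", "ForceCurve", function(x) length(x@Z))

#' Split a curve into approach and withdraw segments
#'
#' The split point is the global maximum of Z (closest approach to the
#' sample); ties are resolved to the earliest apex index. The approach
#' segment includes the apex, the withdraw segment is the remainder and
#' may be empty.
#'
#' @param curve a [ForceCurve-class].
#' @return a list with elements \code{approach} and \code{withdraw}, both
#'   [CurveSegment-class] objects.
#' @examples
#' Z <- c(seq(0, 5000, length.out = 32), seq(4900, 100, length.out = 31))
#' seg <- splitApproachWithdraw(forceCurve(Z, numeric(63), k = 0.03))
#' length(seg$approach@indices)
#' @export
splitApproachWithdraw <- function(curve) {
  stopifnot(is(curve, "ForceCurve"))
  apex <- which.max(curve@Z)
  if (apex < 16L)
    stop("degenerate approach segment: fewer than 16 samples before the Z apex")
  n <- length(curve@Z)
  list(
    approach = new("CurveSegment", indices = seq_len(apex),
                   direction = "approach"),
    withdraw = new("CurveSegment",
                   indices = if (apex < n) seq.int(apex + 1L, n) else integer(),
                   direction = "withdraw")
  )
}

# index of the approach apex
.apexIndex <- function(curve) which.max(curve@Z)

#' Convert deflection to force
#'
#' Hooke's law for the cantilever: F = k d. With k in N/m and d in nm the
#' force comes out in nN.
#'
#' @param d numeric, deflection (nm).
#' @param k numeric(1), spring constant (N/m).
#' @return numeric, force (nN).
#' @examples
#' deflectionToForce(100, 0.03)  # 3 nN
#' @export
deflectionToForce <- function(d, k) {
  if (length(k) != 1L || !is.finite(k) || k <= 0)
    stop("spring constant k must be a single positive number")
  k * d
}

#' Indentation relative to a contact point
#'
#' Transforms piezo displacement into sample indentation for the points
#' at and after the contact point on the approach segment:
#' \deqn{\delta_j = (Z_j - Z_{CP}) - (d_j - d_{CP})}
#' so that the tip travel in excess of the cantilever bending is the
#' sample deformation. By construction \eqn{\delta = 0} exactly at the
#' contact point.
#'
#' @param curve a [ForceCurve-class].
#' @param cpIndex integer(1), contact index within the approach segment.
#' @return numeric vector of indentations (nm) for indices
#'   \code{cpIndex:apex} of the curve.
#' @export
indentation <- function(curve, cpIndex) {
  stopifnot(is(curve, "ForceCurve"))
  apex <- .apexIndex(curve)
  cpIndex <- as.integer(cpIndex)
  if (length(cpIndex) != 1L || is.na(cpIndex) || cpIndex < 1L || cpIndex > apex)
    stop("cpIndex must lie inside the approach segment (1..", apex, ")")
  j <- cpIndex:apex
  (curve@Z[j] - curve@Z[cpIndex]) - (curve@d[j] - curve@d[cpIndex])
}

#' Sample thickness from the glass reference
#'
#' The local sample height is the distance between the piezo position at
#' contact on the sample and the piezo position at contact on the bare
#' substrate: \eqn{h = |Z_{CP} - Z_{glass}|}.
#'
#' @param Zcp numeric(1), piezo position at the sample contact point (nm).
#' @param Zglass numeric(1), piezo position at glass contact (nm).
#' @return numeric(1), thickness (nm).
#' @examples
#' sampleHeight(2000, 5000)  # 3000 nm
#' @export
sampleHeight <- function(Zcp, Zglass) {
  if (is.null(Zglass) || length(Zglass) != 1L || is.na(Zglass))
    stop("height unavailable: no glass reference position; supply h directly")
  if (is.null(Zcp) || length(Zcp) != 1L || is.na(Zcp))
    stop("height unavailable: Zcp is missing")
  abs(Zcp - Zglass)
}

## ---- file I/O --------------------------------------------------------

.metaKeys <- c("k", "theta", "nu", "Zglass", "label")

#' Read a force curve from a delimited text file
#'
#' The expected format is two numeric columns named \code{Z} and \code{d}
#' (nm), preceded by optional \code{#}-prefixed metadata header lines of
#' the form \code{# key: value} with keys \code{k}, \code{theta},
#' \code{nu}, \code{Zglass}, \code{label}. Metadata given as arguments
#' (e.g. from a batch-wide sidecar config) complete the header; when a key
#' is present in both, the curve's own header wins. Deflection must already be calibrated to length units.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (tab-separated) or \code{"csv"}.
#' @param k,theta,nu,Zglass,label optional metadata overrides.
#' @return a [ForceCurve-class].
#' @seealso [writeForceCurve()], [readBatch()]
#' @export
readForceCurve <- function(path, dialect = c("tsv", "csv"),
                           k = NULL, theta = NULL, nu = NULL,
                           Zglass = NULL, label = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isMeta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[isMeta]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L && m[2L] %in% .metaKeys)
      meta[[m[2L]]] <- if (m[2L] == "label") trimws(m[3L]) else as.numeric(m[3L])
  }
  body <- lines[!isMeta & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("format error: no data rows in ", path)
  header <- strsplit(body[1L], sep, fixed = TRUE)[[1L]]
  header <- trimws(header)
  for (col in c("Z", "d"))
    if (!col %in% header)
      stop("format error: missing column '", col, "' in ", path)
  fields <- strsplit(body[-1L], sep, fixed = TRUE)
  ncol <- length(header)
  bad <- which(vapply(fields, length, 0L) != ncol)
  if (length(bad))
    stop("parse error at data line ", bad[1L] + 1L, " of ", path,
         ": expected ", ncol, " fields")
  getCol <- function(name) {
    idx <- match(name, header)
    raw <- vapply(fields, `[[`, "", idx)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val))
      stop("parse error at data line ", which(is.na(val))[1L] + 1L, " of ",
           path, ": non-numeric value '", raw[which(is.na(val))[1L]],
           "' in column '", name, "'")
    val
  }
  pick <- function(arg, key, default = NULL) {
    if (!is.null(meta[[key]])) meta[[key]]
    else if (!is.null(arg)) arg
    else default
  }
  kk <- pick(k, "k")
  tt <- pick(theta, "theta")
  if (is.null(kk))
    stop("metadata error: spring constant 'k' missing (header or argument)")
  if (is.null(tt))
    stop("metadata error: half-opening angle 'theta' missing (header or argument)")
  forceCurve(getCol("Z"), getCol("d"), k = kk, theta = tt,
             nu = pick(nu, "nu", 0.5),
             Zglass = pick(Zglass, "Zglass", NA_real_),
             label = pick(label, "label", basename(path)))
}

#' Write a force curve to a delimited text file
#'
#' Writes the metadata header and the Z/d columns at full double
#' precision, so that a read/write round trip is lossless.
#'
#' @param curve a [ForceCurve-class].
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeForceCurve <- function(curve, path, dialect = c("tsv", "csv")) {
  stopifnot(is(curve, "ForceCurve"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# k: %.17g", curve@k),
    sprintf("# theta: %.17g", curve@theta),
    sprintf("# nu: %.17g", curve@nu),
    if (!is.na(curve@Zglass)) sprintf("# Zglass: %.17g", curve@Zglass),
    if (nzchar(curve@label)) paste0("# label: ", curve@label),
    paste("Z", "d", sep = sep)
  ), con)
  writeLines(paste(sprintf("%.17g", curve@Z), sprintf("%.17g", curve@d),
                   sep = sep), con)
  invisible(path)
}

#' Read a directory of force curves
#'
#' Reads every \code{.tsv}/\code{.csv} file in a directory as a force
#' curve. Shared metadata may be supplied in a YAML config file in the
#' same directory (keys \code{k}, \code{theta}, \code{nu}, \code{Zglass});
#' per-file headers take precedence over the config. Unreadable files are
#' skipped with a warning.
#'
#' @param dir directory path.
#' @param config name of the YAML config file inside \code{dir}.
#' @return named list of [ForceCurve-class] objects (possibly empty), with
#'   attribute \code{"skipped"} naming files that failed to parse.
#' @export
readBatch <- function(dir, config = "config.yaml") {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  cfgPath <- file.path(dir, config)
  cfg <- if (file.exists(cfgPath)) yaml::read_yaml(cfgPath) else list()
  files <- sort(list.files(dir, pattern = "\\.(tsv|csv)$", full.names = TRUE))
  files <- files[basename(files) != "truth.tsv"]
  curves <- list()
  skipped <- character()
  for (f in files) {
    dialect <- if (grepl("\\.csv$", f)) "csv" else "tsv"
    fc <- tryCatch(
      readForceCurve(f, dialect = dialect, k = cfg$k, theta = cfg$theta,
                     nu = cfg$nu, Zglass = cfg$Zglass),
      error = function(e) {
        warning("skipping ", basename(f), ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fc)) skipped <- c(skipped, basename(f))
    else curves[[curveLabel(fc)]] <- fc
  }
  structure(curves, skipped = skipped)
}
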