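#' @include profile.R
NULL

#' Muscle-specific shape factor
#'
#' The dimensionless ratio
#' \deqn{p = MV_{slice-by-slice} / (L \times ACSA_{max})}
#' characterizing how much of the bounding cylinder a muscle fills: 1 for a
#' cylinder, 1/3 for a cone, around 0.55-0.65 for human thigh muscles.
#' Since the reference volume can never exceed length times maximal area,
#' \eqn{0 < p \le 1}.
#'
#' @param mvRef slice-by-slice reference volume (mm^3).
#' @param lengthMm muscle length (mm).
#' @param acsaMaxMm2 maximal ACSA (mm^2).
#' @return Shape factor(s); vectorized over equal-length inputs.
#' @examples
#' shapeFactor(992000, 400, 4000)  # 0.62, a typical vastus lateralis
#' @export
shapeFactor <- function(mvRef, lengthMm, acsaMaxMm2) {
  if (any(!is.finite(mvRef)) || any(mvRef <= 0) ||
      any(!is.finite(lengthMm)) || any(lengthMm <= 0) ||
      any(!is.finite(acsaMaxMm2)) || any(acsaMaxMm2 <= 0))
    stop("volume, length and ACSA_max must all be positive")
  mvRef / (lengthMm * acsaMaxMm2)
}

#' Fit a cohort shape-factor model
#'
#' Computes one shape factor per subject from that subject's own reference
#' volume, length and maximal ACSA, and summarizes the cohort: mean and
#' sample SD of p, and the cohort-average relative location of the maximal
#' ACSA. These cohort averages are what the shape-factor method carries
#' into practice for new subjects.
#'
#' @param mvRef numeric vector of reference volumes (mm^3), one per
#'   subject.
#' @param profiles list of [AcsaProfile-class], same length and order.
#' @param subjects optional character subject ids.
#' @param leaveOneOut if TRUE, [estimateShapeFactor()] excludes the target
#'   subject from the cohort averages (requires the subject id at
#'   estimation time). Default FALSE: plain full-cohort averages, the
#'   self-estimation design used when a reference cohort doubles as the
#'   test cohort.
#' @return A [ShapeFactorModel-class].
#' @export
fitShapeFactorModel <- function(mvRef, profiles, subjects = NULL,
                                leaveOneOut = FALSE) {
  n <- length(mvRef)
  if (n < 2L)
    stop("fitting a shape-factor model needs at least 2 subjects")
  if (length(profiles) != n)
    stop("mvRef and profiles must have the same length")
  stopifnot(all(vapply(profiles, is, logical(1L), "AcsaProfile")))
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(n))
  p <- vapply(seq_len(n), function(i)
    shapeFactor(mvRef[i], profiles[[i]]@lengthMm,
                profiles[[i]]@acsaMaxMm2), numeric(1L))
  loc <- vapply(profiles, acsaMaxLocation, numeric(1L))
  new("ShapeFactorModel", subjects = as.character(subjects), p = p,
      locations = loc, pAvg = mean(p), pSd = stats::sd(p),
      avgAcsaMaxLocation = mean(loc), leaveOneOut = leaveOneOut)
}

#' Shape-factor volume estimate
#'
#' The in-practice estimator
#' \deqn{MV = p_{avg} \times L \times ACSA(\bar{x}_{max})}
#' where the ACSA is read off the subject's profile at the cohort-average
#' peak location (not the subject's own peak). With \code{ideal = TRUE} the
#' subject's own maximal ACSA is substituted instead -- the variant whose
#' bias vanishes when p matches, at the cost of having to find the true
#' peak. The \code{pOverride} argument supports the per-subject identity
#' analysis: with the subject's own p and \code{ideal = TRUE} the estimate
#' reconstructs the reference volume exactly.
#'
#' @param model a fitted [ShapeFactorModel-class].
#' @param profile the target subject's [AcsaProfile-class].
#' @param ideal use the subject's own maximal ACSA instead of the area at
#'   the cohort-average location (default FALSE).
#' @param subject subject id, required when the model was fitted with
#'   \code{leaveOneOut = TRUE}.
#' @param pOverride optional shape-factor override (default: the model's
#'   cohort average, or the leave-one-out average).
#' @return Estimated volume in mm^3.
#' @export
setMethod("estimateShapeFactor", signature("ShapeFactorModel", "AcsaProfile"),
  function(model, profile, ideal = FALSE, subject = NULL,
           pOverride = NULL) {
    keep <- rep(TRUE, length(model@p))
    if (model@leaveOneOut) {
      if (is.null(subject))
        stop("a leave-one-out model needs the target subject id")
      keep <- model@subjects != subject
      if (all(keep))
        stop("subject ", subject, " is not part of the fitted cohort")
      if (sum(keep) < 1L)
        stop("leave-one-out requires at least 2 fitted subjects")
    }
    pUse <- if (is.null(pOverride)) mean(model@p[keep]) else pOverride
    loc <- mean(model@locations[keep])
    area <- if (isTRUE(ideal)) profile@acsaMaxMm2 else acsaAt(profile, loc)
    pUse * profile@lengthMm * area
  })

#' Five-slice sampling scheme of the truncated-cone method
#'
#' Builds the five relative sampling positions from the cohort-average
#' peak location \code{avgLocation}: 100% (ACSA_1), halfway between 100%
#' and the peak (ACSA_2), the peak location (ACSA_3), halfway between the
#' peak and 1% (ACSA_4), and 1% (ACSA_5).
#'
#' @param avgLocation cohort-average relative peak location, strictly
#'   between 0.01 and 1.
#' @return A [TruncatedConeSampling-class].
#' @examples
#' samplingPositions(truncatedConePositions(0.61))
#' # 1.000 0.805 0.610 0.310 0.010
#' @export
truncatedConePositions <- function(avgLocation) {
  if (length(avgLocation) != 1L || !is.finite(avgLocation) ||
      avgLocation <= 0.01 || avgLocation >= 1)
    stop("avgLocation must lie strictly between 0.01 and 1")
  new("TruncatedConeSampling",
      positions = c(1, (1 + avgLocation) / 2, avgLocation,
                    (avgLocation + 0.01) / 2, 0.01))
}

#' @describeIn TruncatedConeSampling-class the five relative positions,
#'   proximal (100%) first
#' @param x a TruncatedConeSampling
#' @export
setMethod("samplingPositions", "TruncatedConeSampling",
          function(x) x@positions)

#' Inter-slice distances of a sampling scheme
#'
#' @param sampling a [TruncatedConeSampling-class].
#' @param lengthMm muscle length in mm.
#' @return numeric(4) distances \eqn{d_i = (x_i - x_{i+1}) L} in mm; they
#'   sum to 0.99 L.
#' @export
setMethod("interSliceDistances", "TruncatedConeSampling",
  function(sampling, lengthMm) {
    stopifnot(length(lengthMm) == 1L, lengthMm > 0)
    -diff(sampling@positions) * lengthMm
  })

#' Truncated-cone (frustum) volume estimate
#'
#' Sums four conical-frustum volumes between consecutive sampled
#' cross-sections:
#' \deqn{MV = \sum_{i=1}^{4} \frac{d_i}{3}\left(A_i + A_{i+1} +
#'   \sqrt{A_i A_{i+1}}\right)}
#' with areas read off the 101-point profile by linear interpolation. The
#' frustum quadrature is exact when the equivalent radius varies linearly
#' between samples; the 0-1% slab is not covered, so even a cylinder is
#' estimated at 0.99 of its volume.
#'
#' @param profile an [AcsaProfile-class].
#' @param sampling a [TruncatedConeSampling-class].
#' @return Estimated volume in mm^3.
#' @examples
#' prof <- AcsaProfile(rep(100, 101), lengthMm = 100)
#' estimateTruncatedCone(prof, truncatedConePositions(0.5))  # 9900
#' @export
setMethod("estimateTruncatedCone",
  signature("AcsaProfile", "TruncatedConeSampling"),
  function(profile, sampling) {
    A <- acsaAt(profile, sampling@positions)
    stopifnot(all(A >= 0))
    d <- interSliceDistances(sampling, profile@lengthMm)
    sum(d / 3 * (A[-5L] + A[-1L] + sqrt(A[-5L] * A[-1L])))
  })

#' @describeIn ShapeFactorModel-class per-subject shape factors, named by
#'   subject
#' @param x a ShapeFactorModel
#' @export
setMethod("shapeFactors", "ShapeFactorModel",
          function(x) stats::setNames(x@p, x@subjects))

#' @describeIn ShapeFactorModel-class cohort-average peak location
#' @export
setMethod("acsaMaxLocation", "ShapeFactorModel",
          function(x) x@avgAcsaMaxLocation)

setMethod("show", "ShapeFactorModel", function(object) {
  cat(sprintf(
    "ShapeFactorModel: n = %d, p = %.3f +/- %.3f, ACSA_max at %.1f%% of length%s\n",
    length(object@p), object@pAvg, object@pSd,
    100 * object@avgAcsaMaxLocation,
    if (object@leaveOneOut) " (leave-one-out)" else ""))
})

setMethod("show", "TruncatedConeSampling", function(object) {
  cat("TruncatedConeSampling positions (proximal -> distal): ",
      paste(sprintf("%.3f", object@positions), collapse = ", "), "\n",
      sep = "")
})
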