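#' @import methods
NULL

.PHANTOM_FAMILIES <- c("cylinder", "cone", "frustum", "beta_spindle")
.DISTAL_ENDS <- c("low_index", "high_index")

#' PhantomSpec: analytic description of a synthetic muscle
#'
#' A phantom is a solid of revolution-like body with elliptical
#' cross-sections whose area varies along the long axis according to one of
#' four families: \code{cylinder} (constant area), \code{cone} (apex at the
#' distal end, area proportional to the squared axial coordinate),
#' \code{frustum} (linearly interpolated radius between two end radii) and
#' \code{beta_spindle} (a fusiform, spindle-shaped profile built from a
#' beta-function kernel, tapering to zero at both ends -- the gross shape of
#' the quadriceps and hamstring muscles).
#'
#' For the spindle the area at relative position \eqn{x \in [0,1]} (0 =
#' distal, 1 = proximal) is
#' \deqn{A(x) = A_{max} (x/x_m)^{\alpha-1} ((1-x)/(1-x_m))^{\beta-1}}
#' with \eqn{\alpha = 1 + \kappa x_m}, \eqn{\beta = 1 + \kappa(1-x_m)}, so
#' that the profile attains its maximum \eqn{A_{max}} exactly at the peak
#' location \eqn{x_m}; \eqn{\kappa \ge 0} controls how sharply the muscle
#' tapers (\eqn{\kappa = 0} degenerates to a cylinder).
#'
#' @slot family character, one of \code{"cylinder"}, \code{"cone"},
#'   \code{"frustum"}, \code{"beta_spindle"}.
#' @slot lengthMm positive numeric, muscle length in mm.
#' @slot peakAcsaMm2 positive numeric, maximal cross-sectional area in mm^2.
#'   For the frustum family this is derived from the larger end radius.
#' @slot peakLocation numeric in (0,1), relative location of the maximal
#'   area measured from the distal end (beta_spindle only; fixed at 1 for
#'   cone/frustum-with-growing-radius geometries).
#' @slot sharpness non-negative numeric, the spindle taper exponent
#'   \eqn{\kappa}.
#' @slot aspectRatio positive numeric, ratio of the two ellipse semi-axes of
#'   every cross-section (1 = circular; thigh muscles are closer to 1.5).
#' @slot endRadiiMm numeric(2), distal and proximal equivalent radii in mm
#'   (frustum family only).
#' @seealso [PhantomSpec()], [analyticAcsa()], [analyticVolume()],
#'   [voxelize()]
#' @export
setClass("PhantomSpec",
  representation(
    family = "character",
    lengthMm = "numeric",
    peakAcsaMm2 = "numeric",
    peakLocation = "numeric",
    sharpness = "numeric",
    aspectRatio = "numeric",
    endRadiiMm = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L || !object@family %in% .PHANTOM_FAMILIES)
    msg <- c(msg, sprintf("family must be one of %s",
                          paste(.PHANTOM_FAMILIES, collapse = ", ")))
  if (length(object@lengthMm) != 1L || !is.finite(object@lengthMm) ||
      object@lengthMm <= 0)
    msg <- c(msg, "lengthMm must be a single positive number")
  if (length(object@peakAcsaMm2) != 1L || !is.finite(object@peakAcsaMm2) ||
      object@peakAcsaMm2 <= 0)
    msg <- c(msg, "peakAcsaMm2 must be a single positive number")
  if (length(object@peakLocation) != 1L || !is.finite(object@peakLocation) ||
      object@peakLocation <= 0 || object@peakLocation >= 1)
    msg <- c(msg, "peakLocation must lie strictly inside (0, 1)")
  if (length(object@sharpness) != 1L || !is.finite(object@sharpness) ||
      object@sharpness < 0)
    msg <- c(msg, "sharpness must be a single non-negative number")
  if (length(object@aspectRatio) != 1L || !is.finite(object@aspectRatio) ||
      object@aspectRatio <= 0)
    msg <- c(msg, "aspectRatio must be a single positive number")
  if (identical(object@family, "frustum")) {
    if (length(object@endRadiiMm) != 2L || any(!is.finite(object@endRadiiMm)) ||
        any(object@endRadiiMm < 0) || all(object@endRadiiMm == 0))
      msg <- c(msg, "endRadiiMm must be two non-negative radii, not both zero")
  }
  if (length(msg)) msg else TRUE
})

#' LabelVolume: a 3D integer label map with voxel geometry
#'
#' The raw input of the pipeline: a 3D array of non-negative integer labels
#' (0 = background) as produced by slice-by-slice segmentation of axial MRI,
#' together with the voxel spacing and the physical ordering of the slice
#' axis. Slices are taken along the third array axis; \code{distalEnd}
#' records whether low slice indices are distal (typical inferior-first
#' axial ordering) or proximal.
#'
#' @slot voxels 3D integer array of labels; 0 is background.
#' @slot spacingMm numeric(3) positive voxel spacing (in-plane x, in-plane
#'   y, slice thickness z) in mm.
#' @slot distalEnd \code{"low_index"} or \code{"high_index"}.
#' @seealso [LabelVolume()], [sliceAreas()], [referenceVolume()],
#'   [readLabelVolume()], [writeLabelVolume()]
#' @export
setClass("LabelVolume",
  representation(
    voxels = "array",
    spacingMm = "numeric",
    distalEnd = "character"
  )
)

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
      any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be three positive numbers")
  if (length(object@distalEnd) != 1L || !object@distalEnd %in% .DISTAL_ENDS)
    msg <- c(msg, "distalEnd must be 'low_index' or 'high_index'")
  if (anyNA(object@voxels) || any(object@voxels < 0))
    msg <- c(msg, "voxels must be non-negative and non-missing")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: sampling design for a simulated cohort
#'
#' Describes between-subject variation for a cohort of phantoms: normal
#' distributions for muscle length, peak ACSA and peak location (the latter
#' truncated to [0.05, 0.95] so peaks cannot degenerate onto a muscle end),
#' a common voxel grid and a seed. Given the same seed the generated cohort
#' is bit-identical.
#'
#' @slot nSubjects positive integer.
#' @slot lengthMm numeric(2): mean and SD of muscle length (mm).
#' @slot peakAcsaMm2 numeric(2): mean and SD of peak ACSA (mm^2).
#' @slot peakLocation numeric(2): mean and SD of the relative peak location.
#' @slot voxelSpacingMm numeric(3) positive voxel spacing.
#' @slot seed integer RNG seed.
#' @seealso [CohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    lengthMm = "numeric",
    peakAcsaMm2 = "numeric",
    peakLocation = "numeric",
    voxelSpacingMm = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nSubjects) != 1L || is.na(object@nSubjects) ||
      object@nSubjects < 1L)
    msg <- c(msg, "nSubjects must be a positive integer")
  for (sl in c("lengthMm", "peakAcsaMm2", "peakLocation")) {
    v <- slot(object, sl)
    if (length(v) != 2L || any(!is.finite(v)))
      msg <- c(msg, sprintf("%s must be c(mean, sd)", sl))
    else if (v[2L] < 0)
      msg <- c(msg, sprintf("%s SD must be non-negative", sl))
  }
  if (length(object@lengthMm) == 2L && object@lengthMm[1L] <= 0)
    msg <- c(msg, "mean length must be positive")
  if (length(object@peakAcsaMm2) == 2L && object@peakAcsaMm2[1L] <= 0)
    msg <- c(msg, "mean peak ACSA must be positive")
  if (length(object@voxelSpacingMm) != 3L ||
      any(!is.finite(object@voxelSpacingMm)) ||
      any(object@voxelSpacingMm <= 0))
    msg <- c(msg, "voxelSpacingMm must be three positive numbers")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' RawSliceAreas: per-slice cross-sectional areas of one muscle
#'
#' The pre-normalization carrier between a label map and an [AcsaProfile]:
#' one area per axial slice over the contiguous span of slices the muscle
#' occupies. Gap slices inside the span (segmentation holes) carry area 0.
#'
#' @slot sliceIndex integer vector of slice indices (contiguous span).
#' @slot areaMm2 numeric vector of per-slice areas (mm^2), same length.
#' @slot spacingMm numeric(3) voxel spacing of the source volume.
#' @slot distalEnd slice-axis orientation inherited from the source volume.
#' @seealso [sliceAreas()], [muscleLength()], [resampleProfile()]
#' @export
setClass("RawSliceAreas",
  representation(
    sliceIndex = "integer",
    areaMm2 = "numeric",
    spacingMm = "numeric",
    distalEnd = "character"
  )
)

setValidity("RawSliceAreas", function(object) {
  msg <- character()
  if (length(object@sliceIndex) != length(object@areaMm2))
    msg <- c(msg, "sliceIndex and areaMm2 must have equal length")
  if (length(object@sliceIndex) < 1L)
    msg <- c(msg, "at least one occupied slice is required")
  if (length(object@sliceIndex) > 1L &&
      !all(diff(object@sliceIndex) == 1L))
    msg <- c(msg, "sliceIndex must be a contiguous run")
  if (any(object@areaMm2 < 0))
    msg <- c(msg, "areas must be non-negative")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be three positive numbers")
  if (length(object@distalEnd) != 1L || !object@distalEnd %in% .DISTAL_ENDS)
    msg <- c(msg, "distalEnd must be 'low_index' or 'high_index'")
  if (length(msg)) msg else TRUE
})

#' AcsaProfile: the 101-point ACSA profile over relative muscle length
#'
#' Anatomical cross-sectional areas resampled to one value per 1% of muscle
#' length, on the convention 0% = distal end, 100% = proximal end. Houses
#' the muscle length, the maximal ACSA and its relative location (argmax on
#' the 1% grid; ties resolved to the midpoint of the maximal plateau).
#'
#' @slot values numeric(101), areas in mm^2 at 0%, 1%, ..., 100%.
#' @slot lengthMm positive numeric, muscle length in mm.
#' @slot acsaMaxMm2 maximal area over the grid (mm^2).
#' @slot acsaMaxLocation relative location of the maximum, a multiple of
#'   0.01 in [0, 1].
#' @seealso [resampleProfile()], [findAcsaMax()], [acsaAt()]
#' @export
setClass("AcsaProfile",
  representation(
    values = "numeric",
    lengthMm = "numeric",
    acsaMaxMm2 = "numeric",
    acsaMaxLocation = "numeric"
  )
)

setValidity("AcsaProfile", function(object) {
  msg <- character()
  if (length(object@values) != 101L)
    msg <- c(msg, "values must hold 101 areas (0%..100% in 1% steps)")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "areas must be finite and non-negative")
  if (length(object@lengthMm) != 1L || object@lengthMm <= 0)
    msg <- c(msg, "lengthMm must be a single positive number")
  if (length(object@acsaMaxMm2) != 1L ||
      abs(object@acsaMaxMm2 - max(object@values)) >
        1e-9 * max(1, object@acsaMaxMm2))
    msg <- c(msg, "acsaMaxMm2 must equal max(values)")
  if (length(object@acsaMaxLocation) != 1L ||
      object@acsaMaxLocation < 0 || object@acsaMaxLocation > 1 ||
      abs(object@acsaMaxLocation * 100 -
          round(object@acsaMaxLocation * 100)) > 1e-9)
    msg <- c(msg, "acsaMaxLocation must be a multiple of 0.01 in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ShapeFactorModel: cohort shape factors and average peak location
#'
#' Per-subject shape factors \eqn{p = MV / (L \times ACSA_{max})}, their
#' cohort mean and SD, and the cohort-average relative location of the
#' maximal ACSA. These are the two quantities the shape-factor estimator
#' carries from a reference cohort into practice. An optional leave-one-out
#' mode recomputes the cohort averages excluding the subject being
#' estimated.
#'
#' @slot subjects character subject identifiers.
#' @slot p numeric per-subject shape factors (dimensionless, in (0, 1]).
#' @slot locations numeric per-subject peak locations (fractions).
#' @slot pAvg,pSd cohort mean and sample SD of \code{p}.
#' @slot avgAcsaMaxLocation cohort mean peak location (fraction).
#' @slot leaveOneOut logical; if TRUE, estimation excludes the target
#'   subject from the averages.
#' @seealso [fitShapeFactorModel()], [estimateShapeFactor()]
#' @export
setClass("ShapeFactorModel",
  representation(
    subjects = "character",
    p = "numeric",
    locations = "numeric",
    pAvg = "numeric",
    pSd = "numeric",
    avgAcsaMaxLocation = "numeric",
    leaveOneOut = "logical"
  )
)

setValidity("ShapeFactorModel", function(object) {
  msg <- character()
  n <- length(object@p)
  if (n < 2L)
    msg <- c(msg, "a fitted model needs at least 2 subjects")
  if (length(object@subjects) != n || length(object@locations) != n)
    msg <- c(msg, "subjects, p and locations must have equal length")
  if (any(object@p <= 0) || any(object@p > 1 + 1e-9))
    msg <- c(msg, "shape factors must lie in (0, 1]")
  if (any(object@locations < 0) || any(object@locations > 1))
    msg <- c(msg, "locations must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TruncatedConeSampling: the five sampling positions of the frustum method
#'
#' The truncated-cone estimator samples the ACSA at five relative
#' positions: 100% (ACSA_1, proximal), 1% (ACSA_5, distal), the
#' cohort-average peak location (ACSA_3), and the two positions halfway
#' between the peak location and each end slice (ACSA_2, ACSA_4). Indices
#' descend from proximal to distal. Inter-slice distances are obtained by
#' scaling the position gaps by the muscle length.
#'
#' @slot positions numeric(5), strictly decreasing relative positions with
#'   \code{positions[1] == 1} and \code{positions[5] == 0.01}.
#' @seealso [truncatedConePositions()], [estimateTruncatedCone()]
#' @export
setClass("TruncatedConeSampling",
  representation(positions = "numeric")
)

setValidity("TruncatedConeSampling", function(object) {
  msg <- character()
  x <- object@positions
  if (length(x) != 5L || any(!is.finite(x)))
    msg <- c(msg, "positions must be five finite numbers")
  else {
    if (any(diff(x) >= 0))
      msg <- c(msg, "positions must be strictly decreasing")
    if (abs(x[1L] - 1) > 1e-12 || abs(x[5L] - 0.01) > 1e-12)
      msg <- c(msg, "positions must run from 100% down to 1%")
  }
  if (length(msg)) msg else TRUE
})
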