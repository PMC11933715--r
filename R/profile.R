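#' @include AllGenerics.R
NULL

.REL_GRID <- seq(0, 1, by = 0.01)

## argmax on the 1% grid; exact ties -> midpoint of the maximal run,
## rounded down to the grid (orientation-symmetric for full plateaus)
.gridArgmax <- function(values) {
  m <- max(values)
  idx0 <- which(values == m) - 1L            # 0-based grid indices
  mid <- (min(idx0) + max(idx0)) %/% 2L
  list(area = m, location = mid / 100)
}

.AcsaProfile <- function(values, lengthMm) {
  peak <- .gridArgmax(values)
  new("AcsaProfile", values = as.numeric(values),
      lengthMm = as.numeric(lengthMm),
      acsaMaxMm2 = peak$area, acsaMaxLocation = peak$location)
}

#' Construct an AcsaProfile from 101 area values
#'
#' Mostly used through [resampleProfile()]; exposed for building profiles
#' from analytic areas or externally resampled data.
#'
#' @param values numeric(101), areas in mm^2 at 0%, 1%, ..., 100% of muscle
#'   length (0% = distal).
#' @param lengthMm muscle length in mm.
#' @return An [AcsaProfile-class]; the maximal ACSA and its location are
#'   computed on construction.
#' @export
AcsaProfile <- function(values, lengthMm) .AcsaProfile(values, lengthMm)

#' Per-slice cross-sectional areas of one label
#'
#' Decomposes a label map into per-slice ACSAs: area(i) = labelled-voxel
#' count in slice i times the in-plane voxel area. Only the contiguous span
#' from the first to the last occupied slice is returned; interior empty
#' slices (segmentation holes along the axis) are retained with area 0 and
#' flagged with a warning.
#'
#' @param vol a [LabelVolume-class].
#' @param label integer label to measure; must be present.
#' @return A [RawSliceAreas-class].
#' @export
setMethod("sliceAreas", "LabelVolume", function(vol, label) {
  stopifnot(length(label) == 1L)
  label <- as.integer(label)
  d <- dim(vol@voxels)
  counts <- colSums(matrix(vol@voxels == label, ncol = d[3L]))
  occ <- which(counts > 0)
  if (!length(occ))
    stop("label ", label, " is absent from the volume")
  span <- occ[1L]:occ[length(occ)]
  if (any(counts[span] == 0))
    warning(sprintf(
      "label %d occupies a non-contiguous slice range; %d gap slice(s) kept with area 0",
      label, sum(counts[span] == 0)))
  inPlane <- vol@spacingMm[1L] * vol@spacingMm[2L]
  new("RawSliceAreas", sliceIndex = as.integer(span),
      areaMm2 = counts[span] * inPlane,
      spacingMm = vol@spacingMm, distalEnd = vol@distalEnd)
})

#' Muscle length from occupied slices
#'
#' Length = number of slices in the occupied span times the slice
#' thickness: each slice stands for a full slab, which keeps length
#' consistent with volume = sum(area x dz) bookkeeping.
#'
#' @param x a [RawSliceAreas-class].
#' @return Length in mm.
#' @examples
#' raw <- new("RawSliceAreas", sliceIndex = 10:59,
#'            areaMm2 = rep(100, 50), spacingMm = c(1, 1, 2),
#'            distalEnd = "low_index")
#' muscleLength(raw)  # 100
#' @export
setMethod("muscleLength", "RawSliceAreas", function(x)
  length(x@sliceIndex) * x@spacingMm[3L])

#' Resample per-slice areas to the 101-point relative-length profile
#'
#' Maps slice centers to relative positions \eqn{x_i = (i - 0.5)/N} over
#' the occupied span of \eqn{N} slices and linearly interpolates onto the
#' 1% grid (0%, 1%, ..., 100%), with constant extrapolation beyond the
#' outermost slice centers. When the distal end is at high slice indices
#' the areas are flipped first, so 0% is always distal.
#'
#' @param raw a [RawSliceAreas-class] with at least two slices.
#' @return An [AcsaProfile-class].
#' @export
setMethod("resampleProfile", "RawSliceAreas", function(raw) {
  n <- length(raw@areaMm2)
  if (n < 2L)
    stop("resampling needs at least 2 occupied slices")
  areas <- raw@areaMm2
  if (identical(raw@distalEnd, "high_index")) areas <- rev(areas)
  centers <- (seq_len(n) - 0.5) / n
  vals <- stats::approx(centers, areas, xout = .REL_GRID, rule = 2)$y
  .AcsaProfile(vals, muscleLength(raw))
})

#' Maximal ACSA and its relative location
#'
#' Returns the maximum of the 101-point profile and its location on the 1%
#' grid. Exact ties (flat plateaus) resolve to the plateau midpoint,
#' rounded down to the grid, so a constant profile reports 50%.
#'
#' @param profile an [AcsaProfile-class].
#' @return A list with \code{acsaMaxMm2} and \code{location} (fraction of
#'   muscle length, distal = 0).
#' @export
setMethod("findAcsaMax", "AcsaProfile", function(profile)
  list(acsaMaxMm2 = profile@acsaMaxMm2,
       location = profile@acsaMaxLocation))

#' ACSA at an arbitrary relative position
#'
#' Linear interpolation of the 101-point profile at relative position
#' \code{x} (0 = distal, 1 = proximal).
#'
#' @param profile an [AcsaProfile-class].
#' @param x relative position(s) in [0, 1]; vectorized.
#' @return Area(s) in mm^2.
#' @export
setMethod("acsaAt", "AcsaProfile", function(profile, x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("relative position x must lie in [0, 1]")
  stats::approx(.REL_GRID, profile@values, xout = x)$y
})

#' Slice-by-slice reference volume of a label
#'
#' Total labelled-voxel count times the voxel volume -- the reference
#' method. Identical, by construction, to the sum over slices of
#' area x slice thickness.
#'
#' @param vol a [LabelVolume-class].
#' @param label integer label; must be present.
#' @return Volume in mm^3.
#' @export
setMethod("referenceVolume", "LabelVolume", function(vol, label) {
  stopifnot(length(label) == 1L)
  cnt <- sum(vol@voxels == as.integer(label))
  if (cnt == 0)
    stop("label ", label, " is absent from the volume")
  cnt * prod(vol@spacingMm)
})

#' Export an ACSA profile as CSV
#'
#' Writes the 101-point profile with columns \code{relative_position_pct}
#' and \code{acsa_mm2}.
#'
#' @param profile an [AcsaProfile-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportAcsaProfile <- function(profile, path) {
  stopifnot(is(profile, "AcsaProfile"))
  utils::write.csv(
    data.frame(relative_position_pct = 100 * .REL_GRID,
               acsa_mm2 = profile@values),
    path, row.names = FALSE)
  invisible(path)
}

#' @describeIn AcsaProfile-class the 101 area values (mm^2)
#' @param x an AcsaProfile
#' @export
setMethod("profileValues", "AcsaProfile", function(x) x@values)

#' @describeIn AcsaProfile-class muscle length in mm
#' @export
setMethod("muscleLength", "AcsaProfile", function(x) x@lengthMm)

#' @describeIn AcsaProfile-class maximal ACSA (mm^2)
#' @export
setMethod("acsaMax", "AcsaProfile", function(x) x@acsaMaxMm2)

#' @describeIn AcsaProfile-class relative location of the maximal ACSA
#' @export
setMethod("acsaMaxLocation", "AcsaProfile", function(x) x@acsaMaxLocation)

setMethod("show", "AcsaProfile", function(object) {
  cat(sprintf(
    "AcsaProfile: L = %.1f mm, ACSA_max = %.1f mm^2 at %.0f%% of length\n",
    object@lengthMm, object@acsaMaxMm2, 100 * object@acsaMaxLocation))
})

setMethod("show", "RawSliceAreas", function(object) {
  cat(sprintf(
    "RawSliceAreas: slices %d..%d (dz = %g mm), peak slice area %.1f mm^2\n",
    min(object@sliceIndex), max(object@sliceIndex),
    object@spacingMm[3L], max(object@areaMm2)))
})
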