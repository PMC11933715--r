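#' @include AllGenerics.R
NULL

#' Construct a PhantomSpec
#'
#' @param family one of \code{"cylinder"}, \code{"cone"}, \code{"frustum"},
#'   \code{"beta_spindle"}.
#' @param lengthMm muscle length in mm.
#' @param peakAcsaMm2 maximal cross-sectional area in mm^2. Ignored for the
#'   frustum family, where it is derived from the larger end radius.
#' @param peakLocation relative location of the maximal area, in (0,1),
#'   measured from the distal end. Only the beta_spindle profile shape
#'   depends on it.
#' @param sharpness spindle taper exponent kappa (>= 0); 0 degenerates to a
#'   cylinder. Default 3 gives shape factors near 0.58 at thigh-muscle peak
#'   locations, in the range observed for quadriceps muscles in vivo.
#' @param aspectRatio ellipse semi-axis ratio of the cross-sections;
#'   default 1.5 (muscle bellies are not circular).
#' @param endRadiiMm numeric(2), distal and proximal equivalent radii (mm),
#'   frustum family only.
#' @return A [PhantomSpec-class] object.
#' @examples
#' PhantomSpec("beta_spindle", lengthMm = 300, peakAcsaMm2 = 2000,
#'             peakLocation = 0.61)
#' @export
PhantomSpec <- function(family, lengthMm, peakAcsaMm2 = NULL,
                        peakLocation = 0.5, sharpness = 3,
                        aspectRatio = 1.5, endRadiiMm = numeric()) {
  family <- match.arg(family, .PHANTOM_FAMILIES)
  if (identical(family, "frustum")) {
    if (length(endRadiiMm) != 2L)
      stop("frustum phantoms need endRadiiMm = c(distal, proximal)")
    peakAcsaMm2 <- pi * max(endRadiiMm)^2
  }
  if (is.null(peakAcsaMm2))
    stop("peakAcsaMm2 is required for ", family, " phantoms")
  new("PhantomSpec", family = family, lengthMm = as.numeric(lengthMm),
      peakAcsaMm2 = as.numeric(peakAcsaMm2),
      peakLocation = as.numeric(peakLocation),
      sharpness = as.numeric(sharpness),
      aspectRatio = as.numeric(aspectRatio),
      endRadiiMm = as.numeric(endRadiiMm))
}

#' Construct a CohortSpec
#'
#' @param nSubjects number of subjects to simulate.
#' @param lengthMm numeric(2): mean and SD of muscle length (mm).
#' @param peakAcsaMm2 numeric(2): mean and SD of peak ACSA (mm^2).
#' @param peakLocation numeric(2): mean and SD of the relative peak
#'   location; draws are truncated to [0.05, 0.95].
#' @param voxelSpacingMm numeric(3) voxel spacing; the default
#'   c(0.65, 0.65, 2) reproduces a typical reconstructed axial MRI grid.
#' @param seed RNG seed; the same seed yields a bit-identical cohort.
#' @return A [CohortSpec-class] object.
#' @examples
#' CohortSpec(5, lengthMm = c(300, 20), peakAcsaMm2 = c(2500, 300),
#'            peakLocation = c(0.61, 0.10), seed = 7)
#' @export
CohortSpec <- function(nSubjects, lengthMm, peakAcsaMm2, peakLocation,
                       voxelSpacingMm = c(0.65, 0.65, 2), seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      lengthMm = as.numeric(lengthMm),
      peakAcsaMm2 = as.numeric(peakAcsaMm2),
      peakLocation = as.numeric(peakLocation),
      voxelSpacingMm = as.numeric(voxelSpacingMm),
      seed = as.integer(seed))
}

#' Construct a LabelVolume
#'
#' @param voxels 3D array of non-negative integer labels (0 = background);
#'   the slice axis is the third array axis.
#' @param spacingMm numeric(3) positive voxel spacing in mm.
#' @param distalEnd whether low slice indices are the distal end
#'   (\code{"low_index"}, default) or the proximal end
#'   (\code{"high_index"}).
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(voxels, spacingMm, distalEnd = "low_index") {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, spacingMm = as.numeric(spacingMm),
      distalEnd = match.arg(distalEnd, .DISTAL_ENDS))
}

## beta-spindle kernel, safe at the endpoints (0^0 == 1 when kappa == 0)
.spindleKernel <- function(x, xm, kappa) {
  a1 <- kappa * xm          # alpha - 1
  b1 <- kappa * (1 - xm)    # beta - 1
  k <- numeric(length(x))
  inner <- x > 0 & x < 1
  k[inner] <- exp(a1 * (log(x[inner]) - log(xm)) +
                  b1 * (log1p(-x[inner]) - log1p(-xm)))
  k[x == 0] <- if (a1 == 0) (1 - 0)^b1 / (1 - xm)^b1 else 0
  k[x == 1] <- if (b1 == 0) 1 / xm^a1 else 0
  k
}

#' Analytic ACSA of a phantom at a relative position
#'
#' Closed-form cross-sectional area of a phantom at relative position
#' \code{x} along the long axis (0 = distal end, 1 = proximal end).
#'
#' @param spec a [PhantomSpec-class].
#' @param x relative position(s) in [0, 1]; vectorized.
#' @return Area(s) in mm^2.
#' @examples
#' sp <- PhantomSpec("beta_spindle", 300, 100, peakLocation = 0.5,
#'                   sharpness = 2)
#' analyticAcsa(sp, c(0.25, 0.5))  # 75, 100
#' @export
setMethod("analyticAcsa", "PhantomSpec", function(spec, x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("relative position x must lie in [0, 1]")
  switch(spec@family,
    cylinder = rep(spec@peakAcsaMm2, length(x)),
    cone = spec@peakAcsaMm2 * x^2,
    frustum = {
      r <- spec@endRadiiMm[1L] + diff(spec@endRadiiMm) * x
      pi * r^2
    },
    beta_spindle = spec@peakAcsaMm2 *
      .spindleKernel(x, spec@peakLocation, spec@sharpness)
  )
})

#' Analytic volume of a phantom
#'
#' Closed-form volume \eqn{V = L \int_0^1 A(x)\,dx}: \eqn{A L} for the
#' cylinder, \eqn{A_{max} L / 3} for the cone,
#' \eqn{\pi L (r_0^2 + r_0 r_1 + r_1^2)/3} for the frustum, and
#' \eqn{A_{max} L\, B(\alpha,\beta) / (x_m^{\alpha-1} (1-x_m)^{\beta-1})}
#' for the beta spindle. Each closed form agrees with adaptive quadrature of
#' [analyticAcsa()] to better than 1e-8 relative tolerance.
#'
#' @param spec a [PhantomSpec-class].
#' @return Volume in mm^3.
#' @examples
#' analyticVolume(PhantomSpec("cone", 100, 300))  # 10000
#' @export
setMethod("analyticVolume", "PhantomSpec", function(spec) {
  L <- spec@lengthMm
  A <- spec@peakAcsaMm2
  switch(spec@family,
    cylinder = A * L,
    cone = A * L / 3,
    frustum = {
      r <- spec@endRadiiMm
      pi * L * (r[1L]^2 + r[1L] * r[2L] + r[2L]^2) / 3
    },
    beta_spindle = {
      xm <- spec@peakLocation
      al <- 1 + spec@sharpness * xm
      be <- 1 + spec@sharpness * (1 - xm)
      A * L * exp(lbeta(al, be) - (al - 1) * log(xm) -
                  (be - 1) * log1p(-xm))
    }
  )
})

#' Voxelize a phantom onto an anisotropic grid
#'
#' Rasterizes the phantom into a binary label map: slices are taken along
#' the third axis; a voxel is labelled 1 iff its in-plane center lies inside
#' the elliptical cross-section evaluated at the slice-center's axial
#' coordinate (center-inclusion, no partial-volume weighting -- the way a
#' binary segmentation behaves). Cross-section semi-axes are solved from
#' the analytic area and the aspect ratio:
#' \eqn{a = \sqrt{A\,r/\pi}}, \eqn{b = \sqrt{A/(\pi r)}}.
#'
#' @param spec a [PhantomSpec-class].
#' @param spacingMm numeric(3) positive voxel spacing (mm).
#' @param distalEnd which slice-index end is distal; default
#'   \code{"low_index"}.
#' @param maxVoxels guard against accidentally huge grids (default 2^27,
#'   about 134 million voxels).
#' @return A [LabelVolume-class] with labels in \{0, 1\}.
#' @examples
#' sp <- PhantomSpec("cylinder", 20, pi * 100, aspectRatio = 1)
#' vol <- voxelize(sp, c(1, 1, 2))
#' referenceVolume(vol, 1L) / analyticVolume(sp)
#' @export
setMethod("voxelize", "PhantomSpec",
  function(spec, spacingMm, distalEnd = "low_index", maxVoxels = 2^27) {
    stopifnot(length(spacingMm) == 3L, all(spacingMm > 0))
    distalEnd <- match.arg(distalEnd, .DISTAL_ENDS)
    maxArea <- spec@peakAcsaMm2
    aMax <- sqrt(maxArea * spec@aspectRatio / pi)
    bMax <- sqrt(maxArea / (pi * spec@aspectRatio))
    nx <- 2L * as.integer(ceiling(aMax / spacingMm[1L])) + 3L
    ny <- 2L * as.integer(ceiling(bMax / spacingMm[2L])) + 3L
    nz <- as.integer(ceiling(spec@lengthMm / spacingMm[3L]))
    if (as.double(nx) * ny * nz > maxVoxels)
      stop(sprintf("grid %d x %d x %d exceeds maxVoxels = %g",
                   nx, ny, nz, maxVoxels))
    xc2 <- ((seq_len(nx) - (nx + 1) / 2) * spacingMm[1L])^2
    yc2 <- ((seq_len(ny) - (ny + 1) / 2) * spacingMm[2L])^2
    vox <- array(0L, dim = c(nx, ny, nz))
    zc <- (seq_len(nz) - 0.5) * spacingMm[3L]
    rel <- zc / spec@lengthMm
    if (identical(distalEnd, "high_index")) rel <- 1 - rel
    ok <- rel >= 0 & rel <= 1
    areas <- numeric(nz)
    areas[ok] <- analyticAcsa(spec, rel[ok])
    for (k in which(areas > 0)) {
      a2 <- areas[k] * spec@aspectRatio / pi
      b2 <- areas[k] / (pi * spec@aspectRatio)
      inside <- outer(xc2 / a2, yc2 / b2, `+`) <= 1
      if (any(inside)) vox[, , k][inside] <- 1L
    }
    LabelVolume(vox, spacingMm, distalEnd)
  })

## truncated-normal draw by rejection; deterministic given the RNG state
.rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate draw (SD = 0) falls outside the truncation bounds")
    return(mean)
  }
  repeat {
    v <- stats::rnorm(1L, mean, sd)
    if (v >= lower && v <= upper) return(v)
  }
}

#' Simulate a cohort of voxelized phantoms with ground truth
#'
#' Draws per-subject muscle length, peak ACSA and peak location from the
#' cohort distributions (peak location truncated to [0.05, 0.95]; length
#' and area truncated to positive values), builds one phantom per subject
#' from the template (family, sharpness and aspect ratio are shared), and
#' voxelizes each on the cohort grid. Given the same seed the result is
#' bit-identical; the caller's RNG state is left untouched.
#'
#' @param cohort a [CohortSpec-class].
#' @param template a [PhantomSpec-class] supplying family, sharpness and
#'   aspect ratio (its length/area/location are replaced per subject).
#' @param distalEnd slice ordering for the voxelized maps.
#' @param maxVoxels per-subject grid guard, passed to [voxelize()].
#' @return A list with \code{volumes} (list of [LabelVolume-class]) and
#'   \code{truth}, a data.frame with one row per subject: subject_id,
#'   family, length_mm, peak_acsa_mm2, peak_location, analytic_volume_mm3,
#'   seed.
#' @examples
#' cs <- CohortSpec(2, c(120, 10), c(900, 50), c(0.5, 0.05),
#'                  voxelSpacingMm = c(2, 2, 4), seed = 7)
#' tmpl <- PhantomSpec("beta_spindle", 1, 1)
#' coh <- generateCohort(cs, tmpl)
#' coh$truth
#' @export
setMethod("generateCohort", signature("CohortSpec", "PhantomSpec"),
  function(cohort, template, distalEnd = "low_index", maxVoxels = 2^27) {
    validObject(cohort)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(oldSeed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", oldSeed, envir = globalenv())
    })
    set.seed(cohort@seed)
    n <- cohort@nSubjects
    len <- acsa <- loc <- numeric(n)
    for (i in seq_len(n)) {
      len[i] <- .rtruncnorm1(cohort@lengthMm[1L], cohort@lengthMm[2L],
                             lower = .Machine$double.eps)
      acsa[i] <- .rtruncnorm1(cohort@peakAcsaMm2[1L], cohort@peakAcsaMm2[2L],
                              lower = .Machine$double.eps)
      loc[i] <- .rtruncnorm1(cohort@peakLocation[1L], cohort@peakLocation[2L],
                             lower = 0.05, upper = 0.95)
    }
    volumes <- vector("list", n)
    truth <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      family = template@family,
      length_mm = len, peak_acsa_mm2 = acsa, peak_location = loc,
      analytic_volume_mm3 = NA_real_, seed = cohort@seed,
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n)) {
      sp <- PhantomSpec(template@family, lengthMm = len[i],
                        peakAcsaMm2 = acsa[i], peakLocation = loc[i],
                        sharpness = template@sharpness,
                        aspectRatio = template@aspectRatio)
      truth$analytic_volume_mm3[i] <- analyticVolume(sp)
      volumes[[i]] <- voxelize(sp, cohort@voxelSpacingMm,
                               distalEnd = distalEnd, maxVoxels = maxVoxels)
    }
    names(volumes) <- truth$subject_id
    list(volumes = volumes, truth = truth)
  })

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s, L = %.1f mm, peak ACSA = %.1f mm^2\n",
              object@family, object@lengthMm, object@peakAcsaMm2))
  if (identical(object@family, "beta_spindle"))
    cat(sprintf("  peak at %.0f%% of length, sharpness = %.2f\n",
                100 * object@peakLocation, object@sharpness))
  if (identical(object@family, "frustum"))
    cat(sprintf("  end radii %.1f / %.1f mm\n",
                object@endRadiiMm[1L], object@endRadiiMm[2L]))
  cat(sprintf("  aspect ratio %.2f, analytic volume %.0f mm^3\n",
              object@aspectRatio, analyticVolume(object)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels at (%g, %g, %g) mm\n",
              d[1L], d[2L], d[3L], object@spacingMm[1L],
              object@spacingMm[2L], object@spacingMm[3L]))
  labs <- setdiff(sort(unique(as.vector(object@voxels))), 0L)
  cat(sprintf("  labels: %s; distal end: %s\n",
              if (length(labs)) paste(labs, collapse = ", ") else "(none)",
              object@distalEnd))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: n = %d, seed = %d\n  length %.0f +/- %.0f mm, peak ACSA %.0f +/- %.0f mm^2, location %.2f +/- %.2f\n",
    object@nSubjects, object@seed,
    object@lengthMm[1L], object@lengthMm[2L],
    object@peakAcsaMm2[1L], object@peakAcsaMm2[2L],
    object@peakLocation[1L], object@peakLocation[2L]))
})

#' @describeIn LabelVolume-class voxel spacing in mm
#' @param x a LabelVolume
#' @export
setMethod("spacingMm", "LabelVolume", function(x) x@spacingMm)

#' @describeIn LabelVolume-class slice-axis orientation
#' @export
setMethod("distalEnd", "LabelVolume", function(x) x@distalEnd)

#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@voxels))
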