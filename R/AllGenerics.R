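#' @include AllClasses.R
NULL

#' @export
setGeneric("analyticAcsa", function(spec, x) standardGeneric("analyticAcsa"))

#' @export
setGeneric("analyticVolume", function(spec) standardGeneric("analyticVolume"))

#' @export
setGeneric("voxelize", function(spec, spacingMm,
                                distalEnd = "low_index", ...)
  standardGeneric("voxelize"))

#' @export
setGeneric("generateCohort", function(cohort, template, ...)
  standardGeneric("generateCohort"))

#' @export
setGeneric("sliceAreas", function(vol, label, ...)
  standardGeneric("sliceAreas"))

#' @export
setGeneric("muscleLength", function(x) standardGeneric("muscleLength"))

#' @export
setGeneric("resampleProfile", function(raw) standardGeneric("resampleProfile"))

#' @export
setGeneric("findAcsaMax", function(profile) standardGeneric("findAcsaMax"))

#' @export
setGeneric("acsaAt", function(profile, x) standardGeneric("acsaAt"))

#' @export
setGeneric("referenceVolume", function(vol, label, ...)
  standardGeneric("referenceVolume"))

#' @export
setGeneric("estimateShapeFactor", function(model, profile, ...)
  standardGeneric("estimateShapeFactor"))

#' @export
setGeneric("estimateTruncatedCone", function(profile, sampling)
  standardGeneric("estimateTruncatedCone"))

#' @export
setGeneric("interSliceDistances", function(sampling, lengthMm)
  standardGeneric("interSliceDistances"))

#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @export
setGeneric("distalEnd", function(x) standardGeneric("distalEnd"))

#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @export
setGeneric("acsaMax", function(x) standardGeneric("acsaMax"))

#' @export
setGeneric("acsaMaxLocation", function(x) standardGeneric("acsaMaxLocation"))

#' @export
setGeneric("shapeFactors", function(x) standardGeneric("shapeFactors"))

#' @export
setGeneric("samplingPositions", function(x)
  standardGeneric("samplingPositions"))
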