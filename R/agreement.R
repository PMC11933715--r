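#' @include AllGenerics.R
NULL

#' Relative difference between reference and estimated volumes
#'
#' Bland-Altman relative difference in percent,
#' \deqn{100 (MV_{ref} - MV_{est}) / \frac{MV_{ref} + MV_{est}}{2}}
#' by default against the mean of the two methods (the classical choice
#' for ratio-scale data); positive values mean the estimator
#' underestimates. Set \code{denominator = "reference"} to divide by the
#' reference volume instead; with differences around 10% the two
#' conventions differ by under one percentage point.
#'
#' @param mvRef reference volume(s), mm^3, positive.
#' @param mvEst estimated volume(s), mm^3, positive.
#' @param denominator \code{"mean"} (default) or \code{"reference"}.
#' @return Relative difference(s) in percent.
#' @examples
#' relativeDifference(1100, 900)  # 20
#' @export
relativeDifference <- function(mvRef, mvEst, denominator = c("mean", "reference")) {
  denominator <- match.arg(denominator)
  if (any(!is.finite(mvRef)) || any(mvRef <= 0) ||
      any(!is.finite(mvEst)) || any(mvEst <= 0))
    stop("volumes must be positive")
  den <- switch(denominator, mean = (mvRef + mvEst) / 2, reference = mvRef)
  100 * (mvRef - mvEst) / den
}

#' Bland-Altman summary of paired relative differences
#'
#' Bias (mean difference), sample SD (n - 1 denominator) and the classical
#' fixed limits of agreement at bias +/- 1.96 SD.
#'
#' @param differences numeric vector of per-subject relative differences
#'   (percent), length >= 2.
#' @param label optional method/muscle label for the output row.
#' @return One-row data.frame: \code{label}, \code{n}, \code{bias_pct},
#'   \code{sd_pct}, \code{lloa_pct}, \code{uloa_pct}.
#' @examples
#' blandAltman(c(0, 10, 20))  # bias 10, SD 10, limits -9.6 / 29.6
#' @export
blandAltman <- function(differences, label = NA_character_) {
  if (length(differences) < 2L)
    stop("Bland-Altman limits need at least 2 paired differences")
  if (any(!is.finite(differences)))
    stop("differences must be finite")
  bias <- mean(differences)
  s <- stats::sd(differences)
  data.frame(label = label, n = length(differences), bias_pct = bias,
             sd_pct = s, lloa_pct = bias - 1.96 * s,
             uloa_pct = bias + 1.96 * s, stringsAsFactors = FALSE)
}

#' Cohort summary table of muscle parameters
#'
#' Mean and SD per muscle of the slice-by-slice volume, muscle length,
#' maximal ACSA, its relative location (in percent of muscle length) and
#' the shape factor.
#'
#' @param results data.frame with one row per subject-muscle and columns
#'   \code{muscle}, \code{mv_ref_mm3}, \code{length_mm},
#'   \code{acsa_max_mm2}, \code{acsa_max_location_pct}, \code{p}.
#' @return data.frame with one row per muscle: n, then mean and SD columns
#'   for each parameter.
#' @export
cohortSummary <- function(results) {
  needed <- c("muscle", "mv_ref_mm3", "length_mm", "acsa_max_mm2",
              "acsa_max_location_pct", "p")
  if (!all(needed %in% names(results)))
    stop("results must have columns: ", paste(needed, collapse = ", "))
  if (nrow(results) < 2L)
    stop("cohort summaries need at least 2 subjects")
  vars <- needed[-1L]
  out <- do.call(rbind, lapply(split(results, results$muscle), function(g) {
    row <- data.frame(muscle = g$muscle[1L], n = nrow(g),
                      stringsAsFactors = FALSE)
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(g[[v]])
      row[[paste0(v, "_sd")]] <- if (nrow(g) > 1L) stats::sd(g[[v]]) else 0
    }
    row
  }))
  rownames(out) <- NULL
  out
}
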