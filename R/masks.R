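# Reference-region and analysis-mask construction and SUVR normalization.
# All three white-matter reference criteria use strict inequalities as
# conventionally printed (> 0.9, < 0.05, < 0.05); boundary voxels are
# measure-zero on continuous probability maps.

checkProbabilityVolume <- function(vol, what) {
  v <- vol@values
  if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 1))
    stop(what, " probabilities must lie in [0, 1]")
  invisible(TRUE)
}

#' White-matter reference-region mask
#'
#' A voxel belongs to the reference region iff its white-matter
#' probability exceeds 0.9 and both the 8 mm-smoothed gray-matter and
#' 8 mm-smoothed CSF probabilities fall below 0.05 — a conservative core
#' of tissue essentially devoid of gray matter and CSF partial volume,
#' suitable as a PET normalization reference.
#'
#' @param wmProb,gmProb,csfProb compatible probability [Volume3D]s in
#'   \[0, 1\].
#' @param smoothFwhmMm FWHM of the smoothing applied to the GM and CSF
#'   probabilities before thresholding (default 8 mm).
#' @param wmMin,partialMax thresholds (defaults 0.9 and 0.05).
#' @return a nonempty [BrainMask].
#' @export
whiteMatterReferenceMask <- function(wmProb, gmProb, csfProb,
                                     smoothFwhmMm = 8, wmMin = 0.9,
                                     partialMax = 0.05) {
  checkGridCompatibility(list(wmProb, gmProb, csfProb))
  checkProbabilityVolume(wmProb, "WM")
  checkProbabilityVolume(gmProb, "GM")
  checkProbabilityVolume(csfProb, "CSF")
  gmS <- gaussianSmooth(gmProb, smoothFwhmMm)@values
  csfS <- gaussianSmooth(csfProb, smoothFwhmMm)@values
  member <- wmProb@values > wmMin & gmS < partialMax & csfS < partialMax
  member[is.na(member)] <- FALSE
  if (!any(member))
    stop("white-matter reference mask is empty under the given criteria")
  new("BrainMask", grid = wmProb@grid, membership = member)
}

#' Gray-matter analysis mask
#'
#' Membership iff the gray-matter probability strictly exceeds the
#' threshold (default 10%).
#'
#' @param gmProb probability [Volume3D] in \[0, 1\].
#' @param threshold numeric(1), default 0.10.
#' @return a nonempty [BrainMask].
#' @export
grayMatterMask <- function(gmProb, threshold = 0.10) {
  checkProbabilityVolume(gmProb, "GM")
  member <- gmProb@values > threshold
  member[is.na(member)] <- FALSE
  if (!any(member)) stop("gray-matter mask is empty at threshold ", threshold)
  new("BrainMask", grid = gmProb@grid, membership = member)
}

#' Standardized uptake value ratio (SUVR) normalization
#'
#' Divides every voxel of a summed-uptake PET volume by the mean uptake
#' within the reference region, recording that mean.
#'
#' @param petSummed a [Volume3D] of summed uptake.
#' @param reference a nonempty [BrainMask] (e.g. from
#'   [whiteMatterReferenceMask()]) on the same grid.
#' @return a [SuvrMap].
#' @export
computeSuvr <- function(petSummed, reference) {
  stopifnot(is(petSummed, "Volume3D"), is(reference, "BrainMask"))
  checkGridCompatibility(list(petSummed, reference))
  if (!any(reference@membership)) stop("reference mask is empty")
  refVals <- petSummed@values[reference@membership]
  refMean <- mean(refVals, na.rm = TRUE)
  if (!is.finite(refMean) || refMean <= 0)
    stop("reference-region mean must be positive, got ", refMean)
  new("SuvrMap", grid = petSummed@grid, values = petSummed@values / refMean,
      referenceMean = refMean)
}

#' Restrict a SUVR map to gray matter and supra-unity values
#'
#' Values are retained only at voxels inside the gray-matter mask whose
#' SUVR strictly exceeds `minValue` (default 1: at or below the
#' white-matter reference level the tracer signal is treated as
#' nonspecific); all other voxels become missing.
#'
#' @param suvr a [SuvrMap].
#' @param gm a [BrainMask] on the same grid.
#' @param minValue retention threshold (default 1.0, strict).
#' @return a [SuvrMap] with missing values outside the retained domain.
#' @export
thresholdSuvr <- function(suvr, gm, minValue = 1.0) {
  stopifnot(is(suvr, "SuvrMap"), is(gm, "BrainMask"))
  checkGridCompatibility(list(suvr, gm))
  if (!any(gm@membership)) stop("gray-matter mask is empty")
  keep <- gm@membership & !is.na(suvr@values) & suvr@values > minValue
  if (!any(keep))
    stop("no voxel survives the SUVR > ", minValue, " restriction")
  vals <- suvr@values
  vals[!keep] <- NA_real_
  new("SuvrMap", grid = suvr@grid, values = vals,
      referenceMean = suvr@referenceMean)
}
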