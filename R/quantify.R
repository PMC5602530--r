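## Per-case measurements: ROI volumes in cc, ADC quartile statistics and
## relative ADC against the contralateral mirror region.

#' ROI volume in cc
#'
#' Voxel count times voxel volume (mm^3, using the lattice spacing, with the
#' slice spacing standing in for thickness plus gap) divided by 1000.
#'
#' @param mask a [RoiMask-class].
#' @return Volume in cc.
#' @examples
#' m <- RoiMask(array(TRUE, c(10, 10, 10)), c(1, 1, 1), "IPH")
#' roiVolumeCC(m)  # 1 cc
#' @export
roiVolumeCC <- function(mask) {
  stopifnot(is(mask, "RoiMask"))
  nVoxels(mask) * prod(mask@spacing) / 1000
}

#' ADC order statistics over a ROI
#'
#' P25, mean, median and P75 of the ADC values under the mask, plus the ROI
#' volume. Quantiles use linear interpolation between order statistics
#' (type 7).
#'
#' @param adc [ImageVolume-class] ADC map.
#' @param mask nonempty [RoiMask-class] on the same grid.
#' @param quantileType quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return List with `p25`, `mean`, `median`, `p75`, `volumeCC`, `nVoxels`.
#' @export
roiADCStats <- function(adc, mask, quantileType = 7) {
  .checkSameGrid(adc, mask)
  n <- nVoxels(mask)
  if (n == 0L) stop("ROI is empty")
  v <- adc@values[mask@values]
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = quantileType))
  list(p25 = q[1], mean = mean(v), median = q[2], p75 = q[3],
       volumeCC = roiVolumeCC(mask), nVoxels = n)
}

#' Relative ADC of a ROI against the mirror region
#'
#' @param roiMedian ROI median ADC, 10^-6 mm^2/s.
#' @param mirrorMedian mirror-region median ADC, 10^-6 mm^2/s (must be > 0).
#' @return Unitless fraction `roiMedian / mirrorMedian`.
#' @examples
#' relativeADC(624.5, 750)
#' @export
relativeADC <- function(roiMedian, mirrorMedian) {
  if (!is.finite(mirrorMedian) || mirrorMedian <= 0)
    stop("mirror median must be > 0")
  roiMedian / mirrorMedian
}

#' Quantify one case from its volumes and masks
#'
#' Computes per-ROI ADC statistics and volumes for the hematoma, the edema
#' and (when positive) the rim, relative ADC values against the mirror
#' median, and the rim-positivity call. By default rim voxels are excluded
#' from the edema statistics when the two masks overlap
#' (`excludePDRfromPHE`). Recomputation on identical inputs is bit-identical
#' (no randomness).
#'
#' @param volumes named list of [ImageVolume-class] containing at least
#'   `ADC`.
#' @param masks named list of [RoiMask-class] with entries `IPH`, `PHE`,
#'   `PDR`.
#' @param mirrorStats a [MirrorStats-class].
#' @param minPositiveCC rim-positivity volume cutoff in cc (default 0.1).
#' @param excludePDRfromPHE logical (default `TRUE`).
#' @param quantileType quantile convention (default 7).
#' @return A [LesionQuant-class].
#' @export
quantifyCase <- function(volumes, masks, mirrorStats, minPositiveCC = 0.1,
                         excludePDRfromPHE = TRUE, quantileType = 7) {
  stopifnot("ADC" %in% names(volumes),
            all(c("IPH", "PHE", "PDR") %in% names(masks)))
  adc <- volumes$ADC
  status <- classifyPDRStatus(masks$PDR, minPositiveCC)

  pheMask <- masks$PHE
  if (excludePDRfromPHE && nVoxels(masks$PDR) > 0L) {
    pheMask <- RoiMask(pheMask@values & !masks$PDR@values, pheMask@spacing,
                       "PHE")
  }
  rois <- list(IPH = masks$IPH, PHE = pheMask)
  if (status$positive) rois$PDR <- masks$PDR

  stats <- lapply(rois, function(m) {
    if (nVoxels(m) == 0L)
      list(p25 = NA_real_, mean = NA_real_, median = NA_real_,
           p75 = NA_real_, volumeCC = 0, nVoxels = 0L)
    else roiADCStats(adc, m, quantileType)
  })
  if (!status$positive)
    stats$PDR <- list(p25 = NA_real_, mean = NA_real_, median = NA_real_,
                      p75 = NA_real_, volumeCC = status$volumeCC,
                      nVoxels = nVoxels(masks$PDR))

  rADC <- vapply(stats, function(s)
    if (is.na(s$median)) NA_real_ else
      relativeADC(s$median, mirrorStats@adcMedian), numeric(1))

  new("LesionQuant", roiStats = stats, rADC = rADC, mirror = mirrorStats,
      pdrPositive = status$positive,
      note = if (status$positive) "" else "pdr_absent")
}
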