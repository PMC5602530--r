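## Automated emulation of the manual ROI procedure: hematoma on T2*/SWI with
## FLAIR border refinement, whole lesion on FLAIR, edema by subtraction,
## contralateral mirror region, and the mirror-referenced ADC threshold rule
## for the diffusion-restriction rim.

.voxelCC <- function(spacing) prod(spacing) / 1000

.checkSameGrid <- function(...) {
  objs <- list(...)
  d <- lapply(objs, function(o) dim(if (is(o, "ImageVolume")) o@values else
                                    o@values))
  if (!all(vapply(d, identical, logical(1), d[[1]])))
    stop("inputs are not on the same grid")
  sp <- lapply(objs, imgSpacing)
  if (!all(vapply(sp, function(s) max(abs(s - sp[[1]])) < 1e-6, logical(1))))
    stop("inputs differ in voxel spacing")
  invisible(TRUE)
}

#' Segment the hematoma (IPH) on T2*/SWI with FLAIR border refinement
#'
#' The candidate clot is the largest 26-connected component of voxels whose
#' T2* signal lies strictly below `median - k * SD` of the in-brain T2*
#' distribution. Because T2*/SWI overestimates the clot (blooming, about
#' 20% by volume), the boundary is then refined against the co-registered
#' FLAIR: the FLAIR intensities inside the candidate are split into two
#' classes by quartile-initialized 1-D k-means, and the class that dominates
#' the eroded core of the candidate - the clot proper, since the blooming
#' margin is a boundary shell of surrounding tissue - is kept. The
#' refinement only engages when the class centres are separated by more than
#' twice the pooled within-class SD; otherwise no margin is evident and the
#' candidate is kept whole.
#'
#' @param t2star,flair co-registered [ImageVolume-class] objects.
#' @param brain [RoiMask-class] brain mask.
#' @param k T2* hypointensity threshold factor (default 2).
#' @param minCC minimum clot volume in cc (default 0.1); below it an empty
#'   mask flagged `"empty"` is returned rather than an error.
#' @param refineWithFLAIR disable to keep the raw (bloomed) T2* component.
#' @return A [RoiMask-class] with label `"IPH"`.
#' @export
segmentIPH <- function(t2star, flair, brain, k = 2, minCC = 0.1,
                       refineWithFLAIR = TRUE) {
  .checkSameGrid(t2star, flair, brain)
  bm <- brain@values
  vals <- t2star@values[bm]
  thr <- median(vals) - k * sd(vals)
  hypo <- t2star@values < thr & bm
  comp <- largestComponent(hypo)
  emptyMask <- function() RoiMask(array(FALSE, dim(bm)), t2star@spacing,
                                  "IPH", note = "empty")
  if (sum(comp) * .voxelCC(t2star@spacing) < minCC) return(emptyMask())

  if (refineWithFLAIR) {
    fl <- flair@values[comp]
    q <- unname(quantile(fl, c(0.25, 0.75), type = 7))
    if (diff(q) > 0) {
      km <- kmeans(fl, centers = matrix(q, ncol = 1))
      withinSD <- sqrt(sum(km$withinss) / max(1, length(fl) - 2))
      if (abs(diff(range(km$centers))) > 2 * withinSD) {
        ## the clot is the interior of the component; the blooming margin is
        ## a boundary shell - keep the FLAIR class dominating the eroded core
        core <- comp & !dilateMask(!comp, 1L)
        clotCl <- if (any(core)) {
          coreCl <- km$cluster[core[comp]]
          as.integer(names(which.max(table(coreCl))))
        } else which.max(km$size)
        keep <- array(FALSE, dim(bm))
        keep[comp] <- km$cluster == clotCl
        comp <- largestComponent(keep)
      }
    }
    if (sum(comp) * .voxelCC(t2star@spacing) < minCC) return(emptyMask())
  }
  RoiMask(comp, t2star@spacing, "IPH")
}

#' Segment the whole lesion (hematoma plus edema) on FLAIR
#'
#' FLAIR-hyperintense voxels (strictly above `median + k * SD` of the
#' in-brain FLAIR distribution) are labelled and cleaned by a one-voxel
#' morphological opening (removing noise speckle and thin protrusions, as a
#' reader's contour would); every remaining 26-connected component of at
#' least `minComponentCC` that touches the (one-voxel-dilated) hematoma mask
#' is united with the hematoma to form the lesion ROI. When nothing beyond
#' the hematoma is hyperintense the lesion equals the hematoma and the mask
#' is flagged `"no_phe"`.
#'
#' @param flair [ImageVolume-class].
#' @param iph [RoiMask-class] hematoma mask (must be nonempty).
#' @param brain [RoiMask-class] brain mask.
#' @param k FLAIR hyperintensity threshold factor (default 2).
#' @param minComponentCC minimum hyperintense component volume in cc
#'   (default 0.05).
#' @return A [RoiMask-class] with label `"LESION"`, always containing `iph`.
#' @export
segmentLesion <- function(flair, iph, brain, k = 2, minComponentCC = 0.05) {
  .checkSameGrid(flair, iph, brain)
  if (nVoxels(iph) == 0L) stop("lesion segmentation requires a nonempty IPH")
  bm <- brain@values
  vals <- flair@values[bm]
  thr <- median(vals) + k * sd(vals)
  hyper <- .openMask(flair@values > thr & bm)
  hyper <- .filterComponents(hyper,
                             ceiling(minComponentCC / .voxelCC(flair@spacing)))
  lab <- labelComponents(hyper)
  touching <- unique(lab[dilateMask(iph@values, 1L) & lab > 0L])
  lesion <- iph@values | (lab %in% touching & lab > 0L)
  dim(lesion) <- dim(bm)
  note <- if (any(lesion & !iph@values)) "" else "no_phe"
  RoiMask(lesion, flair@spacing, "LESION", note = note)
}

#' Derive the perihematomal edema mask by subtraction
#'
#' `PHE = LESION - IPH`; requires `iph` to be contained in `lesion`.
#'
#' @param lesion,iph [RoiMask-class] objects on the same grid.
#' @return A [RoiMask-class] with label `"PHE"`.
#' @export
derivePHE <- function(lesion, iph) {
  .checkSameGrid(lesion, iph)
  if (any(iph@values & !lesion@values))
    stop("contract error: IPH mask is not contained in the lesion mask")
  RoiMask(lesion@values & !iph@values, lesion@spacing, "PHE")
}

#' Build the contralateral mirror region of the lesion
#'
#' The lesion mask is reflected across the midsagittal plane (first-axis
#' index `i -> N - 1 - i`, 0-based) and then automatically adjusted the way a
#' reader would correct it: voxels falling outside the brain mask or inside
#' the lesion dilated by `excludeDilation` voxels are removed.
#'
#' @param lesion [RoiMask-class] lesion mask confined to one hemisphere.
#' @param brain [RoiMask-class] brain mask.
#' @param excludeDilation lesion safety margin in voxels (default 2).
#' @param minVoxels minimum surviving mirror size (default 50); fewer voxels
#'   raise a mirror error.
#' @return A [RoiMask-class] with label `"MIRROR"`.
#' @export
mirrorRegion <- function(lesion, brain, excludeDilation = 2L,
                         minVoxels = 50L) {
  .checkSameGrid(lesion, brain)
  n1 <- dim(lesion@values)[1]
  mirrored <- lesion@values[n1:1, , , drop = FALSE]
  excl <- dilateMask(lesion@values, as.integer(excludeDilation))
  keep <- mirrored & brain@values & !excl
  if (sum(keep) < minVoxels)
    stop(sprintf("mirror error: only %d mirror voxels survive (minimum %d)",
                 sum(keep), as.integer(minVoxels)))
  RoiMask(keep, lesion@spacing, "MIRROR")
}

#' Reference statistics of the mirror region
#'
#' Median and sample SD of the ADC map and the b1000 image over the mirror
#' voxels.
#'
#' @param adc,b1000 [ImageVolume-class] objects.
#' @param mirror [RoiMask-class] mirror region (nonempty).
#' @return A [MirrorStats-class].
#' @export
computeMirrorStats <- function(adc, b1000, mirror) {
  .checkSameGrid(adc, b1000, mirror)
  idx <- mirror@values
  n <- sum(idx)
  if (n == 0L) stop("mirror region is empty")
  a <- adc@values[idx]
  b <- b1000@values[idx]
  new("MirrorStats", adcMedian = median(a),
      adcSD = if (n > 1) sd(a) else 0,
      b1000Median = median(b),
      b1000SD = if (n > 1) sd(b) else 0,
      nVoxels = as.integer(n))
}

#' Detect the perihematomal diffusion-restriction rim (PDR)
#'
#' The candidate search region is the edema mask united with a shell of
#' `shellVoxels` outside the lesion's outer border (the rim is typically
#' adjacent to, and may extend just beyond, the edema). A candidate voxel is
#' retained when it is BOTH hypointense on ADC - at or below
#' `mirror median - adcSDFactor * mirror SD` - and hyperintense on b1000 -
#' at or above `mirror median + b1000SDFactor * mirror SD`. 26-connected
#' components smaller than `minComponentCC` are discarded. An empty mask is
#' a valid outcome (rim-negative case). The hematoma mask, when supplied, is
#' always excluded.
#'
#' @param adc,b1000 co-registered [ImageVolume-class] objects.
#' @param phe [RoiMask-class] edema mask.
#' @param mirrorStats a [MirrorStats-class].
#' @param iph optional [RoiMask-class] hematoma mask used to complete the
#'   lesion for the outer-shell construction and excluded from the result.
#' @param brain optional [RoiMask-class]; candidates are restricted to it.
#' @param adcSDFactor ADC threshold factor (default 1.5).
#' @param b1000SDFactor b1000 threshold factor (default 1.5).
#' @param shellVoxels outer shell thickness in voxels (default 2).
#' @param minComponentCC minimum component volume in cc (default 0.05).
#' @return A [RoiMask-class] with label `"PDR"` and attributes
#'   `"adcCutoff"`/`"b1000Cutoff"` recording the thresholds applied.
#' @export
detectPDR <- function(adc, b1000, phe, mirrorStats, iph = NULL, brain = NULL,
                      adcSDFactor = 1.5, b1000SDFactor = 1.5,
                      shellVoxels = 2L, minComponentCC = 0.05) {
  .checkSameGrid(adc, b1000, phe)
  stopifnot(is(mirrorStats, "MirrorStats"))
  if (adcSDFactor <= 0 || b1000SDFactor <= 0)
    stop("threshold factors must be > 0")
  lesion <- phe@values
  if (!is.null(iph)) lesion <- lesion | iph@values
  candidate <- phe@values |
    (dilateMask(lesion, as.integer(shellVoxels)) & !lesion)
  if (!is.null(brain)) candidate <- candidate & brain@values
  if (!is.null(iph)) candidate <- candidate & !iph@values

  adcCut <- mirrorStats@adcMedian - adcSDFactor * mirrorStats@adcSD
  b1000Cut <- mirrorStats@b1000Median + b1000SDFactor * mirrorStats@b1000SD
  sel <- candidate & adc@values <= adcCut & b1000@values >= b1000Cut
  minVox <- ceiling(minComponentCC / .voxelCC(adc@spacing))
  sel <- .filterComponents(sel, minVox)
  out <- RoiMask(sel, adc@spacing, "PDR")
  attr(out, "adcCutoff") <- adcCut
  attr(out, "b1000Cutoff") <- b1000Cut
  out
}

#' Classify rim-positivity from the detected PDR mask
#'
#' A case is rim-positive when the detected rim volume is at least
#' `minPositiveCC` (inclusive).
#'
#' @param pdr [RoiMask-class] detected rim.
#' @param minPositiveCC positivity volume cutoff in cc (default 0.1).
#' @return List with elements `positive` (logical) and `volumeCC`.
#' @export
classifyPDRStatus <- function(pdr, minPositiveCC = 0.1) {
  vol <- nVoxels(pdr) * .voxelCC(pdr@spacing)
  list(positive = vol >= minPositiveCC, volumeCC = vol)
}
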