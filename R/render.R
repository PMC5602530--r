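## Signal rendering: compartment-wise ADC draws plus unitless signal levels
## for FLAIR / b1000 / T2*, with additive Gaussian noise.

## signal levels rendered outside the brain (document-level constants; the
## segmentation never looks outside the brain mask, but registration exploits
## the brain/background contrast)
.OUTSIDE_LEVELS <- c(FLAIR = 10, B1000 = 10, ADC = 0, T2STAR = 30)

#' Draw from a piecewise-scaled (split) normal given median and IQR
#'
#' Uses separate normal scales below and above the median, chosen so that the
#' sample quartiles of the distribution equal `p25` and `p75` exactly:
#' `sigma_low = (median - p25) / qnorm(0.75)` and
#' `sigma_high = (p75 - median) / qnorm(0.75)`. A degenerate IQR
#' (`p25 = median = p75`) yields the median with probability one.
#'
#' @param n number of draws.
#' @param med distribution median.
#' @param p25,p75 first and third quartiles (`p25 <= med <= p75`).
#' @return Numeric vector of length `n`.
#' @export
rSplitNormal <- function(n, med, p25, p75) {
  stopifnot(p25 <= med, med <= p75)
  sl <- (med - p25) / qnorm(0.75)
  su <- (p75 - med) / qnorm(0.75)
  z <- qnorm(runif(n))
  med + ifelse(z < 0, z * sl, z * su)
}

#' Render the modality volumes of a phantom from its ground truth
#'
#' Per-voxel ADC values are drawn compartment-wise from the split-normal
#' distribution matching each compartment's median/IQR; FLAIR is hyperintense
#' over the lesion (IPH and PHE) but not over the PDR; b1000 is hyperintense
#' over the PDR; the T2* clot hypointensity covers the IPH ellipsoid inflated
#' in volume by `bloomingFraction` (radii scaled by `(1 + f)^(1/3)`),
#' emulating susceptibility blooming. Additive Gaussian noise with the
#' per-modality SDs is applied last; ADC is clamped at 0. The result is fully
#' reproducible from `(truth, spec, seed)`.
#'
#' @param truth integer label array from [buildGeometry()].
#' @param spec the generating [PhantomSpec-class].
#' @param seed integer RNG seed.
#' @return Named list of [ImageVolume-class] objects (`FLAIR`, `B1000`,
#'   `ADC`, `T2STAR`), voxel-aligned with `truth`.
#' @export
renderModalities <- function(truth, spec, seed) {
  validObject(spec)
  if (any(spec@noiseSD < 0)) stop("parameter error: negative noise SD")
  gs <- dim(truth)
  stopifnot(all(gs == spec@gridShape))
  set.seed(as.integer(seed))

  comp <- spec@compartments
  compLabel <- c(BACKGROUND_BRAIN = .LABELS[["background_brain"]],
                 IPH = .LABELS[["iph"]], PHE = .LABELS[["phe"]],
                 PDR = .LABELS[["pdr"]])

  adc <- array(.OUTSIDE_LEVELS[["ADC"]], gs)
  flair <- array(.OUTSIDE_LEVELS[["FLAIR"]], gs)
  b1000 <- array(.OUTSIDE_LEVELS[["B1000"]], gs)
  t2star <- array(.OUTSIDE_LEVELS[["T2STAR"]], gs)

  ## compartment fills in fixed order so the RNG stream is deterministic
  for (nm in names(compLabel)) {
    idx <- which(truth == compLabel[[nm]])
    if (!length(idx)) next
    cs <- comp[[nm]]
    adc[idx] <- rSplitNormal(length(idx), cs@adcMedian, cs@adcIQR[1],
                             cs@adcIQR[2])
    flair[idx] <- cs@flairLevel
    b1000[idx] <- cs@b1000Level
    t2star[idx] <- cs@t2starLevel
  }

  ## T2* blooming: clot hypointensity over the volume-inflated IPH ellipsoid
  bloomScale <- (1 + spec@bloomingFraction)^(1 / 3)
  bloom <- ellipsoidMask(gs, spec@spacing, spec@iphCenter,
                         spec@iphRadii * bloomScale) & truth > 0L
  t2star[bloom] <- comp[["IPH"]]@t2starLevel

  noisy <- function(a, modality) {
    sdN <- spec@noiseSD[[modality]]
    if (sdN > 0) a <- a + array(rnorm(length(a), 0, sdN), dim(a))
    if (modality == "ADC") a[a < 0] <- 0
    ImageVolume(a, spec@spacing, modality)
  }
  list(FLAIR = noisy(flair, "FLAIR"), B1000 = noisy(b1000, "B1000"),
       ADC = noisy(adc, "ADC"), T2STAR = noisy(t2star, "T2STAR"))
}
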