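## Phantom assembly and default study-condition parameters.

#' Default compartment signal specifications
#'
#' The compartment ADC medians and interquartile ranges are those observed in
#' hyperacute hemorrhage: PDR 624.5 (598.5-670), IPH 789 (710-890), PHE 1030
#' (948-1110), all in 10^-6 mm^2/s; normal (background) brain is set to 790
#' (750-830), a typical supratentorial parenchyma value, so that the mirror
#' region yields a realistic reference. Unitless signal levels encode the
#' qualitative contrasts the analysis relies on: FLAIR hyperintensity of clot
#' (140) and edema (180) against brain (100) but not of the rim (100); b1000
#' hyperintensity of the rim only (140 vs 100); and T2* hypointensity of the
#' clot (40 vs 100).
#'
#' @return Named list of [CompartmentSpec-class] objects.
#' @export
defaultCompartments <- function() {
  mk <- function(name, med, iqr, fl, b1, t2)
    new("CompartmentSpec", name = name, adcMedian = med, adcIQR = iqr,
        flairLevel = fl, b1000Level = b1, t2starLevel = t2)
  list(
    BACKGROUND_BRAIN = mk("BACKGROUND_BRAIN", 790, c(750, 830), 100, 100, 100),
    IPH = mk("IPH", 789, c(710, 890), 140, 100, 40),
    PHE = mk("PHE", 1030, c(948, 1110), 180, 100, 100),
    PDR = mk("PDR", 624.5, c(598.5, 670), 100, 140, 100)
  )
}

#' Default phantom specification
#'
#' A 64 x 64 x 48 lattice at 2 mm isotropic spacing holding a left-right
#' symmetric brain ellipsoid (semi-axes 58, 58, 44 mm) with a right-sided
#' hematoma of semi-axes 14 x 11 x 11 mm (about 7 cc), a 7 mm edema shell
#' and, by default, a 4 mm diffusion-restriction rim. T2* blooming fraction
#' 0.20. Any argument overrides the default.
#'
#' @param gridShape,spacing,brainRadii,iphCenter,iphRadii,pheThickness
#'   geometry overrides (mm); `iphCenter = NULL` places the hematoma 26 mm to
#'   the right of the midsagittal plane at mid-height.
#' @param pdrPresent,pdrThickness rim presence and thickness (mm).
#' @param compartments named list of [CompartmentSpec-class].
#' @param noiseSD named per-modality additive noise SDs.
#' @param bloomingFraction T2* clot volume overestimation fraction.
#' @param rigidOffset named list of per-modality mm translations.
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- defaultPhantomSpec(pdrPresent = FALSE)
#' @export
defaultPhantomSpec <- function(gridShape = c(64L, 64L, 48L),
                               spacing = c(2, 2, 2),
                               brainRadii = c(58, 58, 44),
                               iphCenter = NULL,
                               iphRadii = c(14, 11, 11),
                               pheThickness = 7,
                               pdrPresent = TRUE,
                               pdrThickness = 4,
                               compartments = defaultCompartments(),
                               noiseSD = c(FLAIR = 5, B1000 = 5, ADC = 20,
                                           T2STAR = 5),
                               bloomingFraction = 0.20,
                               rigidOffset = NULL) {
  gridShape <- as.integer(gridShape)
  if (is.null(iphCenter)) {
    ctr <- (gridShape - 1) / 2 * spacing
    iphCenter <- ctr + c(26, 0, 0)
  }
  if (is.null(rigidOffset))
    rigidOffset <- list(FLAIR = c(0, 0, 0), B1000 = c(0, 0, 0),
                        ADC = c(0, 0, 0), T2STAR = c(0, 0, 0))
  new("PhantomSpec", gridShape = gridShape, spacing = as.numeric(spacing),
      brainRadii = as.numeric(brainRadii), iphCenter = as.numeric(iphCenter),
      iphRadii = as.numeric(iphRadii), pheThickness = as.numeric(pheThickness),
      pdrPresent = isTRUE(pdrPresent), pdrThickness = as.numeric(pdrThickness),
      compartments = compartments, noiseSD = noiseSD,
      bloomingFraction = as.numeric(bloomingFraction),
      rigidOffset = rigidOffset)
}

#' Generate one multimodal phantom case
#'
#' Composes [buildGeometry()] and [renderModalities()], then applies each
#' modality's rigid offset (rounded to whole voxels; exposed voxels take the
#' modality's outside-brain level). The truth array stays on the reference
#' (ADC-aligned) grid. Regeneration with the same `(spec, seed)` is
#' bit-identical.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer RNG seed.
#' @return A [PhantomCase-class].
#' @examples
#' case <- makePhantom(defaultPhantomSpec(gridShape = c(48L, 48L, 28L),
#'                                        brainRadii = c(44, 44, 25),
#'                                        iphRadii = c(8, 7, 7),
#'                                        pheThickness = 5,
#'                                        iphCenter = c(67, 47, 27)), seed = 1)
#' case
#' @export
makePhantom <- function(spec, seed) {
  truth <- buildGeometry(spec)
  vols <- renderModalities(truth, spec, seed)
  for (m in names(vols)) {
    off <- round(spec@rigidOffset[[m]] / spec@spacing)
    if (any(off != 0)) {
      shifted <- shiftArray(vols[[m]]@values, off,
                            fill = .OUTSIDE_LEVELS[[m]])
      vols[[m]] <- ImageVolume(shifted, spec@spacing, m)
    }
  }
  new("PhantomCase", volumes = vols, truth = truth, spec = spec,
      seed = as.integer(seed))
}

#' Extract a ground-truth compartment mask from a phantom
#'
#' @param case a [PhantomCase-class].
#' @param compartment one of `"iph"`, `"phe"`, `"pdr"`, `"background_brain"`,
#'   `"lesion"` (IPH + PHE) or `"brain"` (everything inside the brain).
#' @return A [RoiMask-class] on the reference grid.
#' @export
truthMask <- function(case, compartment = c("iph", "phe", "pdr",
                                            "background_brain", "lesion",
                                            "brain")) {
  compartment <- match.arg(compartment)
  tr <- case@truth
  m <- switch(compartment,
              brain = tr > .LABELS[["outside_brain"]],
              lesion = tr == .LABELS[["iph"]] | tr == .LABELS[["phe"]],
              tr == .LABELS[[compartment]])
  label <- switch(compartment, iph = "IPH", phe = "PHE", pdr = "PDR",
                  lesion = "LESION", "BRAIN")
  RoiMask(array(m, dim(tr)), case@spec@spacing, label)
}

#' Brain mask of a phantom case
#'
#' @param case a [PhantomCase-class].
#' @return A [RoiMask-class] with label `"BRAIN"`.
#' @export
brainMask <- function(case) truthMask(case, "brain")
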