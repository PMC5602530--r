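#' @import methods
#' @importFrom stats median sd quantile rnorm runif qnorm pchisq pt pnorm
#'   dhyper pwilcox kmeans setNames
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib pdrim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Ground-truth voxel label codes shared by the generator and the tests.
.LABELS <- c(outside_brain = 0L, background_brain = 1L, iph = 2L, phe = 3L, pdr = 4L)

.MODALITIES <- c("FLAIR", "B1000", "ADC", "T2STAR")
.ROI_LABELS <- c("IPH", "LESION", "PHE", "PDR", "MIRROR", "BRAIN")

#' One MRI modality as a 3-D scalar lattice
#'
#' `ImageVolume` holds one co-registered modality: a 3-D numeric array, its
#' physical voxel spacing in mm, and a modality tag. Only the ADC modality
#' carries physical units (10^-6 mm^2/s); FLAIR, b1000 and T2* are unitless
#' signal levels.
#'
#' @slot values 3-D numeric array.
#' @slot spacing numeric(3), voxel spacing in mm (in-plane, in-plane, slice).
#' @slot modality one of `"FLAIR"`, `"B1000"`, `"ADC"`, `"T2STAR"`.
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric", modality = "character"))

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite numbers (mm)")
  if (length(object@modality) != 1L || !(object@modality %in% .MODALITIES))
    msg <- c(msg, sprintf("'modality' must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (identical(object@modality, "ADC") &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "ADC values must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Binary region-of-interest mask on an image lattice
#'
#' @slot values 3-D logical array on the same lattice as its parent volume.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot label ROI tag: `"IPH"`, `"LESION"`, `"PHE"`, `"PDR"`, `"MIRROR"`
#'   or `"BRAIN"`.
#' @slot note character flag set by operations that return a valid but
#'   degenerate result (for example an empty hematoma mask); `""` otherwise.
#' @export
setClass("RoiMask",
  representation(values = "array", spacing = "numeric", label = "character",
                 note = "character"),
  prototype(note = ""))

setValidity("RoiMask", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L || !is.logical(object@values))
    msg <- c(msg, "'values' must be a 3-D logical array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive numbers (mm)")
  if (length(object@label) != 1L || !(object@label %in% .ROI_LABELS))
    msg <- c(msg, sprintf("'label' must be one of %s",
                          paste(.ROI_LABELS, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Integer-voxel rigid translation between modality grids
#'
#' @slot translation integer(3), voxel shift to apply to the moving volume so
#'   that it aligns with the fixed (ADC) grid.
#' @export
setClass("RigidTransform", representation(translation = "integer"))

setValidity("RigidTransform", function(object) {
  if (length(object@translation) != 3L || any(is.na(object@translation)))
    "'translation' must be integer(3)" else TRUE
})

#' Contralateral mirror-region reference statistics
#'
#' Median and sample SD of the ADC map and the b1000 image over the mirror
#' region; these anchor the rim-detection thresholds.
#'
#' @slot adcMedian,adcSD ADC median / SD in 10^-6 mm^2/s.
#' @slot b1000Median,b1000SD b1000 median / SD (unitless signal).
#' @slot nVoxels number of mirror voxels the statistics were computed over.
#' @export
setClass("MirrorStats",
  representation(adcMedian = "numeric", adcSD = "numeric",
                 b1000Median = "numeric", b1000SD = "numeric",
                 nVoxels = "integer"))

setValidity("MirrorStats", function(object) {
  msg <- NULL
  if (object@nVoxels < 1L) msg <- c(msg, "'nVoxels' must be >= 1")
  if (object@adcSD < 0 || object@b1000SD < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Per-compartment signal specification for the phantom generator
#'
#' ADC is described by its median and interquartile range (P25, P75) in
#' 10^-6 mm^2/s and drawn from a piecewise-scaled (split) normal whose
#' quartiles match them exactly; the other modalities are constant unitless
#' levels plus noise.
#'
#' @slot name `"BACKGROUND_BRAIN"`, `"IPH"`, `"PHE"` or `"PDR"`.
#' @slot adcMedian ADC median, 10^-6 mm^2/s.
#' @slot adcIQR numeric(2): P25 and P75, 10^-6 mm^2/s.
#' @slot flairLevel,b1000Level,t2starLevel unitless signal levels.
#' @export
setClass("CompartmentSpec",
  representation(name = "character", adcMedian = "numeric", adcIQR = "numeric",
                 flairLevel = "numeric", b1000Level = "numeric",
                 t2starLevel = "numeric"))

setValidity("CompartmentSpec", function(object) {
  msg <- NULL
  if (!(object@name %in% c("BACKGROUND_BRAIN", "IPH", "PHE", "PDR")))
    msg <- c(msg, "unknown compartment name")
  if (length(object@adcIQR) != 2L ||
      !(object@adcIQR[1] <= object@adcMedian &&
        object@adcMedian <= object@adcIQR[2]))
    msg <- c(msg, "need adcIQR[1] <= adcMedian <= adcIQR[2]")
  if (object@adcMedian <= 0 || object@adcMedian > 4000 ||
      any(object@adcIQR <= 0) || any(object@adcIQR > 4000))
    msg <- c(msg, "ADC values must lie in (0, 4000] (10^-6 mm^2/s)")
  if (is.null(msg)) TRUE else msg
})

#' Geometry and signal specification of one multimodal phantom
#'
#' The phantom is a left-right symmetric brain ellipsoid containing, in one
#' hemisphere, a solid hematoma (IPH) ellipsoid, a perihematomal edema (PHE)
#' shell of fixed thickness around it, and optionally a diffusion-restriction
#' rim (PDR) shell immediately outside the edema. All coordinates are in mm;
#' voxel `(i, j, k)` (0-based) sits at `c(i, j, k) * spacing` mm. The first
#' lattice axis is left-right; the midsagittal plane is its central plane.
#'
#' @slot gridShape integer(3) lattice dimensions.
#' @slot spacing numeric(3) voxel spacing in mm (the third component stands for
#'   the slice spacing of a resampled contiguous grid).
#' @slot brainRadii numeric(3) semi-axes (mm) of the brain ellipsoid, centred
#'   in the grid.
#' @slot iphCenter numeric(3) hematoma centre in mm coordinates.
#' @slot iphRadii numeric(3) hematoma ellipsoid semi-axes, mm.
#' @slot pheThickness,pdrThickness shell thicknesses in mm (>= 0).
#' @slot pdrPresent logical; when `FALSE`, `pdrThickness` is ignored.
#' @slot compartments named list of [CompartmentSpec-class] for
#'   `BACKGROUND_BRAIN`, `IPH`, `PHE`, `PDR`.
#' @slot noiseSD named numeric, additive Gaussian noise SD per modality.
#' @slot bloomingFraction T2*/SWI clot volume overestimation fraction
#'   (default 0.20).
#' @slot rigidOffset named list of numeric(3) mm translations applied to each
#'   modality when the phantom is assembled (simulated mis-registration).
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 brainRadii = "numeric", iphCenter = "numeric",
                 iphRadii = "numeric", pheThickness = "numeric",
                 pdrPresent = "logical", pdrThickness = "numeric",
                 compartments = "list", noiseSD = "numeric",
                 bloomingFraction = "numeric", rigidOffset = "list"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "'gridShape' must be integer(3), each >= 8")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be positive numeric(3) (mm)")
  if (length(object@brainRadii) != 3L || any(object@brainRadii <= 0))
    msg <- c(msg, "'brainRadii' must be positive numeric(3) (mm)")
  if (length(object@iphRadii) != 3L || any(object@iphRadii <= 0))
    msg <- c(msg, "'iphRadii' must be positive numeric(3) (mm)")
  if (object@pheThickness < 0 || object@pdrThickness < 0)
    msg <- c(msg, "shell thicknesses must be >= 0")
  if (object@bloomingFraction < 0)
    msg <- c(msg, "'bloomingFraction' must be >= 0")
  if (any(object@noiseSD < 0))
    msg <- c(msg, "noise SDs must be >= 0")
  need <- c("BACKGROUND_BRAIN", "IPH", "PHE", "PDR")
  if (!all(need %in% names(object@compartments)))
    msg <- c(msg, sprintf("'compartments' must contain %s",
                          paste(need, collapse = ", ")))
  if (!all(.MODALITIES %in% names(object@noiseSD)))
    msg <- c(msg, "'noiseSD' must be named for every modality")
  if (!all(.MODALITIES %in% names(object@rigidOffset)))
    msg <- c(msg, "'rigidOffset' must be named for every modality")
  if (is.null(msg)) TRUE else msg
})

#' A generated phantom case: modality volumes plus ground truth
#'
#' @slot volumes named list of [ImageVolume-class] for FLAIR, B1000, ADC,
#'   T2STAR (with per-modality rigid offsets already applied).
#' @slot truth integer 3-D array of ground-truth labels on the reference (ADC)
#'   grid: 0 outside brain, 1 background brain, 2 IPH, 3 PHE, 4 PDR.
#' @slot spec the [PhantomSpec-class] that generated the case.
#' @slot seed integer RNG seed; `(spec, seed)` regenerates bit-identically.
#' @export
setClass("PhantomCase",
  representation(volumes = "list", truth = "array", spec = "PhantomSpec",
                 seed = "integer"))

setValidity("PhantomCase", function(object) {
  msg <- NULL
  if (!all(.MODALITIES %in% names(object@volumes)))
    msg <- c(msg, "'volumes' must contain every modality")
  if (!all(vapply(object@volumes, is, logical(1), "ImageVolume")))
    msg <- c(msg, "'volumes' entries must be ImageVolume objects")
  dims <- vapply(object@volumes, function(v) dim(v@values), integer(3))
  if (!all(dims == dim(object@truth)))
    msg <- c(msg, "all volumes must share the truth grid shape")
  if (!all(object@truth %in% .LABELS))
    msg <- c(msg, "truth labels must be codes 0..4")
  if (is.null(msg)) TRUE else msg
})

#' Marginal structure of a synthetic patient cohort
#'
#' Defaults mirror the baseline characteristics of an 83-patient hyperacute
#' hemorrhage cohort: PDR prevalence 56/83, 54 males / 29 females with
#' gender-specific age distributions, hematoma volume median 12.9
#' (IQR 7.9-26.6) cc, admission NIHSS 11 (7-15), time-from-onset bins
#' including a wake-up stratum, 66 deep / 15 lobar / 2 infratentorial
#' locations, removal rate 4/83 and mortality 7/83.
#'
#' @slot nPatients cohort size.
#' @slot pdrPrevalence marginal probability of a positive diffusion rim.
#' @slot maleFraction fraction of male patients.
#' @slot ageMale,ageFemale numeric(3) `(median, P25, P75)` age in years.
#' @slot iphVolume,pdrVolume,nihssAdmission,nihssDischarge numeric(3)
#'   `(median, P25, P75)`; volumes in cc, drawn on the log scale.
#' @slot timeBinWeights named probabilities of the onset-to-MRI bins
#'   (`<=1`, `1-2`, ..., `5-6` hours and `wakeup`), summing to 1.
#' @slot locationWeights named probabilities for deep / lobar /
#'   infratentorial, summing to 1.
#' @slot removalFraction,mortalityFraction event probabilities.
#' @slot pdrIphCorrelation target Pearson correlation between log PDR and
#'   log IPH volumes among rim-positive patients.
#' @slot compartments named list of [CompartmentSpec-class] used to draw
#'   per-patient compartment ADC medians.
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", pdrPrevalence = "numeric",
                 maleFraction = "numeric", ageMale = "numeric",
                 ageFemale = "numeric", iphVolume = "numeric",
                 pdrVolume = "numeric", nihssAdmission = "numeric",
                 nihssDischarge = "numeric", timeBinWeights = "numeric",
                 locationWeights = "numeric", removalFraction = "numeric",
                 mortalityFraction = "numeric", pdrIphCorrelation = "numeric",
                 compartments = "list"))

setValidity("CohortSpec", function(object) {
  msg <- NULL
  fr <- c(object@pdrPrevalence, object@maleFraction, object@removalFraction,
          object@mortalityFraction)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "all fractions must lie in [0, 1]")
  if (object@nPatients < 0L)
    msg <- c(msg, "'nPatients' must be >= 0")
  if (abs(sum(object@timeBinWeights) - 1) > 1e-8)
    msg <- c(msg, "'timeBinWeights' must sum to 1")
  if (abs(sum(object@locationWeights) - 1) > 1e-8)
    msg <- c(msg, "'locationWeights' must sum to 1")
  if (abs(object@pdrIphCorrelation) >= 1)
    msg <- c(msg, "'pdrIphCorrelation' must lie in (-1, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Maximum-likelihood logistic regression fit
#'
#' Fitted by iteratively reweighted least squares; odds ratios are
#' `exp(coefficient)` with Wald 95% confidence intervals on the exponential
#' scale.
#'
#' @slot coefficients named numeric, log-odds coefficients (incl. intercept).
#' @slot oddsRatios `exp(coefficients)`.
#' @slot ci numeric matrix, columns `lower`/`upper`: Wald 95% CI on the odds
#'   scale.
#' @slot pValues two-sided Wald p-values.
#' @slot se coefficient standard errors.
#' @slot vcov coefficient covariance matrix.
#' @slot converged logical; `FALSE` signals non-convergence (for example
#'   perfect separation).
#' @slot nIterations IRLS iterations used.
#' @slot logLik maximized log-likelihood.
#' @export
setClass("LogisticFit",
  representation(coefficients = "numeric", oddsRatios = "numeric",
                 ci = "matrix", pValues = "numeric", se = "numeric",
                 vcov = "matrix", converged = "logical",
                 nIterations = "integer", logLik = "numeric"))

#' Per-case lesion quantification
#'
#' @slot roiStats named list of per-ROI summaries (`p25`, `mean`, `median`,
#'   `p75`, `volumeCC`, `nVoxels`) for IPH, PHE and (when positive) PDR.
#' @slot rADC named numeric: ROI median ADC divided by the mirror median ADC
#'   (unitless fraction); `NA` for an absent rim.
#' @slot mirror the [MirrorStats-class] used.
#' @slot pdrPositive logical rim-positivity call.
#' @slot note character flag (for example `"pdr_absent"`).
#' @export
setClass("LesionQuant",
  representation(roiStats = "list", rADC = "numeric", mirror = "MirrorStats",
                 pdrPositive = "logical", note = "character"),
  prototype(note = ""))
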