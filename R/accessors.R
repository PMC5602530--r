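#' Construct an ImageVolume
#'
#' @param values 3-D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param modality one of `"FLAIR"`, `"B1000"`, `"ADC"`, `"T2STAR"`.
#' @return An [ImageVolume-class].
#' @examples
#' v <- ImageVolume(array(0, c(4, 4, 2)), c(1, 1, 6.5), "ADC")
#' imgSpacing(v)
#' @export
ImageVolume <- function(values, spacing, modality) {
  storage.mode(values) <- "double"
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      modality = as.character(modality))
}

#' Construct a RoiMask
#'
#' @param values 3-D logical array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param label ROI tag.
#' @param note optional flag string for degenerate-but-valid results.
#' @return A [RoiMask-class].
#' @export
RoiMask <- function(values, spacing, label, note = "") {
  storage.mode(values) <- "logical"
  new("RoiMask", values = values, spacing = as.numeric(spacing),
      label = as.character(label), note = as.character(note))
}

#' @rdname ImageVolume-class
#' @export
setMethod("imgValues", "ImageVolume", function(object) object@values)

#' @rdname ImageVolume-class
#' @export
setMethod("imgSpacing", "ImageVolume", function(object) object@spacing)

#' @rdname ImageVolume-class
#' @export
setMethod("imgModality", "ImageVolume", function(object) object@modality)

#' @rdname RoiMask-class
#' @export
setMethod("maskValues", "RoiMask", function(object) object@values)

#' @rdname RoiMask-class
#' @export
setMethod("imgSpacing", "RoiMask", function(object) object@spacing)

#' @rdname RoiMask-class
#' @export
setMethod("maskLabel", "RoiMask", function(object) object@label)

#' @rdname RoiMask-class
#' @export
setMethod("maskNote", "RoiMask", function(object) object@note)

#' @rdname RoiMask-class
#' @export
setMethod("nVoxels", "RoiMask", function(object) sum(object@values))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume [%s] %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  rng <- range(object@values)
  cat(sprintf("  value range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("RoiMask [%s] %dx%dx%d: %d voxels (%.3f cc)%s\n",
              object@label, d[1], d[2], d[3], sum(object@values),
              sum(object@values) * prod(object@spacing) / 1000,
              if (nzchar(object@note)) paste0(" [", object@note, "]") else ""))
})

setMethod("show", "MirrorStats", function(object) {
  cat(sprintf(paste0("MirrorStats over %d voxels: ADC median %.1f (SD %.1f)",
                     " x10^-6 mm^2/s; b1000 median %.1f (SD %.1f)\n"),
              object@nVoxels, object@adcMedian, object@adcSD,
              object@b1000Median, object@b1000SD))
})

setMethod("show", "PhantomCase", function(object) {
  d <- dim(object@truth)
  cnt <- table(factor(object@truth, levels = .LABELS, labels = names(.LABELS)))
  cat(sprintf("PhantomCase %dx%dx%d (seed %d)\n", d[1], d[2], d[3],
              object@seed))
  cat("  voxels:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "),
      "\n")
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit (%s, %d IRLS iterations, logLik %.3f)\n",
              if (object@converged) "converged" else "NOT converged",
              object@nIterations, object@logLik))
  tab <- data.frame(coef = object@coefficients, OR = object@oddsRatios,
                    lower = object@ci[, "lower"], upper = object@ci[, "upper"],
                    p = object@pValues)
  print(round(tab, 4))
})

setMethod("show", "LesionQuant", function(object) {
  cat("LesionQuant:", if (object@pdrPositive) "PDR-positive" else
      "PDR-negative", "\n")
  for (nm in names(object@roiStats)) {
    s <- object@roiStats[[nm]]
    cat(sprintf("  %-4s volume %.2f cc, ADC median %.1f (P25 %.1f, P75 %.1f)\n",
                nm, s$volumeCC, s$median, s$p25, s$p75))
  }
  if (length(object@rADC))
    cat("  rADC:", paste(sprintf("%s=%.3f", names(object@rADC), object@rADC),
                         collapse = ", "), "\n")
})

#' Ground-truth label codes used by the phantom generator
#'
#' @return Named integer vector mapping label names (`outside_brain`,
#'   `background_brain`, `iph`, `phe`, `pdr`) to the codes stored in the
#'   truth array of a [PhantomCase-class].
#' @export
truthLabelCodes <- function() .LABELS
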