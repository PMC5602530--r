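## Integer-translation registration by exhaustive normalized cross-correlation.

#' Register a moving volume to a fixed volume by integer translation
#'
#' Exhaustively evaluates the normalized cross-correlation (Pearson
#' correlation over the overlapping voxels) for every integer voxel shift
#' within `searchRadius` along each axis and returns the shift that maximizes
#' it. Ties are broken by smallest shift magnitude, then lexicographic order.
#'
#' @param moving,fixed [ImageVolume-class] objects on grids of equal shape.
#' @param searchRadius maximum absolute shift per axis, voxels (default 3).
#' @return A [RigidTransform-class]: the translation to apply to `moving`
#'   (via [applyTransform()]) to align it with `fixed`.
#' @examples
#' spec <- defaultPhantomSpec(gridShape = c(48L, 48L, 28L),
#'                            brainRadii = c(44, 44, 25),
#'                            iphRadii = c(8, 7, 7), pheThickness = 5,
#'                            iphCenter = c(67, 47, 27))
#' case <- makePhantom(spec, seed = 2)
#' registerTranslation(case@volumes$T2STAR, case@volumes$ADC)
#' @export
registerTranslation <- function(moving, fixed, searchRadius = 3L) {
  stopifnot(is(moving, "ImageVolume"), is(fixed, "ImageVolume"))
  mv <- moving@values
  fx <- fixed@values
  if (!identical(dim(mv), dim(fx)))
    stop("registration error: grids differ in shape")
  if (sd(mv) == 0 || sd(fx) == 0)
    stop("registration error: zero-variance image")
  r <- as.integer(searchRadius)
  stopifnot(r >= 0L)
  d <- dim(mv)

  best <- NULL
  shifts <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  ncc <- numeric(nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    sh <- as.integer(shifts[s, ])
    ## overlap index ranges after shifting `moving` by sh
    lo <- pmax(1L, 1L + sh)
    hi <- pmin(d, d + sh)
    if (any(lo > hi)) { ncc[s] <- -Inf; next }
    a <- mv[(lo[1] - sh[1]):(hi[1] - sh[1]),
            (lo[2] - sh[2]):(hi[2] - sh[2]),
            (lo[3] - sh[3]):(hi[3] - sh[3])]
    b <- fx[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sa <- sd(a); sb <- sd(b)
    ncc[s] <- if (sa == 0 || sb == 0) -Inf else
      suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
  }
  mag2 <- shifts$dx^2 + shifts$dy^2 + shifts$dz^2
  ord <- order(-ncc, mag2, shifts$dx, shifts$dy, shifts$dz)
  bestRow <- shifts[ord[1], ]
  new("RigidTransform",
      translation = as.integer(c(bestRow$dx, bestRow$dy, bestRow$dz)))
}

#' Apply a rigid integer translation to a volume
#'
#' @param volume an [ImageVolume-class].
#' @param transform a [RigidTransform-class] from [registerTranslation()].
#' @param fill value for voxels shifted in from outside the grid (default:
#'   the volume's minimum).
#' @return Shifted [ImageVolume-class].
#' @export
applyTransform <- function(volume, transform, fill = NULL) {
  stopifnot(is(volume, "ImageVolume"), is(transform, "RigidTransform"))
  if (is.null(fill)) fill <- min(volume@values)
  ImageVolume(shiftArray(volume@values, transform@translation, fill),
              volume@spacing, volume@modality)
}
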