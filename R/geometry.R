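## Deterministic phantom geometry: nested ellipsoid compartments on a
## left-right symmetric brain lattice.

## squared normalized ellipsoid coordinate for every voxel centre
.ellipsoidR2 <- function(gridShape, spacing, center, radii) {
  cx <- ((seq_len(gridShape[1]) - 1) * spacing[1] - center[1]) / radii[1]
  cy <- ((seq_len(gridShape[2]) - 1) * spacing[2] - center[2]) / radii[2]
  cz <- ((seq_len(gridShape[3]) - 1) * spacing[3] - center[3]) / radii[3]
  outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
}

#' Voxelized solid ellipsoid
#'
#' A voxel belongs to the ellipsoid when its centre satisfies
#' `sum(((x - center) / radii)^2) <= 1`.
#'
#' @param gridShape integer(3) lattice dimensions.
#' @param spacing numeric(3) voxel spacing, mm.
#' @param center numeric(3) centre in mm coordinates (voxel `(0,0,0)` sits at
#'   0 mm).
#' @param radii numeric(3) semi-axes, mm.
#' @return 3-D logical array.
#' @export
ellipsoidMask <- function(gridShape, spacing, center, radii) {
  .ellipsoidR2(gridShape, spacing, center, radii) <= 1
}

## grid centre in mm coordinates (also the brain ellipsoid centre)
.gridCenterMM <- function(spec) (spec@gridShape - 1) / 2 * spec@spacing

#' Build the ground-truth compartment geometry of a phantom
#'
#' Deterministically labels every voxel as outside brain, background brain,
#' IPH (solid ellipsoid), PHE (shell of `pheThickness` mm around the IPH) or
#' PDR (shell of `pdrThickness` mm immediately outside the PHE, only when
#' `pdrPresent`). The three lesion compartments are pairwise disjoint by
#' construction. The lesion (including its shells) must lie strictly on one
#' side of the midsagittal plane (the central plane of the first lattice
#' axis) and inside the brain ellipsoid; violations raise a geometry error.
#'
#' @param spec a [PhantomSpec-class].
#' @return Integer 3-D array of label codes (see [truthLabelCodes()]) with a
#'   `"spacing"` attribute.
#' @examples
#' spec <- defaultPhantomSpec(gridShape = c(48L, 48L, 28L))
#' truth <- buildGeometry(spec)
#' table(truth)
#' @export
buildGeometry <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  sp <- spec@spacing
  brain <- ellipsoidMask(gs, sp, .gridCenterMM(spec), spec@brainRadii)

  iph <- ellipsoidMask(gs, sp, spec@iphCenter, spec@iphRadii)
  pheOuter <- ellipsoidMask(gs, sp, spec@iphCenter,
                            spec@iphRadii + spec@pheThickness)
  phe <- pheOuter & !iph
  if (spec@pdrPresent && spec@pdrThickness > 0) {
    pdrOuter <- ellipsoidMask(gs, sp, spec@iphCenter,
                              spec@iphRadii + spec@pheThickness +
                                spec@pdrThickness)
    pdr <- pdrOuter & !pheOuter
  } else {
    pdrOuter <- pheOuter
    pdr <- array(FALSE, gs)
  }
  lesionAll <- iph | phe | pdr

  if (!any(iph))
    stop("geometry error: IPH ellipsoid contains no voxel centre")
  if (any(lesionAll & !brain))
    stop("geometry error: lesion extends outside the brain ellipsoid")
  ## strict laterality: no lesion voxel centre on or across the midsagittal
  ## plane x = (n1 - 1) / 2 * spacing[1]
  xmid <- (gs[1] - 1) / 2 * sp[1]
  xs <- (which(lesionAll, arr.ind = TRUE)[, 1] - 1) * sp[1]
  side <- sign(spec@iphCenter[1] - xmid)
  if (side == 0 || any(sign(xs - xmid) != side))
    stop("geometry error: lesion touches or crosses the midsagittal plane")

  truth <- array(.LABELS[["outside_brain"]], gs)
  truth[brain] <- .LABELS[["background_brain"]]
  truth[iph] <- .LABELS[["iph"]]
  truth[phe] <- .LABELS[["phe"]]
  truth[pdr] <- .LABELS[["pdr"]]
  storage.mode(truth) <- "integer"
  attr(truth, "spacing") <- sp
  truth
}
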