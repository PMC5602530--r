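## Low-level 3-D lattice utilities: array shifting, 26-neighbourhood dilation
## and connected components (Rcpp backend). These operate on plain logical /
## numeric arrays; the user-facing S4 layer wraps them.

#' Shift a 3-D array by integer voxel offsets
#'
#' Voxels shifted in from outside the grid are filled with `fill`.
#'
#' @param a 3-D array.
#' @param shift integer(3) voxel offsets (positive = towards higher indices).
#' @param fill fill value for exposed voxels.
#' @return Array of the same shape.
#' @export
shiftArray <- function(a, shift, fill = 0) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(shift) == 3L)
  shift <- as.integer(round(shift))
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) {
      src[[ax]] <- seq_len(d[ax] - s)
      dst[[ax]] <- seq_len(d[ax] - s) + s
    } else {
      src[[ax]] <- seq_len(d[ax] + s) - s
      dst[[ax]] <- seq_len(d[ax] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## one 26-neighbourhood binary dilation step, vectorized over axis shifts
.dilate1 <- function(mask) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shiftArray(mask, c(dx, dy, dz), FALSE)
  }
  out
}

#' Binary dilation of a 3-D mask (26-connectivity)
#'
#' @param mask 3-D logical array.
#' @param iterations number of one-voxel dilation steps.
#' @return Dilated logical array.
#' @export
dilateMask <- function(mask, iterations = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, iterations >= 0L)
  for (i in seq_len(iterations)) mask <- .dilate1(mask)
  mask
}

#' Binary erosion of a 3-D mask (26-connectivity)
#'
#' @param mask 3-D logical array.
#' @param iterations number of one-voxel erosion steps.
#' @return Eroded logical array.
#' @export
erodeMask <- function(mask, iterations = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, iterations >= 0L)
  for (i in seq_len(iterations)) mask <- !.dilate1(!mask)
  mask
}

## morphological opening (erosion then dilation): removes speckle and thin
## protrusions while preserving bulky structures
.openMask <- function(mask) dilateMask(erodeMask(mask, 1L), 1L)

#' Label connected components of a 3-D binary mask (26-connectivity)
#'
#' @param mask 3-D logical array.
#' @return Integer array of the same shape: 0 background, 1..K component ids
#'   in order of first encounter (column-major).
#' @export
labelComponents <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .cc_label_26(mask, dim(mask))
}

#' Keep the largest connected component of a binary mask
#'
#' @param mask 3-D logical array.
#' @return Logical array containing only the largest 26-connected component
#'   (all-`FALSE` if the mask is empty). Ties are broken by first encounter.
#' @export
largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  if (!any(lab > 0L)) return(array(FALSE, dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim(mask))
}

## drop connected components smaller than minVoxels
.filterComponents <- function(mask, minVoxels) {
  if (!any(mask)) return(mask)
  lab <- labelComponents(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minVoxels)
  array(lab %in% keep & lab > 0L, dim(mask))
}

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b 3-D logical arrays or [RoiMask-class] objects.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "RoiMask")) a <- a@values
  if (is(b, "RoiMask")) b <- b@values
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
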