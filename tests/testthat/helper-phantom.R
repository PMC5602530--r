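## Shared fixtures: a reduced phantom (48 x 48 x 28 at 2 mm) that keeps the
## full compartment structure but runs in a fraction of a second, cached per
## seed so multiple test files can reuse it.

.fixtureCache <- new.env(parent = emptyenv())

smallSpec <- function(...) {
  args <- list(gridShape = c(48L, 48L, 28L), brainRadii = c(44, 44, 25),
               iphCenter = c(67, 47, 27), iphRadii = c(8, 7, 7),
               pheThickness = 5, pdrThickness = 4)
  over <- list(...)
  args[names(over)] <- over
  do.call(defaultPhantomSpec, args)
}

smallCase <- function(seed = 1, pdrPresent = TRUE) {
  key <- sprintf("case_%d_%d", seed, pdrPresent)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makePhantom(smallSpec(pdrPresent = pdrPresent),
                                        seed)
  .fixtureCache[[key]]
}

smallSegmented <- function(seed = 1, pdrPresent = TRUE) {
  key <- sprintf("seg_%d_%d", seed, pdrPresent)
  if (is.null(.fixtureCache[[key]])) {
    case <- smallCase(seed, pdrPresent)
    .fixtureCache[[key]] <- segmentCase(case@volumes, brainMask(case),
                                        pipelineConfig(seed = 0L))
  }
  .fixtureCache[[key]]
}

## tiny uniform-brain scene for hand-constructed threshold tests
flatVolume <- function(value, dims = c(16L, 16L, 8L), spacing = c(1, 1, 1),
                       modality = "ADC") {
  ImageVolume(array(value, dims), spacing, modality)
}

maskFromIndices <- function(idx, dims = c(16L, 16L, 8L), spacing = c(1, 1, 1),
                            label = "PHE") {
  a <- array(FALSE, dims)
  a[idx] <- TRUE
  RoiMask(a, spacing, label)
}
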