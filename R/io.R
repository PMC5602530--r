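## Standard-format I/O: NIfTI-1 volumes and masks (RNifti backend), cohort
## CSV with schema validation, JSON pipeline configuration, and an optional
## SPSS SAV importer.

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param modality modality tag to attach.
#' @return An [ImageVolume-class] with spacing taken from the header pixdim.
#' @export
readVolume <- function(path, modality) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  ImageVolume(vals, RNifti::pixdim(img)[1:3], modality)
}

#' Write a volume as NIfTI-1 (float32)
#'
#' @param volume an [ImageVolume-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  vals <- volume@values
  attr(vals, "pixdim") <- volume@spacing
  RNifti::writeNifti(RNifti::asNifti(vals), path, datatype = "float")
  invisible(path)
}

#' Read a NIfTI-1 mask
#'
#' @param path NIfTI file holding a 0/1 volume.
#' @param label ROI tag to attach.
#' @param spacingRef optional [ImageVolume-class]; when given, the mask
#'   spacing must match it to 1e-6 mm or a mismatch error is raised.
#' @return A [RoiMask-class].
#' @export
readMask <- function(path, label, spacingRef = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (!is.null(spacingRef) && max(abs(sp - imgSpacing(spacingRef))) > 1e-6)
    stop("spacing mismatch between mask and reference volume")
  RoiMask(array(as.numeric(img) != 0, dim(img)), sp, label)
}

#' Write a mask as NIfTI-1 (uint8)
#'
#' @param mask a [RoiMask-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "RoiMask"))
  vals <- array(as.integer(mask@values), dim(mask@values))
  attr(vals, "pixdim") <- mask@spacing
  RNifti::writeNifti(RNifti::asNifti(vals), path, datatype = "uint8")
  invisible(path)
}

#' Read a cohort CSV with schema validation
#'
#' @param path CSV file with the patient-record columns.
#' @param required columns that must be present (default: the analysis
#'   schema). A missing column raises a schema error naming it.
#' @return A `data.frame`.
#' @export
readCohort <- function(path, required = .REQUIRED_COHORT) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: cohort CSV is missing columns: ",
         paste(missing, collapse = ", "))
  for (v in intersect(c("pdr_positive", "removal", "death"), names(df)))
    df[[v]] <- as.logical(df[[v]])
  df
}

#' Write a cohort table as CSV
#'
#' @param cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Import a cohort from an SPSS SAV file
#'
#' Thin wrapper over `foreign::read.spss()`. Because the layout of such
#' supplementary files is undocumented, an explicit `columnMap` from SAV
#' variable names to the patient-record schema is required; the mapped table
#' is then validated like a cohort CSV.
#'
#' @param path SAV file.
#' @param columnMap named character vector: `c(schema_column = "SAV_NAME")`.
#' @return A `data.frame` in the patient-record schema.
#' @export
readCohortSAV <- function(path, columnMap) {
  if (!requireNamespace("foreign", quietly = TRUE))
    stop("package 'foreign' is required for SAV import")
  if (is.null(names(columnMap)) || any(!nzchar(names(columnMap))))
    stop("columnMap must be a named character vector ",
         "(schema_column = \"SAV_NAME\")")
  raw <- foreign::read.spss(path, to.data.frame = TRUE)
  missing <- setdiff(unname(columnMap), names(raw))
  if (length(missing))
    stop("schema error: SAV file is missing variables: ",
         paste(missing, collapse = ", "))
  out <- raw[, unname(columnMap), drop = FALSE]
  names(out) <- names(columnMap)
  out
}

#' Default pipeline configuration
#'
#' All tunable factors of the pipeline with their defaults: the ADC and
#' b1000 mirror-SD threshold factors (1.5 each), the candidate outer-shell
#' thickness (2 voxels), minimum component and positivity volumes (0.05 and
#' 0.1 cc), segmentation factors, the registration search radius, the
#' quantile convention and the rim prevalence used when simulating.
#'
#' @param seed integer seed (mandatory; no wall-clock seeding).
#' @param nCases number of phantom cases to simulate.
#' @param ... overrides for any configuration entry.
#' @return A named list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(seed, nCases = 10L, ...) {
  cfg <- list(seed = as.integer(seed), nCases = as.integer(nCases),
              pdrPrevalence = 0.5, adcSDFactor = 1.5, b1000SDFactor = 1.5,
              shellVoxels = 2L, minComponentCC = 0.05, minPositiveCC = 0.1,
              iphK = 2, lesionK = 2, minIphCC = 0.1, mirrorDilation = 2L,
              mirrorMinVoxels = 50L, searchRadius = 2L, register = FALSE,
              quantileType = 7L, excludePDRfromPHE = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration entries: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (any(unlist(cfg[c("adcSDFactor", "b1000SDFactor")]) <= 0))
    stop("threshold factors must be > 0")
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' The configuration round-trips losslessly.
#'
#' @param config a `pipelineConfig`.
#' @param path JSON path.
#' @return `writeConfig`: `path` invisibly; `readConfig`: the configuration.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, cfg)
}

## small deterministic FNV-1a hash of a serialized object (manifest checksum)
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## multiply mod 2^32 in two 16-bit halves to stay inside double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
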