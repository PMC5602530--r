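#' @rdname ImageVolume-class
#' @param object an object.
#' @export
setGeneric("imgValues", function(object) standardGeneric("imgValues"))

#' @rdname ImageVolume-class
#' @export
setGeneric("imgSpacing", function(object) standardGeneric("imgSpacing"))

#' @rdname ImageVolume-class
#' @export
setGeneric("imgModality", function(object) standardGeneric("imgModality"))

#' @rdname RoiMask-class
#' @param object an object.
#' @export
setGeneric("maskValues", function(object) standardGeneric("maskValues"))

#' @rdname RoiMask-class
#' @export
setGeneric("maskLabel", function(object) standardGeneric("maskLabel"))

#' @rdname RoiMask-class
#' @export
setGeneric("maskNote", function(object) standardGeneric("maskNote"))

#' @rdname RoiMask-class
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
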