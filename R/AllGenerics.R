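#' @rdname ImageVolume-class
#' @param object an object
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname ImageVolume-class
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname Contour-class
#' @param object an object
#' @export
setGeneric("mask", function(object) standardGeneric("mask"))
#' @rdname Contour-class
#' @export
setGeneric("oarType", function(object) standardGeneric("oarType"))
#' @rdname Contour-class
#' @export
setGeneric("setId", function(object) standardGeneric("setId"))
#' @rdname Contour-class
#' @export
setGeneric("truthLabel", function(object) standardGeneric("truthLabel"))
#' @rdname Contour-class
#' @export
setGeneric("errorMeta", function(object) standardGeneric("errorMeta"))

#' @rdname StructureSet-class
#' @param object an object
#' @export
setGeneric("contours", function(object) standardGeneric("contours"))
#' @rdname StructureSet-class
#' @export
setGeneric("contourNames", function(object) standardGeneric("contourNames"))
#' @rdname StructureSet-class
#' @export
setGeneric("imageVolume", function(object) standardGeneric("imageVolume"))
#' @rdname StructureSet-class
#' @export
setGeneric("bodyContour", function(object) standardGeneric("bodyContour"))

#' @rdname OarModelBundle-class
#' @param object an object
#' @export
setGeneric("featureStats", function(object) standardGeneric("featureStats"))
#' @rdname OarModelBundle-class
#' @export
setGeneric("ccrBounds", function(object) standardGeneric("ccrBounds"))
#' @rdname OarModelBundle-class
#' @export
setGeneric("partsThreshold", function(object) standardGeneric("partsThreshold"))
#' @rdname OarModelBundle-class
#' @export
setGeneric("tunedThresholds", function(object) standardGeneric("tunedThresholds"))
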