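# Constructors, accessors and show methods

#' Create an ImageVolume
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin physical position (mm) of the first voxel center.
#' @return an \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a Contour
#'
#' @param mask 3D logical array.
#' @param oarType canonical OAR label.
#' @param setId structure-set identifier.
#' @param truthLabel optional "acceptable"/"erroneous".
#' @param errorMeta optional list describing an injected error.
#' @return a \linkS4class{Contour}.
#' @export
Contour <- function(mask, oarType, setId = "", truthLabel = NA_character_,
                    errorMeta = list()) {
  storage.mode(mask) <- "logical"
  new("Contour", mask = mask, oarType = oarType, setId = setId,
      truthLabel = truthLabel, errorMeta = errorMeta)
}

#' Create a StructureSet
#'
#' @param contours list of \linkS4class{Contour} (named by OAR type, or names
#'   are taken from the contours themselves).
#' @param image optional \linkS4class{ImageVolume}.
#' @param body optional body \linkS4class{Contour}.
#' @param setId set identifier.
#' @return a \linkS4class{StructureSet}.
#' @export
StructureSet <- function(contours = list(), image = NULL, body = NULL,
                         setId = "") {
  if (length(contours) && is.null(names(contours)))
    names(contours) <- vapply(contours, oarType, character(1))
  new("StructureSet", contours = contours, image = image, body = body,
      setId = setId)
}

#' @rdname ImageVolume-class
#' @export
setMethod("voxels", "ImageVolume", function(object) object@voxels)
#' @rdname ImageVolume-class
#' @export
setMethod("voxelSpacing", "ImageVolume", function(object) object@spacing)
#' @rdname ImageVolume-class
#' @export
setMethod("gridOrigin", "ImageVolume", function(object) object@origin)

#' @rdname Contour-class
#' @export
setMethod("mask", "Contour", function(object) object@mask)
#' @rdname Contour-class
#' @export
setMethod("oarType", "Contour", function(object) object@oarType)
#' @rdname Contour-class
#' @export
setMethod("setId", "Contour", function(object) object@setId)
#' @rdname Contour-class
#' @export
setMethod("truthLabel", "Contour", function(object) object@truthLabel)
#' @rdname Contour-class
#' @export
setMethod("errorMeta", "Contour", function(object) object@errorMeta)

#' @rdname StructureSet-class
#' @export
setMethod("contours", "StructureSet", function(object) object@contours)
#' @rdname StructureSet-class
#' @export
setMethod("contourNames", "StructureSet", function(object) names(object@contours))
#' @rdname StructureSet-class
#' @export
setMethod("imageVolume", "StructureSet", function(object) object@image)
#' @rdname StructureSet-class
#' @export
setMethod("bodyContour", "StructureSet", function(object) object@body)
#' @rdname StructureSet-class
#' @export
setMethod("setId", "StructureSet", function(object) object@setId)

#' @rdname StructureSet-class
#' @param x a StructureSet
#' @param name OAR type
#' @export
setMethod("$", "StructureSet", function(x, name) x@contours[[name]])
#' @rdname StructureSet-class
#' @param i index or OAR type
#' @export
setMethod("[[", "StructureSet", function(x, i) x@contours[[i]])
#' @rdname StructureSet-class
#' @export
setMethod("length", "StructureSet", function(x) length(x@contours))

#' @rdname OarModelBundle-class
#' @export
setMethod("oarType", "OarModelBundle", function(object) object@oarType)
#' @rdname OarModelBundle-class
#' @export
setMethod("featureStats", "OarModelBundle", function(object) object@featureStats)
#' @rdname OarModelBundle-class
#' @export
setMethod("ccrBounds", "OarModelBundle", function(object) object@ccrBounds)
#' @rdname OarModelBundle-class
#' @export
setMethod("partsThreshold", "OarModelBundle", function(object) object@partsThreshold)
#' @rdname OarModelBundle-class
#' @export
setMethod("tunedThresholds", "OarModelBundle", function(object) object@tunedThresholds)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat("ImageVolume:", paste(d, collapse = " x "),
      "voxels, spacing", paste(signif(object@spacing, 4), collapse = "/"),
      "mm\n  HU range:", paste(signif(range(object@voxels), 4), collapse = " .. "), "\n")
})

setMethod("show", "Contour", function(object) {
  cat("Contour '", object@oarType, "' (set ", object@setId, "): ",
      sum(object@mask), " voxels", sep = "")
  if (!is.na(object@truthLabel)) cat(" [", object@truthLabel, "]", sep = "")
  if (length(object@errorMeta))
    cat(" <", object@errorMeta$category, "/", object@errorMeta$severity, ">", sep = "")
  cat("\n")
})

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet '", object@setId, "': ", length(object@contours),
      " contours", sep = "")
  if (!is.null(object@image)) cat(" + image")
  if (!is.null(object@body)) cat(" + body")
  cat("\n  ", paste(names(object@contours), collapse = ", "), "\n")
})

setMethod("show", "CcrBound", function(object) {
  cat("CcrBound ", object@selectedOar, " -> ", object@comparisonOar, " [",
      object@feature, "]: [", signif(object@lower, 4), ", ",
      signif(object@upper, 4), "]\n", sep = "")
})

setMethod("show", "OarModelBundle", function(object) {
  cat("OarModelBundle '", object@oarType, "': ", length(object@featureNames),
      " features, ", length(object@ccrBounds), " CCR bounds, max parts ",
      object@partsThreshold$max_parts %||% NA, "\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
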