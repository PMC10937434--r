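#' @useDynLib ContourQA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cov mahalanobis median sd cor quantile qgamma qbeta pbinom dbinom rnorm runif setNames predict
#' @importFrom utils read.csv write.csv head
NULL

#' ImageVolume: a 3D scalar image on a regular grid
#'
#' Holds a CT (or other scalar) volume in Hounsfield units together with its
#' voxel spacing and physical origin. The coordinate convention is positive x
#' lateral, positive y vertical (anterior-posterior), positive z longitudinal
#' (inferior-superior); the center of voxel (1,1,1) sits at \code{origin}.
#'
#' @slot voxels 3D numeric array of voxel values (HU).
#' @slot spacing numeric(3), voxel spacing in mm (dx, dy, dz), all > 0.
#' @slot origin numeric(3), physical position (mm) of the first voxel center.
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be three finite numbers")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "'voxels' must be finite")
  if (length(msg)) msg else TRUE
})

#' Contour: one organ-at-risk delineation as a 3D binary mask
#'
#' @slot mask 3D logical array on the grid of its parent image.
#' @slot oarType canonical OAR label, e.g. \code{"brainstem"}, \code{"parotid_l"}.
#' @slot setId identifier of the structure set (patient) the contour belongs to.
#' @slot truthLabel \code{"acceptable"}, \code{"erroneous"}, or \code{NA} when unknown.
#' @slot errorMeta list with elements \code{category} (one of \code{boundary},
#'   \code{volume}, \code{nonadjacent_slice}, \code{position}) and
#'   \code{severity} (\code{moderate}/\code{major}) for injected errors;
#'   empty otherwise.
#' @export
setClass("Contour",
  representation(mask = "array", oarType = "character", setId = "character",
                 truthLabel = "character", errorMeta = "list"),
  prototype(truthLabel = NA_character_, errorMeta = list(), setId = ""))

setValidity("Contour", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "'mask' must be a 3D logical array")
  if (length(object@oarType) != 1L || !nzchar(object@oarType))
    msg <- c(msg, "'oarType' must be a non-empty string")
  if (!is.na(object@truthLabel) &&
      !object@truthLabel %in% c("acceptable", "erroneous"))
    msg <- c(msg, "'truthLabel' must be 'acceptable', 'erroneous' or NA")
  if (length(msg)) msg else TRUE
})

#' StructureSet: one patient's collection of contours
#'
#' @slot contours named list of \linkS4class{Contour}, keyed by OAR type
#'   (at most one contour per type).
#' @slot image optional \linkS4class{ImageVolume} (or \code{NULL}).
#' @slot body optional body \linkS4class{Contour} (or \code{NULL}) used by
#'   contour-to-body relationship checks.
#' @slot setId set identifier.
#' @export
setClass("StructureSet",
  representation(contours = "list", image = "ANY", body = "ANY",
                 setId = "character"),
  prototype(image = NULL, body = NULL, setId = ""))

setValidity("StructureSet", function(object) {
  msg <- character()
  nm <- names(object@contours)
  if (length(object@contours)) {
    if (is.null(nm) || any(!nzchar(nm)))
      msg <- c(msg, "'contours' must be a named list keyed by oarType")
    if (anyDuplicated(nm))
      msg <- c(msg, "at most one contour per oarType")
    ok <- vapply(object@contours, is, logical(1), class2 = "Contour")
    if (!all(ok)) msg <- c(msg, "'contours' must contain Contour objects")
  }
  if (!is.null(object@image) && !is(object@image, "ImageVolume"))
    msg <- c(msg, "'image' must be NULL or an ImageVolume")
  if (!is.null(object@body) && !is(object@body, "Contour"))
    msg <- c(msg, "'body' must be NULL or a Contour")
  if (length(msg)) msg else TRUE
})

#' CcrBound: fitted acceptance interval for one contour-pair feature
#'
#' A contour-to-contour relationship (CCR) bound stores the fitted
#' distribution (gamma for minimum distance, beta for fractional overlap) and
#' the expanded two-sided acceptance interval for one (selected, comparison)
#' OAR pair.
#'
#' @slot selectedOar selected (row) OAR type.
#' @slot comparisonOar comparison (column) OAR type; may be \code{"body"}.
#' @slot feature \code{"min_distance"} or \code{"fractional_overlap"}.
#' @slot params numeric(2): gamma (shape, scale) or beta (alpha, beta);
#'   \code{NA} for degenerate point-mass fits.
#' @slot lower,upper acceptance interval after expansion and domain clipping.
#' @export
setClass("CcrBound",
  representation(selectedOar = "character", comparisonOar = "character",
                 feature = "character", params = "numeric",
                 lower = "numeric", upper = "numeric"))

setValidity("CcrBound", function(object) {
  msg <- character()
  if (!object@feature %in% c("min_distance", "fractional_overlap"))
    msg <- c(msg, "'feature' must be 'min_distance' or 'fractional_overlap'")
  if (object@lower > object@upper)
    msg <- c(msg, "'lower' must be <= 'upper'")
  if (object@lower < 0)
    msg <- c(msg, "bounds must be clipped to the feature domain (>= 0)")
  if (object@feature == "fractional_overlap" && object@upper > 1)
    msg <- c(msg, "fractional_overlap bounds must be clipped to [0, 1]")
  if (length(msg)) msg else TRUE
})

#' OarModelBundle: all trained artifacts for one OAR type
#'
#' @slot oarType OAR type the bundle was trained for.
#' @slot featureNames ordered names of the 20 single-contour features.
#' @slot featureStats data.frame with per-feature \code{mean}, \code{sd},
#'   \code{median} and unscaled \code{mad} from the filtered training set.
#' @slot mdModel list with \code{mean}, \code{cov} (shrunk) and \code{covInv}.
#' @slot repEigenvectors list with unit vectors \code{pc1} and \code{pc2}:
#'   the representative eigenvectors used to sign-standardize orientations.
#' @slot aeModel list with autoencoder weights \code{W1}, \code{b1},
#'   \code{W2}, \code{b2} plus training configuration.
#' @slot ccrBounds list of \linkS4class{CcrBound} for pairs where this OAR is
#'   the selected contour (may be empty).
#' @slot partsThreshold list with \code{max_parts} and optional fitted gamma
#'   \code{params}.
#' @slot tunedThresholds named numeric: decision thresholds for
#'   \code{zscore}, \code{md}, \code{ae} (solo and \code{*_combined}).
#' @export
setClass("OarModelBundle",
  representation(oarType = "character", featureNames = "character",
                 featureStats = "data.frame", mdModel = "list",
                 repEigenvectors = "list", aeModel = "list",
                 ccrBounds = "list", partsThreshold = "list",
                 tunedThresholds = "numeric"),
  prototype(ccrBounds = list(), tunedThresholds = numeric()))

setValidity("OarModelBundle", function(object) {
  msg <- character()
  if (length(object@featureNames) != nrow(object@featureStats))
    msg <- c(msg, "featureStats must have one row per feature")
  if (nrow(object@featureStats) && any(object@featureStats$sd < 0))
    msg <- c(msg, "feature sd must be >= 0")
  if (!is.null(object@mdModel$cov)) {
    S <- object@mdModel$cov
    if (max(abs(S - t(S))) > 1e-8) msg <- c(msg, "covariance must be symmetric")
  }
  for (nm in c("pc1", "pc2")) {
    v <- object@repEigenvectors[[nm]]
    if (!is.null(v) && abs(sqrt(sum(v^2)) - 1) > 1e-6)
      msg <- c(msg, sprintf("representative eigenvector '%s' must be unit length", nm))
  }
  if (!is.null(object@partsThreshold$max_parts) &&
      object@partsThreshold$max_parts < 1)
    msg <- c(msg, "max_parts must be >= 1")
  ok <- vapply(object@ccrBounds, is, logical(1), class2 = "CcrBound")
  if (length(ok) && !all(ok))
    msg <- c(msg, "'ccrBounds' must contain CcrBound objects")
  if (length(msg)) msg else TRUE
})
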