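# Single-contour feature extraction and pairwise (CCR) features.
#
# The 20 single-contour features: centroid relative to the brainstem
# (pituitary for the brainstem itself), raw first/second principal-component
# eigenvector components, volume, covariance eigenvalue ratios, per-axis
# extents, sphericity, and four CT statistics. All geometry is computed on
# voxel-center coordinates in mm so anisotropic slices do not distort
# orientation features.

#' Names of the 20 single-contour features, in canonical order
#'
#' @return character vector of length 20.
#' @export
featureNames <- function() {
  c("centroid_x", "centroid_y", "centroid_z",
    "pc1_x", "pc1_y", "pc1_z", "pc2_x", "pc2_y", "pc2_z",
    "volume_cc", "lambda2_ratio", "lambda3_ratio",
    "extent_x", "extent_y", "extent_z", "sphericity",
    "ct_min", "ct_max", "ct_mean", "ct_std")
}

#' Contour centroid relative to the set's reference structure
#'
#' The mask centroid (mean of occupied voxel centers, in mm) minus the
#' centroid of the reference contour: the brainstem for every OAR except the
#' brainstem itself, which is referenced to the pituitary. This removes
#' patient-to-patient differences in image coordinates.
#'
#' @param contour a \linkS4class{Contour}.
#' @param structureSet the parent \linkS4class{StructureSet}.
#' @param refOar reference OAR type (default \code{"brainstem"}).
#' @param refOarForReference reference used when \code{contour} is itself the
#'   reference structure (default \code{"pituitary"}); set \code{NA} to
#'   disable and return the raw offset to itself (zero).
#' @param spacing,origin grid geometry in mm.
#' @return numeric(3) centroid offset in mm.
#' @export
relativeCentroid <- function(contour, structureSet, refOar = "brainstem",
                             refOarForReference = "pituitary",
                             spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  ref <- refOar
  if (identical(oarType(contour), refOar) && !is.na(refOarForReference))
    ref <- refOarForReference
  refContour <- contours(structureSet)[[ref]]
  if (is.null(refContour))
    stop("reference contour '", ref, "' missing from structure set '",
         setId(structureSet), "'")
  c0 <- colMeans(voxelCoords(mask(contour), spacing, origin))
  cr <- colMeans(voxelCoords(mask(refContour), spacing, origin))
  as.numeric(c0 - cr)
}

#' Per-axis extent of a mask in mm
#'
#' Difference between the largest and smallest occupied voxel-center
#' coordinate on each axis (a single-voxel contour has zero extent).
#'
#' @inheritParams relativeCentroid
#' @return numeric(3) extents (mm).
#' @export
maskExtents <- function(contour, spacing = c(1, 1, 1)) {
  idx <- which(mask(contour), arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  (apply(idx, 2, max) - apply(idx, 2, min)) * spacing
}

#' Principal-component shape and orientation features
#'
#' Eigendecomposition of the covariance of occupied voxel-center coordinates
#' (mm). Eigenvalues are sorted descending; eigenvectors are unit length with
#' arbitrary sign (sign standardization against the per-OAR representative
#' eigenvector happens at model training/inference).
#'
#' @inheritParams relativeCentroid
#' @return list with \code{pc1}, \code{pc2}, \code{pc3} (unit vectors),
#'   \code{lambda} (eigenvalues), \code{lambda2_ratio}, \code{lambda3_ratio}.
#' @export
pcaShapeOrientation <- function(contour, spacing = c(1, 1, 1)) {
  xyz <- voxelCoords(mask(contour), spacing)
  if (nrow(xyz) < 3) stop("PCA requires at least 3 voxels")
  e <- eigen(cov(xyz), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[1] <= 0) {
    warning("rank-deficient voxel cloud; eigenvalue ratios set to 0")
    r2 <- r3 <- 0
  } else {
    r2 <- lam[2] / lam[1]
    r3 <- lam[3] / lam[1]
  }
  list(pc1 = e$vectors[, 1], pc2 = e$vectors[, 2], pc3 = e$vectors[, 3],
       lambda = lam, lambda2_ratio = r2, lambda3_ratio = r3)
}

#' Representative eigenvector of a set of unit vectors
#'
#' Returns the member maximizing the summed absolute dot product with all
#' other members; ties are broken by lowest index. Used to define a stable
#' per-OAR reference direction for sign standardization.
#'
#' @param vectors matrix with one unit vector per row (or a list of vectors).
#' @return the representative unit vector.
#' @export
representativeEigenvector <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  n <- nrow(vectors)
  if (!n) stop("empty set of vectors")
  if (n == 1) return(as.numeric(vectors[1, ]))
  G <- abs(vectors %*% t(vectors))
  score <- rowSums(G) - diag(G)
  as.numeric(vectors[which.max(score), ])
}

#' Sign-standardize an eigenvector against a representative direction
#'
#' @param v unit vector.
#' @param r representative unit vector.
#' @return \code{v} if \code{sum(v * r) >= 0}, else \code{-v}.
#' @export
orientEigenvector <- function(v, r) {
  if (sum(v * r) >= 0) v else -v
}

#' Sphericity of a mask
#'
#' Wadell sphericity \eqn{\pi^{1/3} (6V)^{2/3} / A} with \eqn{V} the voxel
#' volume and \eqn{A} the area of an iso-surface mesh of the mask; 1 for a
#' perfect sphere, smaller for less compact shapes.
#'
#' @inheritParams relativeCentroid
#' @return sphericity value.
#' @export
sphericity <- function(contour, spacing = c(1, 1, 1)) {
  m <- mask(contour)
  nv <- sum(m)
  if (!nv) stop("empty mask")
  V <- nv * prod(spacing)
  if (nv == 1) {
    A <- 2 * (spacing[1] * spacing[2] + spacing[2] * spacing[3] +
              spacing[1] * spacing[3])
  } else {
    A <- maskSurfaceArea(m, spacing)
  }
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' CT intensity statistics within a contour
#'
#' @param contour a \linkS4class{Contour}.
#' @param image the co-registered \linkS4class{ImageVolume}.
#' @return named numeric: \code{ct_min}, \code{ct_max}, \code{ct_mean},
#'   \code{ct_std} (sample standard deviation; 0 for a single voxel).
#' @export
ctStatistics <- function(contour, image) {
  if (is.null(image)) stop("no image attached")
  v <- voxels(image)[mask(contour)]
  if (!length(v)) stop("empty mask")
  s <- if (length(v) > 1) sd(v) else 0
  c(ct_min = min(v), ct_max = max(v), ct_mean = mean(v), ct_std = s)
}

#' Number of disconnected parts of a mask (26-connectivity)
#'
#' @param contour a \linkS4class{Contour} (or a 3D logical array).
#' @return integer count >= 1 for a nonempty mask.
#' @export
countParts <- function(contour) {
  m <- if (is(contour, "Contour")) mask(contour) else contour
  attr(labelComponents(m), "n_components")
}

#' Minimum surface distance between two contours in mm
#'
#' Zero when the masks intersect; otherwise the minimum Euclidean distance
#' between boundary-voxel centers. Sub-voxel surface distance is not
#' attempted.
#'
#' @param a,b \linkS4class{Contour}s on the same grid.
#' @param spacing voxel spacing in mm.
#' @return distance in mm (>= 0).
#' @export
minSurfaceDistance <- function(a, b, spacing = c(1, 1, 1)) {
  ma <- mask(a); mb <- mask(b)
  if (!identical(dim(ma), dim(mb))) stop("contours are on different grids")
  if (any(ma & mb)) return(0)
  pa <- voxelCoords(boundaryMask(ma), spacing)
  pb <- voxelCoords(boundaryMask(mb), spacing)
  if (!nrow(pa) || !nrow(pb)) stop("empty mask")
  .cq_min_dist(pa, pb)
}

#' Directional fractional overlap of one contour with another
#'
#' Fraction of the selected contour's volume that lies inside the comparison
#' contour (rows of the CCR matrix correspond to the selected contour).
#'
#' @param selected,comparison \linkS4class{Contour}s on the same grid.
#' @return fraction in [0, 1].
#' @export
fractionalOverlap <- function(selected, comparison) {
  ms <- mask(selected); mc <- mask(comparison)
  if (!identical(dim(ms), dim(mc))) stop("contours are on different grids")
  sum(ms & mc) / sum(ms)
}

#' Extract the single-contour feature table for a structure set
#'
#' One row per contour with the 20 features of \code{\link{featureNames}} in
#' fixed order, plus \code{set_id}, \code{oar_type}, \code{truth},
#' \code{category}, \code{severity} metadata and the disconnected
#' \code{parts} count used by the connectedness model. Eigenvector components
#' are stored with raw signs; standardization is deferred to training and
#' inference where the representative eigenvectors live. When no image is
#' attached, CT features are \code{NA} (imputed to the training mean at
#' inference).
#'
#' @param structureSet a \linkS4class{StructureSet}.
#' @param spacing voxel spacing in mm.
#' @param refOar,refOarForReference see \code{\link{relativeCentroid}}.
#' @return data.frame, one row per contour.
#' @export
extractFeatures <- function(structureSet, spacing = c(1, 1, 1),
                            refOar = "brainstem",
                            refOarForReference = "pituitary") {
  img <- imageVolume(structureSet)
  rows <- lapply(contours(structureSet), function(ct) {
    out <- try({
      cen <- relativeCentroid(ct, structureSet, refOar, refOarForReference,
                              spacing = spacing)
      p <- pcaShapeOrientation(ct, spacing)
      ext <- maskExtents(ct, spacing)
      vol <- sum(mask(ct)) * prod(spacing) / 1000
      sph <- sphericity(ct, spacing)
      cts <- if (!is.null(img)) ctStatistics(ct, img)
             else c(ct_min = NA_real_, ct_max = NA_real_,
                    ct_mean = NA_real_, ct_std = NA_real_)
      meta <- errorMeta(ct)
      data.frame(set_id = setId(structureSet), oar_type = oarType(ct),
                 truth = truthLabel(ct),
                 category = meta$category %||% NA_character_,
                 severity = meta$severity %||% NA_character_,
                 centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3],
                 pc1_x = p$pc1[1], pc1_y = p$pc1[2], pc1_z = p$pc1[3],
                 pc2_x = p$pc2[1], pc2_y = p$pc2[2], pc2_z = p$pc2[3],
                 volume_cc = vol,
                 lambda2_ratio = p$lambda2_ratio,
                 lambda3_ratio = p$lambda3_ratio,
                 extent_x = ext[1], extent_y = ext[2], extent_z = ext[3],
                 sphericity = sph,
                 ct_min = cts[["ct_min"]], ct_max = cts[["ct_max"]],
                 ct_mean = cts[["ct_mean"]], ct_std = cts[["ct_std"]],
                 parts = countParts(ct),
                 stringsAsFactors = FALSE)
    }, silent = TRUE)
    if (inherits(out, "try-error")) {
      warning("feature extraction failed for '", oarType(ct), "' in set '",
              setId(structureSet), "': ", attr(out, "condition")$message)
      return(NULL)
    }
    out
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Extract CCR pair features for a structure set
#'
#' For every TRUE cell of the CCR matrix whose selected and comparison
#' contours are present, computes minimum surface distance and directional
#' fractional overlap. The column \code{"body"} compares against the set's
#' body contour.
#'
#' @param structureSet a \linkS4class{StructureSet}.
#' @param ccrMatrix logical matrix, rows = selected OAR types, columns =
#'   comparison OAR types (optionally including \code{"body"}).
#' @param spacing voxel spacing in mm.
#' @return data.frame `set_id, selected, comparison, min_distance,
#'   fractional_overlap`.
#' @export
extractPairFeatures <- function(structureSet, ccrMatrix,
                                spacing = c(1, 1, 1)) {
  cts <- contours(structureSet)
  body <- bodyContour(structureSet)
  out <- list()
  for (sel in intersect(rownames(ccrMatrix), names(cts))) {
    for (comp in colnames(ccrMatrix)[which(ccrMatrix[sel, ])]) {
      compContour <- if (comp == "body") body else cts[[comp]]
      if (is.null(compContour) || comp == sel) next
      d <- minSurfaceDistance(cts[[sel]], compContour, spacing)
      f <- fractionalOverlap(cts[[sel]], compContour)
      out[[length(out) + 1L]] <- data.frame(
        set_id = setId(structureSet), selected = sel, comparison = comp,
        min_distance = d, fractional_overlap = f, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(set_id = character(), selected = character(),
                      comparison = character(), min_distance = numeric(),
                      fractional_overlap = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greedy removal of strongly correlated features
#'
#' While any pair of retained features has \code{|Pearson r| > threshold},
#' drops the member of the worst pair with the larger mean absolute
#' correlation to all other retained features. Constant columns have
#' undefined correlation, treated as 0.
#'
#' @param featureTable data.frame or matrix of numeric feature columns.
#' @param threshold absolute-correlation threshold (default 0.7).
#' @return character vector of retained feature names.
#' @export
pruneCorrelated <- function(featureTable, threshold = 0.7) {
  X <- as.matrix(featureTable)
  if (nrow(X) < 2) stop("need at least 2 rows")
  keep <- colnames(X)
  suppressWarnings(R <- abs(cor(X)))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  while (TRUE) {
    sub <- R[keep, keep, drop = FALSE]
    if (!length(sub) || max(sub) <= threshold) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    cand <- keep[c(w[1], w[2])]
    meanAbs <- rowMeans(sub[cand, , drop = FALSE])
    drop <- cand[which.max(meanAbs)]
    keep <- setdiff(keep, drop)
  }
  keep
}
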