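# Readers/writers: NIfTI label volumes and mask files, model-bundle
# persistence (JSON, full double precision), feature/report CSV.

BUNDLE_FORMAT <- "contourqa_bundle_v1"

#' Load a structure set from a NIfTI label volume
#'
#' Reads a co-registered integer label volume and splits it into one binary
#' mask per label, mapping label values to canonical OAR types through a
#' user-supplied alias table (labels in a volume are disjoint by
#' construction; nested organs require per-OAR mask files, see
#' \code{\link{readCorpusSet}}). Voxel spacing is taken from the NIfTI
#' header. Unknown labels are skipped with a warning; empty labels are
#' skipped with a warning.
#'
#' @param labelPath path to a NIfTI label volume.
#' @param aliasTable named vector or two-column data.frame mapping label
#'   value to OAR type (e.g. \code{c(`1` = "brainstem", `2` = "cord")}).
#' @param imagePath optional path to the co-registered CT NIfTI.
#' @param setId set identifier (defaults to the file name).
#' @return a \linkS4class{StructureSet}; attribute \code{"spacing"} carries
#'   the voxel spacing in mm.
#' @export
readStructureSet <- function(labelPath, aliasTable, imagePath = NULL,
                             setId = NULL) {
  if (!file.exists(labelPath)) stop("label volume not found: ", labelPath)
  nii <- RNifti::readNifti(labelPath)
  lab <- array(as.integer(round(as.array(nii))), dim = dim(nii))
  sp <- RNifti::pixdim(nii)
  if (length(sp) < 3 || any(sp[1:3] <= 0))
    stop("label volume has no usable voxel geometry")
  sp <- sp[1:3]
  if (is.data.frame(aliasTable))
    aliasTable <- setNames(as.character(aliasTable[[2]]),
                           as.character(aliasTable[[1]]))
  if (is.null(setId))
    setId <- sub("\\.nii(\\.gz)?$", "", basename(labelPath))
  img <- NULL
  if (!is.null(imagePath)) {
    ii <- RNifti::readNifti(imagePath)
    img <- ImageVolume(array(as.numeric(ii), dim = dim(ii)), spacing = sp)
  }
  cts <- list()
  for (lv in sort(setdiff(unique(as.vector(lab)), 0L))) {
    nm <- unname(aliasTable[as.character(lv)])
    if (length(nm) != 1 || is.na(nm)) {
      warning("unknown label ", lv, "; skipped")
      next
    }
    m <- lab == lv
    if (!sum(m)) {
      warning("label ", lv, " ('", nm, "') is empty; skipped")
      next
    }
    cts[[nm]] <- Contour(m, nm, setId = setId)
  }
  out <- StructureSet(contours = cts, image = img, setId = setId)
  attr(out, "spacing") <- sp
  out
}

# ---- bundle persistence ----------------------------------------------

bundleToList <- function(bundle) {
  list(format = BUNDLE_FORMAT,
       oar_type = bundle@oarType,
       feature_names = bundle@featureNames,
       feature_stats = bundle@featureStats,
       md_model = list(mean = bundle@mdModel$mean,
                       cov = as.vector(bundle@mdModel$cov),
                       cov_inv = as.vector(bundle@mdModel$covInv),
                       d = length(bundle@mdModel$mean)),
       rep_eigenvectors = bundle@repEigenvectors,
       ae_model = bundle@aeModel[c("W1", "b1", "W2", "b2", "hidden", "decay",
                                   "maxit", "seed", "value", "features")],
       ccr_bounds = lapply(bundle@ccrBounds, function(b)
         list(selected = b@selectedOar, comparison = b@comparisonOar,
              feature = b@feature, params = b@params,
              lower = b@lower, upper = b@upper)),
       parts_threshold = bundle@partsThreshold,
       tuned_thresholds = as.list(bundle@tunedThresholds))
}

listToBundle <- function(x) {
  if (is.null(x$format) || !identical(x$format, BUNDLE_FORMAT))
    stop("bundle format mismatch: expected '", BUNDLE_FORMAT, "', found '",
         x$format %||% "<none>", "'")
  d <- x$md_model$d
  fs <- as.data.frame(x$feature_stats, stringsAsFactors = FALSE)
  ae <- x$ae_model
  if (!is.null(ae$W1)) {
    ae$W1 <- matrix(as.numeric(unlist(ae$W1)), ncol = ae$hidden)
    ae$W2 <- matrix(as.numeric(unlist(ae$W2)), ncol = length(ae$features))
    ae$b1 <- as.numeric(ae$b1); ae$b2 <- as.numeric(ae$b2)
    ae$features <- as.character(ae$features)
  }
  fn <- as.character(x$feature_names)
  mu <- as.numeric(unlist(x$md_model$mean))
  names(mu) <- fn
  dn <- list(fn, fn)
  th <- unlist(x$tuned_thresholds)
  new("OarModelBundle",
      oarType = x$oar_type,
      featureNames = fn,
      featureStats = fs,
      mdModel = list(mean = mu,
                     cov = matrix(as.numeric(unlist(x$md_model$cov)), d, d,
                                  dimnames = dn),
                     covInv = matrix(as.numeric(unlist(x$md_model$cov_inv)),
                                     d, d, dimnames = dn)),
      repEigenvectors = lapply(x$rep_eigenvectors, as.numeric),
      aeModel = ae,
      ccrBounds = lapply(x$ccr_bounds, function(b)
        new("CcrBound", selectedOar = b$selected, comparisonOar = b$comparison,
            feature = b$feature, params = as.numeric(b$params),
            lower = as.numeric(b$lower), upper = as.numeric(b$upper))),
      partsThreshold = list(
        max_parts = as.integer(x$parts_threshold$max_parts),
        params = if (length(x$parts_threshold$params))
          unlist(x$parts_threshold$params) else NULL,
        quantile = x$parts_threshold$quantile),
      tunedThresholds = if (length(th)) {
        th <- setNames(as.numeric(th), names(th)); th
      } else numeric())
}

#' Save / load an OAR model bundle (JSON, exact round trip)
#'
#' Scalars and arrays are serialized at full double precision, so a
#' save/load round trip reproduces classification output exactly.
#'
#' @param bundle an \linkS4class{OarModelBundle}.
#' @param path JSON file path.
#' @return \code{loadBundle} returns the \linkS4class{OarModelBundle}.
#' @export
saveBundle <- function(bundle, path) {
  # I(17) significant digits: doubles survive the round trip bitwise
  jsonlite::write_json(bundleToList(bundle), path, digits = I(17),
                       auto_unbox = TRUE, null = "null",
                       dataframe = "columns")
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  x <- try(jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = TRUE), silent = TRUE)
  if (inherits(x, "try-error"))
    stop("cannot parse bundle file '", path, "': ",
         attr(x, "condition")$message)
  listToBundle(x)
}

# ---- corpus on disk ---------------------------------------------------

#' Write a phantom corpus to disk
#'
#' One directory per structure set holding the synthetic CT
#' (\code{ct.nii.gz}) and one NIfTI mask per contour (lossless for nested
#' organs), plus a corpus-level manifest CSV
#' (\code{set_id,oar_type,truth_label,category,severity,file}).
#'
#' @param sets list of \linkS4class{StructureSet}s, or a generator function
#'   \code{function(i) StructureSet} called for \code{i = 1..n} (memory
#'   friendly).
#' @param dir output directory (must be empty or absent unless
#'   \code{force}).
#' @param n number of sets when \code{sets} is a generator.
#' @param force overwrite a non-empty directory.
#' @return the manifest data.frame, invisibly.
#' @export
writeCorpus <- function(sets, dir, n = length(sets), force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory '", dir, "' is not empty (use force = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    ss <- if (is.function(sets)) sets(i) else sets[[i]]
    sdir <- file.path(dir, setId(ss))
    dir.create(sdir, showWarnings = FALSE)
    sp <- if (!is.null(imageVolume(ss))) voxelSpacing(imageVolume(ss)) else c(1, 1, 1)
    writeNii <- function(arr, path) {
      img <- RNifti::asNifti(arr, reference = NULL)
      RNifti::pixdim(img) <- sp
      RNifti::writeNifti(img, path)
    }
    if (!is.null(imageVolume(ss)))
      writeNii(voxels(imageVolume(ss)), file.path(sdir, "ct.nii.gz"))
    if (!is.null(bodyContour(ss)))
      writeNii(mask(bodyContour(ss)) * 1L, file.path(sdir, "body.nii.gz"))
    for (ct in contours(ss)) {
      f <- file.path(sdir, paste0(oarType(ct), ".nii.gz"))
      writeNii(mask(ct) * 1L, f)
      meta <- errorMeta(ct)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = setId(ss), oar_type = oarType(ct),
        truth_label = truthLabel(ct),
        category = meta$category %||% NA_character_,
        severity = meta$severity %||% NA_character_,
        file = file.path(setId(ss), basename(f)),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one structure set of an on-disk corpus
#'
#' @param dir corpus directory written by \code{\link{writeCorpus}}.
#' @param id set identifier (subdirectory name).
#' @return a \linkS4class{StructureSet}.
#' @export
readCorpusSet <- function(dir, id) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  rows <- manifest[manifest$set_id == id, , drop = FALSE]
  if (!nrow(rows)) stop("set '", id, "' not in manifest")
  sdir <- file.path(dir, id)
  sp <- NULL
  readMask <- function(path) {
    nii <- RNifti::readNifti(path)
    if (is.null(sp)) sp <<- RNifti::pixdim(nii)[1:3]
    array(as.array(nii) > 0.5, dim = dim(nii))
  }
  cts <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    meta <- if (!is.na(r$category))
      list(category = r$category, severity = r$severity) else list()
    cts[[r$oar_type]] <- Contour(readMask(file.path(dir, r$file)), r$oar_type,
                                 setId = id, truthLabel = r$truth_label,
                                 errorMeta = meta)
  }
  img <- NULL
  ctPath <- file.path(sdir, "ct.nii.gz")
  if (file.exists(ctPath)) {
    nii <- RNifti::readNifti(ctPath)
    img <- ImageVolume(array(as.numeric(nii), dim = dim(nii)),
                       spacing = RNifti::pixdim(nii)[1:3])
  }
  body <- NULL
  bodyPath <- file.path(sdir, "body.nii.gz")
  if (file.exists(bodyPath))
    body <- Contour(readMask(bodyPath), "body", setId = id)
  out <- StructureSet(contours = cts, image = img, body = body, setId = id)
  attr(out, "spacing") <- sp
  out
}
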