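# Framework orchestration: per-OAR training, contour scoring, threshold
# tuning and Table-style evaluation.

orientFeatureRows <- function(tab, r1, r2) {
  p1 <- as.matrix(tab[, c("pc1_x", "pc1_y", "pc1_z")])
  p2 <- as.matrix(tab[, c("pc2_x", "pc2_y", "pc2_z")])
  s1 <- as.numeric(p1 %*% r1) < 0
  s2 <- as.numeric(p2 %*% r2) < 0
  tab[s1, c("pc1_x", "pc1_y", "pc1_z")] <- -p1[s1, , drop = FALSE]
  tab[s2, c("pc2_x", "pc2_y", "pc2_z")] <- -p2[s2, , drop = FALSE]
  tab
}

#' Train all per-OAR model bundles
#'
#' For each OAR type with at least \code{minRows} training contours:
#' identifies the representative PC1/PC2 eigenvectors and sign-standardizes
#' orientation features, removes rows deviating more than \code{kMad} MAD
#' from the feature median, fits feature statistics (z-score model), the
#' shrunk-covariance Mahalanobis model and the autoencoder, fits CCR bounds
#' for every evaluated pair where the OAR is the selected contour, and the
#' connectedness parts threshold. Rows lacking CT features are excluded
#' from training.
#'
#' @param features training feature table (acceptable contours only), as
#'   from \code{\link{extractFeatures}}.
#' @param pairs training pair-feature table from
#'   \code{\link{extractPairFeatures}}.
#' @param ccrMat logical CCR matrix.
#' @param kMad MAD-filter multiplier (default 12).
#' @param percentile CCR interval coverage (default 0.99).
#' @param partsQuantile connectedness threshold quantile (default 0.9995).
#' @param aeSeed base RNG seed for autoencoder initialization.
#' @param aeMaxit,aeHidden,aeDecay autoencoder training configuration.
#' @param minRows minimum training contours per OAR (default 10).
#' @param verbose print a per-OAR training log line.
#' @return named list of \linkS4class{OarModelBundle}; attribute
#'   \code{"log"} is a data.frame with per-OAR row counts, MAD removals and
#'   final autoencoder loss.
#' @export
trainBundles <- function(features, pairs, ccrMat, kMad = 12,
                         percentile = 0.99, partsQuantile = 0.9995,
                         aeSeed = 1, aeMaxit = 7000, aeHidden = 18,
                         aeDecay = 0.005, minRows = 10, verbose = FALSE) {
  bundles <- list()
  logRows <- list()
  fn <- featureNames()
  oars <- sort(unique(features$oar_type))
  for (k in seq_along(oars)) {
    oar <- oars[k]
    sub <- features[features$oar_type == oar, , drop = FALSE]
    ctOk <- !is.na(sub$ct_mean)
    if (sum(ctOk) < nrow(sub))
      message(nrow(sub) - sum(ctOk), " '", oar,
              "' contours without CT features excluded from training")
    sub <- sub[ctOk, , drop = FALSE]
    if (nrow(sub) < minRows) {
      warning("OAR '", oar, "' has ", nrow(sub),
              " usable training contours (< ", minRows, "); skipped")
      next
    }
    r1 <- representativeEigenvector(as.matrix(sub[, c("pc1_x", "pc1_y", "pc1_z")]))
    r2 <- representativeEigenvector(as.matrix(sub[, c("pc2_x", "pc2_y", "pc2_z")]))
    sub <- orientFeatureRows(sub, r1, r2)
    flt <- madFilter(sub, k = kMad, features = fn)
    kept <- flt$kept
    stats <- computeFeatureStats(kept, fn)
    md <- fitMd(kept, fn)
    ae <- fitAutoencoder(kept, stats = stats, hidden = aeHidden,
                         decay = aeDecay, maxit = aeMaxit,
                         seed = aeSeed + k, features = fn)
    bounds <- list()
    if (!is.null(pairs) && nrow(pairs)) {
      psub <- pairs[pairs$selected == oar, , drop = FALSE]
      for (comp in sort(unique(psub$comparison))) {
        v <- psub[psub$comparison == comp, , drop = FALSE]
        bounds[[length(bounds) + 1L]] <-
          fitCcrBounds(v$min_distance, "min_distance", oar, comp, percentile)
        bounds[[length(bounds) + 1L]] <-
          fitCcrBounds(v$fractional_overlap, "fractional_overlap", oar, comp,
                       percentile)
      }
    }
    pt <- fitPartsThreshold(sub$parts, quantile = partsQuantile)
    bundles[[oar]] <- new("OarModelBundle", oarType = oar, featureNames = fn,
                          featureStats = stats, mdModel = md,
                          repEigenvectors = list(pc1 = r1, pc2 = r2),
                          aeModel = ae, ccrBounds = bounds,
                          partsThreshold = pt, tunedThresholds = numeric())
    logRows[[oar]] <- data.frame(
      oar_type = oar, n_train = nrow(sub), n_removed = length(flt$removed),
      fraction_removed = flt$fraction_removed, ae_loss = ae$value,
      max_parts = pt$max_parts, stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("trained %-16s n=%3d removed=%d maxParts=%d",
                      oar, nrow(sub), length(flt$removed), pt$max_parts))
  }
  attr(bundles, "log") <- do.call(rbind, unname(logRows))
  bundles
}

#' Score contours against trained bundles
#'
#' Computes the three single-contour output metrics (max |z|, squared
#' Mahalanobis distance, autoencoder MSRE), the connectedness flag, and the
#' CCR flag (a contour is CCR-flagged when any of its evaluated pairs falls
#' outside its fitted bounds; both members of a flagged pair are flagged).
#' Missing CT features are imputed to the training mean (neutral
#' contribution). Contours of OAR types without a bundle are dropped with a
#' note.
#'
#' @param features feature table of the contours to score.
#' @param pairs pair-feature table for the same structure sets.
#' @param bundles named list of \linkS4class{OarModelBundle}.
#' @return data.frame with per-contour metrics and \code{ccr_flag},
#'   \code{conn_flag}; attribute \code{"ccr_violations"} lists the flagged
#'   pairs.
#' @export
scoreContours <- function(features, pairs, bundles) {
  keep <- features$oar_type %in% names(bundles)
  if (any(!keep))
    message(sum(!keep), " contours without a trained bundle omitted")
  features <- features[keep, , drop = FALSE]
  out <- features[, c("set_id", "oar_type", "truth", "category", "severity",
                      "parts")]
  n <- nrow(features)
  out$zscore <- out$md <- out$ae <- NA_real_
  out$conn_flag <- FALSE
  for (oar in unique(features$oar_type)) {
    b <- bundles[[oar]]
    idx <- which(features$oar_type == oar)
    sub <- features[idx, , drop = FALSE]
    stats <- b@featureStats
    for (ctf in c("ct_min", "ct_max", "ct_mean", "ct_std")) {
      isna <- is.na(sub[[ctf]])
      sub[[ctf]][isna] <- stats$mean[stats$feature == ctf]
    }
    sub <- orientFeatureRows(sub, b@repEigenvectors$pc1, b@repEigenvectors$pc2)
    out$zscore[idx] <- zscoreMetric(sub, stats)
    out$md[idx] <- mdMetric(sub, b@mdModel)
    out$ae[idx] <- aeMetric(sub, b@aeModel, stats)
    out$conn_flag[idx] <- connectednessClassify(sub$parts, b@partsThreshold)
  }
  # CCR: evaluate each pair against the selected OAR's bounds
  out$ccr_flag <- FALSE
  viol <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    for (oar in unique(pairs$selected)) {
      b <- bundles[[oar]]
      if (is.null(b) || !length(b@ccrBounds)) next
      for (bound in b@ccrBounds) {
        rows <- which(pairs$selected == oar &
                      pairs$comparison == bound@comparisonOar)
        if (!length(rows)) next
        v <- pairs[[bound@feature]][rows]
        bad <- ccrClassify(v, bound)
        for (r in rows[bad]) {
          # classification is row-based (the selected contour is flagged);
          # both members of the pair are reported for human review
          viol[[length(viol) + 1L]] <- data.frame(
            set_id = pairs$set_id[r], selected = oar,
            comparison = pairs$comparison[r], feature = bound@feature,
            value = pairs[[bound@feature]][r],
            lower = bound@lower, upper = bound@upper,
            stringsAsFactors = FALSE)
          hit <- out$set_id == pairs$set_id[r] & out$oar_type == oar
          out$ccr_flag[hit] <- TRUE
        }
      }
    }
  }
  attr(out, "ccr_violations") <-
    if (length(viol)) do.call(rbind, viol)
    else data.frame(set_id = character(), selected = character(),
                    comparison = character(), feature = character(),
                    value = numeric(), lower = numeric(), upper = numeric())
  rownames(out) <- NULL
  out
}

#' Tune single-contour model thresholds on a validation score table
#'
#' A single global threshold per model type (z-score, MD, AE), tuned twice:
#' once for the model alone and once for the OR-combination with the fixed
#' CCR and connectedness flags (the thresholds need not agree).
#'
#' @param scores validation output of \code{\link{scoreContours}} including
#'   a \code{truth} column with both classes.
#' @return named list of thresholds: \code{zscore}, \code{md}, \code{ae},
#'   \code{zscore_combined}, \code{md_combined}, \code{ae_combined}.
#' @export
tuneAllThresholds <- function(scores) {
  truth <- normalizeTruth(scores$truth)
  fixed <- combineFlags(scores$ccr_flag, scores$conn_flag)
  th <- list()
  for (m in c("zscore", "md", "ae")) {
    th[[m]] <- tuneThreshold(scores[[m]], truth)$threshold
    th[[paste0(m, "_combined")]] <-
      tuneThreshold(scores[[m]], truth, fixed)$threshold
  }
  th
}

#' Apply tuned thresholds to a score table
#'
#' @param scores output of \code{\link{scoreContours}}.
#' @param thresholds output of \code{\link{tuneAllThresholds}}.
#' @return the score table with per-model solo flags and OR-combined flags.
#' @export
applyThresholds <- function(scores, thresholds) {
  fixed <- combineFlags(scores$ccr_flag, scores$conn_flag)
  for (m in c("zscore", "md", "ae")) {
    scores[[paste0(m, "_flag")]] <- scores[[m]] > thresholds[[m]]
    scores[[paste0(m, "_combined")]] <-
      combineFlags(scores[[m]] > thresholds[[paste0(m, "_combined")]], fixed)
  }
  scores
}

#' Classification-results table for a flagged score table
#'
#' One row per model (connectedness, CCR, the three single-contour models
#' solo, and their OR-combinations) with AUC (single models only),
#' balanced accuracy, sensitivity, specificity and confusion counts.
#'
#' @param scored output of \code{\link{applyThresholds}}.
#' @param digits round metrics for reporting (default 3; \code{NA} keeps
#'   full precision).
#' @return data.frame of classification results.
#' @export
evaluateScores <- function(scored, digits = NA) {
  truth <- normalizeTruth(scored$truth)
  rows <- list(
    connectedness = list(pred = scored$conn_flag, auc = NA_real_),
    ccr = list(pred = scored$ccr_flag, auc = NA_real_),
    zscore = list(pred = scored$zscore_flag, auc = rocAuc(scored$zscore, truth)),
    md = list(pred = scored$md_flag, auc = rocAuc(scored$md, truth)),
    ae = list(pred = scored$ae_flag, auc = rocAuc(scored$ae, truth)),
    zscore_combined = list(pred = scored$zscore_combined, auc = NA_real_),
    md_combined = list(pred = scored$md_combined, auc = NA_real_),
    ae_combined = list(pred = scored$ae_combined, auc = NA_real_))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    cm <- confusionMetrics(rows[[nm]]$pred, truth)
    data.frame(model = nm, auc = rows[[nm]]$auc,
               balanced_accuracy = cm$balanced_accuracy,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
               stringsAsFactors = FALSE)
  }))
  if (!is.na(digits))
    for (cc in c("auc", "balanced_accuracy", "sensitivity", "specificity"))
      out[[cc]] <- round(out[[cc]], digits)
  rownames(out) <- NULL
  out
}

# ---- end-to-end phantom study -----------------------------------------

rosterZLength <- function(spec) {
  switch(spec$shape,
    ellipsoid = , paired_ellipsoid = 2 * spec$radii[3],
    tube = 2 * spec$halfLen,
    box_union = max(vapply(spec$boxes, function(b) 2 * b$half[3], numeric(1))),
    NA_real_)
}

planErrors <- function(setIds, roster, errorMix, minErrPaired, minErrUnpaired,
                       noPositionFor = character()) {
  rows <- list()
  for (oar in names(roster)) {
    nErr <- if (isTRUE(roster[[oar]]$paired)) minErrPaired else minErrUnpaired
    nErr <- min(nErr, length(setIds))
    chosen <- sample(setIds, nErr)
    for (i in seq_len(nErr))
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = chosen[i], oar_type = oar, category = NA_character_,
        severity = sample(c("moderate", "major"), 1),
        seed = sample.int(1e8, 1), stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, rows)
  n <- nrow(plan)
  # categories mirror the error-mix proportions exactly (largest-remainder
  # allocation), then are shuffled over the planned contours
  p <- errorMix / sum(errorMix)
  counts <- floor(p * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(p * n - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1L
  }
  plan$category <- sample(rep(names(errorMix), counts))
  # eligibility: single-slice misclicks occur while scrolling through many
  # slices, so organs only a few slices thick swap their slice errors for
  # another category drawn from an eligible row; position errors can be
  # excluded for reference structures the same way
  badFor <- function(oar, cat) {
    if (cat == "nonadjacent_slice") {
      # misclicks and jagged slices arise while scrolling through many
      # slices: only organs spanning a dozen or more slices draw them
      zl <- rosterZLength(roster[[oar]])
      return(!is.na(zl) && zl < 24)
    }
    if (cat == "position") return(oar %in% noPositionFor)
    FALSE
  }
  for (i in seq_len(n)) {
    if (!badFor(plan$oar_type[i], plan$category[i])) next
    for (j in sample(seq_len(n))) {
      if (j == i) next
      if (!badFor(plan$oar_type[j], plan$category[i]) &&
          !badFor(plan$oar_type[i], plan$category[j])) {
        tmp <- plan$category[i]
        plan$category[i] <- plan$category[j]
        plan$category[j] <- tmp
        break
      }
    }
  }
  plan
}

# Features and pair rows for one erroneous variant contour, evaluated
# inside its otherwise-acceptable structure set (the variant is an added
# copy, as erroneous contours are appended to validation/test sets on top
# of the intact gold-standard set). The variant gets a pseudo set id so it
# can coexist with the acceptable original in one score table.
variantRows <- function(ss, planRow, ccrMat, spacing, pseudoId,
                        refOar = "brainstem", refOarForReference = "pituitary") {
  oar <- planRow$oar_type
  ct <- contours(ss)[[oar]]
  if (is.null(ct)) return(NULL)
  spec <- errorSpec(planRow$category, planRow$severity, seed = planRow$seed)
  inj <- try(injectError(ct, imageVolume(ss), spec, spacing = spacing),
             silent = TRUE)
  if (inherits(inj, "try-error")) {
    # magnitude infeasible for this organ (e.g. erosion of a small organ):
    # fall back to the always-feasible variant of the same category
    fallback <- switch(planRow$category,
      boundary = list(direction = "dilate"), volume = list(mode = "add"),
      list())
    spec <- errorSpec(planRow$category, planRow$severity,
                      seed = planRow$seed, params = fallback)
    inj <- injectError(ct, imageVolume(ss), spec, spacing = spacing)
  }
  comps <- if (oar %in% rownames(ccrMat))
    colnames(ccrMat)[which(ccrMat[oar, ])] else character()
  need <- unique(c(oar, refOar, refOarForReference,
                   setdiff(comps, "body")))
  cts <- contours(ss)[intersect(need, contourNames(ss))]
  cts[[oar]] <- inj
  ssSub <- StructureSet(contours = cts, image = imageVolume(ss),
                        body = bodyContour(ss), setId = pseudoId)
  f <- extractFeatures(ssSub, spacing = spacing, refOar = refOar,
                       refOarForReference = refOarForReference)
  f <- f[f$oar_type == oar, , drop = FALSE]
  p <- extractPairFeatures(ssSub, ccrMat, spacing = spacing)
  p <- p[p$selected == oar, , drop = FALSE]
  list(features = f, pairs = p)
}

injectPlanned <- function(ss, plan, spacing) {
  rows <- plan[plan$set_id == setId(ss), , drop = FALSE]
  cts <- contours(ss)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    ct <- cts[[r$oar_type]]
    if (is.null(ct)) next
    spec <- errorSpec(r$category, r$severity, seed = r$seed)
    inj <- try(injectError(ct, imageVolume(ss), spec, spacing = spacing),
               silent = TRUE)
    if (inherits(inj, "try-error")) {
      # magnitude infeasible for this organ (e.g. erosion of a small organ):
      # fall back to the always-feasible variant of the same category
      fallback <- switch(r$category,
        boundary = list(direction = "dilate"),
        volume = list(mode = "add"),
        nonadjacent_slice = list(),
        position = list())
      spec <- errorSpec(r$category, r$severity, seed = r$seed,
                        params = fallback)
      inj <- injectError(ct, imageVolume(ss), spec, spacing = spacing)
    }
    cts[[r$oar_type]] <- inj
  }
  StructureSet(contours = cts, image = imageVolume(ss),
               body = bodyContour(ss), setId = setId(ss))
}

#' Run the complete phantom experiment
#'
#' Generates a corpus of synthetic structure sets, splits it
#' train/validation/test, injects a proportioned mix of the four error
#' categories into the validation and test subsets (with the per-OAR
#' minimum-error rule), trains all per-OAR bundles on the acceptable
#' training contours, tunes the single-contour model thresholds on the
#' validation set, and evaluates both validation and test sets. Structure
#' sets are processed one at a time and discarded after feature extraction.
#'
#' @param nTrain,nVal,nTest subset sizes (default 80/10/10).
#' @param config a \code{\link{phantomConfig}}.
#' @param seed master RNG seed; every downstream seed derives from it.
#' @param errorMix relative frequencies of the four error categories
#'   (default 74:99:14:40, boundary:volume:non-adjacent slice:position).
#' @param minErrPaired,minErrUnpaired minimum erroneous contours per paired
#'   / unpaired OAR type in each of the validation and test subsets
#'   (defaults 4 and 5).
#' @param ccrMat CCR matrix (default \code{\link{defaultCcrMatrix}} of the
#'   config roster).
#' @param verbose progress messages.
#' @param ... passed to \code{\link{trainBundles}}.
#' @return list with \code{bundles}, \code{thresholds}, score tables
#'   \code{val} and \code{test} (flagged), evaluation tables \code{evalVal}
#'   and \code{evalTest}, the error \code{plan}, and the training
#'   \code{log}.
#' @export
phantomStudy <- function(nTrain = 80, nVal = 10, nTest = 10,
                         config = phantomConfig(), seed = 1,
                         errorMix = c(boundary = 74, volume = 99,
                                      nonadjacent_slice = 14, position = 40),
                         minErrPaired = 4, minErrUnpaired = 5,
                         ccrMat = defaultCcrMatrix(config$roster),
                         verbose = FALSE, ...) {
  set.seed(seed)
  nTot <- nTrain + nVal + nTest
  setSeeds <- sample.int(1e8, nTot)
  split <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))
  ids <- sprintf("set%03d", seq_len(nTot))
  planVal <- planErrors(ids[split == "val"], config$roster, errorMix,
                        minErrPaired, minErrUnpaired)
  planTest <- planErrors(ids[split == "test"], config$roster, errorMix,
                         minErrPaired, minErrUnpaired)
  plan <- rbind(cbind(planVal, subset = "val"),
                cbind(planTest, subset = "test"))
  sp <- config$spacing
  feats <- list(); prs <- list()
  for (i in seq_len(nTot)) {
    ss <- generateStructureSet(config, seed = setSeeds[i], setId = ids[i])
    feats[[i]] <- cbind(extractFeatures(ss, spacing = sp), subset = split[i])
    prs[[i]] <- extractPairFeatures(ss, ccrMat, spacing = sp)
    if (split[i] != "train") {
      # erroneous contours are appended as additional variants; the
      # gold-standard acceptable set stays intact
      rows <- plan[plan$set_id == ids[i], , drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        vr <- variantRows(ss, rows[j, ], ccrMat, sp,
                          pseudoId = sprintf("%s.e%02d", ids[i], j))
        if (is.null(vr) || !nrow(vr$features)) next
        feats[[length(feats) + 1L]] <- cbind(vr$features, subset = split[i])
        if (nrow(vr$pairs)) prs[[length(prs) + 1L]] <- vr$pairs
      }
    }
    if (verbose && i %% 10 == 0) message("processed ", i, "/", nTot, " sets")
    rm(ss)
  }
  features <- do.call(rbind, feats)
  pairs <- do.call(rbind, prs)
  baseId <- sub("\\..*$", "", pairs$set_id)   # variants carry "<set>.eNN"
  trainFeat <- features[features$subset == "train", , drop = FALSE]
  trainPairs <- pairs[baseId %in% ids[split == "train"], , drop = FALSE]
  bundles <- trainBundles(trainFeat, trainPairs, ccrMat,
                          aeSeed = sample.int(1e8, 1), verbose = verbose, ...)
  valFeat <- features[features$subset == "val", , drop = FALSE]
  valPairs <- pairs[baseId %in% ids[split == "val"], , drop = FALSE]
  # relational thresholds are adjusted on the validation set to minimize
  # false positives (acceptable rows are the non-variant pair rows)
  bundles <- calibrateCcrBounds(bundles, valPairs,
                                acceptable = !grepl("\\.", valPairs$set_id))
  valScores <- scoreContours(valFeat, valPairs, bundles)
  bundles <- calibratePartsThreshold(bundles, valScores)
  valScores <- scoreContours(valFeat, valPairs, bundles)
  testScores <- scoreContours(features[features$subset == "test", , drop = FALSE],
                              pairs[baseId %in% ids[split == "test"], , drop = FALSE],
                              bundles)
  thresholds <- tuneAllThresholds(valScores)
  val <- applyThresholds(valScores, thresholds)
  test <- applyThresholds(testScores, thresholds)
  list(bundles = bundles, thresholds = thresholds,
       val = val, test = test,
       evalVal = evaluateScores(val), evalTest = evaluateScores(test),
       features = features, pairs = pairs, plan = plan,
       log = attr(bundles, "log"))
}
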