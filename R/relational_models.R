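# Contour-to-contour relationship (CCR) bounds and the connectedness model.
#
# For each evaluated OAR pair, training values of minimum surface distance
# are fitted to a gamma distribution (support [0, inf)) and fractional
# overlaps to a beta distribution (support [0, 1]). Acceptance intervals are
# the two-sided 99% interval of the fitted distribution, expanded by 2 mm
# (distance) or 0.02 (overlap) so small, clinically irrelevant deviations do
# not flag, then clipped to the feature domain.

#' Fit a CCR acceptance bound for one pair feature
#'
#' @param values training feature values across structure sets (>= 20
#'   recommended).
#' @param feature \code{"min_distance"} or \code{"fractional_overlap"}.
#' @param selectedOar,comparisonOar pair labels stored on the bound.
#' @param percentile central coverage of the acceptance interval before
#'   expansion (default 0.99, i.e. quantiles 0.005 and 0.995).
#' @param expansion additive bound expansion; defaults to 2 (mm) for
#'   distance and 0.02 for overlap.
#' @return a \linkS4class{CcrBound}.
#' @export
fitCcrBounds <- function(values, feature = c("min_distance", "fractional_overlap"),
                         selectedOar = "", comparisonOar = "",
                         percentile = 0.99, expansion = NULL) {
  feature <- match.arg(feature)
  if (is.null(expansion))
    expansion <- if (feature == "min_distance") 2 else 0.02
  lo_p <- (1 - percentile) / 2
  hi_p <- 1 - lo_p
  clipDomain <- function(lo, hi) {
    lo <- max(lo, 0)
    if (feature == "fractional_overlap") hi <- min(hi, 1)
    c(lo, hi)
  }
  degenerate <- diff(range(values)) < 1e-9
  params <- c(NA_real_, NA_real_)
  if (degenerate) {
    b <- clipDomain(values[1] - expansion, values[1] + expansion)
  } else {
    fit <- NULL
    if (feature == "min_distance") {
      v <- pmax(values, 0.01)  # gamma needs strictly positive support
      fit <- try(fitdistrplus::fitdist(v, "gamma"), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        shape <- fit$estimate[["shape"]]; rate <- fit$estimate[["rate"]]
        params <- c(shape, 1 / rate)
        q <- qgamma(c(lo_p, hi_p), shape = shape, rate = rate)
      }
    } else {
      v <- pmin(pmax(values, 1e-4), 1 - 1e-4)
      fit <- try(fitdistrplus::fitdist(v, "beta"), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        a <- fit$estimate[["shape1"]]; b2 <- fit$estimate[["shape2"]]
        params <- c(a, b2)
        q <- qbeta(c(lo_p, hi_p), a, b2)
      }
    }
    if (inherits(fit, "try-error")) {
      # fall back to empirical quantiles when the MLE does not converge
      q <- as.numeric(quantile(values, c(lo_p, hi_p), type = 7))
    }
    b <- clipDomain(q[1] - expansion, q[2] + expansion)
  }
  new("CcrBound", selectedOar = selectedOar, comparisonOar = comparisonOar,
      feature = feature, params = params, lower = b[1], upper = b[2])
}

#' Widen CCR bounds that flag acceptable validation pairs
#'
#' After fitting on the training corpus, the acceptance intervals are
#' adjusted on the validation set so that no acceptable contour pair is
#' flagged: any bound violated by an acceptable validation value is widened
#' to cover that value plus a small margin. This is the manual
#' percentile-boundary adjustment step of the method (boundaries are set to
#' minimize false positives on the validation set); it is deterministic and
#' never touches the test set.
#'
#' @param bundles named list of \linkS4class{OarModelBundle}.
#' @param pairs validation pair-feature table (see
#'   \code{\link{extractPairFeatures}}).
#' @param acceptable logical per pair row: is the selected contour
#'   acceptable?
#' @param margin extra slack beyond the covering value: mm for distance,
#'   fraction for overlap (defaults 0.5 mm / 0.005).
#' @return the bundles with widened bounds.
#' @export
calibrateCcrBounds <- function(bundles, pairs, acceptable,
                               margin = c(min_distance = 0.5,
                                          fractional_overlap = 0.005)) {
  if (!nrow(pairs)) return(bundles)
  pairs <- pairs[acceptable, , drop = FALSE]
  for (oar in intersect(unique(pairs$selected), names(bundles))) {
    b <- bundles[[oar]]
    if (!length(b@ccrBounds)) next
    for (k in seq_along(b@ccrBounds)) {
      bd <- b@ccrBounds[[k]]
      v <- pairs[pairs$selected == oar &
                 pairs$comparison == bd@comparisonOar, bd@feature]
      if (!length(v)) next
      eps <- margin[[bd@feature]]
      if (any(v < bd@lower))
        bd@lower <- max(0, min(v) - eps)
      if (any(v > bd@upper)) {
        up <- max(v) + eps
        bd@upper <- if (bd@feature == "fractional_overlap") min(1, up) else up
      }
      b@ccrBounds[[k]] <- bd
    }
    bundles[[oar]] <- b
  }
  bundles
}

#' Raise parts thresholds that flag acceptable validation contours
#'
#' The connectedness threshold is likewise adjusted on the validation set to
#' minimize false positives: if an acceptable validation contour of some OAR
#' type exceeds the fitted maximum parts, the maximum is raised to the
#' largest acceptable validation count.
#'
#' @param bundles named list of \linkS4class{OarModelBundle}.
#' @param scores validation score table (needs \code{oar_type},
#'   \code{parts}, \code{truth}).
#' @return the bundles with adjusted thresholds.
#' @export
calibratePartsThreshold <- function(bundles, scores) {
  acc <- scores[scores$truth == "acceptable", , drop = FALSE]
  for (oar in intersect(unique(acc$oar_type), names(bundles))) {
    b <- bundles[[oar]]
    mx <- max(acc$parts[acc$oar_type == oar])
    if (mx > b@partsThreshold$max_parts) {
      b@partsThreshold$max_parts <- as.integer(mx)
      bundles[[oar]] <- b
    }
  }
  bundles
}

#' Classify a pair feature value against a fitted bound
#'
#' @param value feature value(s).
#' @param bound a \linkS4class{CcrBound}.
#' @return logical: TRUE when the value falls outside [lower, upper].
#' @export
ccrClassify <- function(value, bound) {
  value < bound@lower | value > bound@upper
}

#' Fit the connectedness (disconnected parts) threshold
#'
#' When all training counts are equal the threshold is that value; otherwise
#' a gamma distribution is fitted by maximum likelihood to the counts and the
#' maximum allowed parts is the ceiling of its 99.95% quantile.
#'
#' @param counts integer vector of training part counts (>= 1).
#' @param quantile statistical threshold (default 0.9995).
#' @return list with \code{max_parts}, optional \code{params}
#'   (gamma shape, scale) and the \code{quantile} used.
#' @export
fitPartsThreshold <- function(counts, quantile = 0.9995) {
  stopifnot(length(counts) >= 1, all(counts >= 1))
  if (length(unique(counts)) == 1L)
    return(list(max_parts = as.integer(counts[1]), params = NULL,
                quantile = quantile))
  fit <- try(fitdistrplus::fitdist(as.numeric(counts), "gamma"), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(max_parts = as.integer(max(counts)), params = NULL,
                quantile = quantile))
  shape <- fit$estimate[["shape"]]; rate <- fit$estimate[["rate"]]
  mp <- as.integer(ceiling(qgamma(quantile, shape = shape, rate = rate)))
  list(max_parts = max(mp, 1L), params = c(shape = shape, scale = 1 / rate),
       quantile = quantile)
}

#' Connectedness classification
#'
#' @param partsCount observed number of 26-connected parts.
#' @param threshold output of \code{\link{fitPartsThreshold}}.
#' @return logical: TRUE when the count exceeds the allowed maximum.
#' @export
connectednessClassify <- function(partsCount, threshold) {
  partsCount > threshold$max_parts
}

#' Default CCR matrix for a roster of OAR types
#'
#' Boolean matrix (rows = selected contour, columns = comparison contour plus
#' a \code{"body"} column). Pairs are declared from the roster's adjacency
#' annotations: nested pairs (e.g. lens inside eye), abutting pairs (e.g.
#' cord and brainstem) and near pairs; every OAR is additionally compared to
#' the body contour. The evaluated pair list is configuration: edit the
#' matrix (or its CSV form) to match institutional rosters.
#'
#' @param oarTypes character vector of OAR types (rows).
#' @param pairs two-column character matrix/data.frame of (selected,
#'   comparison) pairs to evaluate, or NULL for body-only.
#' @param body include a body comparison column for every OAR (default TRUE).
#' @return logical matrix with rownames = oarTypes, colnames = c(oarTypes,
#'   "body").
#' @export
ccrMatrix <- function(oarTypes, pairs = NULL, body = TRUE) {
  cols <- c(oarTypes, if (body) "body")
  M <- matrix(FALSE, length(oarTypes), length(cols),
              dimnames = list(oarTypes, cols))
  if (body) M[, "body"] <- TRUE
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    for (i in seq_len(nrow(pairs))) {
      sel <- pairs[i, 1]; comp <- pairs[i, 2]
      if (sel %in% rownames(M) && comp %in% colnames(M) && sel != comp)
        M[sel, comp] <- TRUE
    }
  }
  diagCols <- intersect(rownames(M), colnames(M))
  for (d in diagCols) M[d, d] <- FALSE
  M
}

#' Read/write a CCR matrix as labeled 0/1 CSV
#'
#' @param path CSV path.
#' @param M logical matrix as from \code{\link{ccrMatrix}}.
#' @return \code{readCcrMatrix} returns the logical matrix.
#' @export
writeCcrMatrix <- function(M, path) {
  df <- data.frame(selected = rownames(M), `+`(M * 1L, 0L),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCcrMatrix
#' @export
readCcrMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(M) <- df[[1]]
  M
}
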