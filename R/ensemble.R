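# Flag combination, threshold tuning, and evaluation metrics.
#
# The three single-contour feature models, the CCR model and the
# connectedness model each emit a per-contour classification; the final
# verdict is their logical OR. Single-contour model thresholds are tuned on
# a validation set to maximize balanced accuracy of the combined classifier
# (CCR and connectedness flags held fixed); the test set always reuses
# validation thresholds.

#' Logical-OR combination of model flags
#'
#' @param ... logical vectors of per-contour flags (recycled to equal
#'   length).
#' @return logical vector: TRUE when any model flagged the contour.
#' @export
combineFlags <- function(...) {
  Reduce(`|`, list(...))
}

normalizeTruth <- function(truth) {
  if (is.logical(truth)) return(truth)
  truth == "erroneous"
}

#' Tune a metric threshold to maximize combined balanced accuracy
#'
#' Scans candidate thresholds (midpoints of sorted unique finite metric
#' values, plus -Inf and +Inf), computes the balanced accuracy of
#' \code{(metric > t) | fixedFlags} at each, and returns the maximizer. Ties
#' are broken toward the higher threshold (favors specificity).
#'
#' @param metric numeric output metric per contour.
#' @param truth truth labels (logical TRUE = erroneous, or
#'   "acceptable"/"erroneous").
#' @param fixedFlags logical flags from the fixed models (CCR OR
#'   connectedness); default none.
#' @return list with \code{threshold} and \code{ba}.
#' @export
tuneThreshold <- function(metric, truth, fixedFlags = NULL) {
  truth <- normalizeTruth(truth)
  if (length(unique(truth)) < 2) stop("both classes must be present")
  if (is.null(fixedFlags)) fixedFlags <- rep(FALSE, length(metric))
  u <- sort(unique(metric[is.finite(metric)]))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + u[-1]) / 2, Inf)
  best <- list(threshold = Inf, ba = -1)
  for (t in cand) {
    pred <- (metric > t) | fixedFlags
    ba <- balancedAccuracy(pred, truth)
    if (ba > best$ba || (ba == best$ba && t > best$threshold))
      best <- list(threshold = t, ba = ba)
  }
  best
}

balancedAccuracy <- function(pred, truth) {
  sens <- sum(pred & truth) / sum(truth)
  spec <- sum(!pred & !truth) / sum(!truth)
  (sens + spec) / 2
}

#' Confusion counts and derived classification metrics
#'
#' @param pred logical predictions (TRUE = flagged erroneous).
#' @param truth truth labels.
#' @return list with \code{tp}, \code{fn}, \code{tn}, \code{fp},
#'   \code{sensitivity}, \code{specificity}, \code{balanced_accuracy}
#'   (full precision; round to 3 decimals for reporting).
#' @export
confusionMetrics <- function(pred, truth) {
  truth <- normalizeTruth(truth)
  if (!length(pred)) stop("empty input")
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  metricsFromCounts(tp, fn, tn, fp)
}

#' @rdname confusionMetrics
#' @param tp,fn,tn,fp confusion counts.
#' @export
metricsFromCounts <- function(tp, fn, tn, fp) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2)
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' \eqn{P(m_{err} > m_{acc}) + \tfrac12 P(m_{err} = m_{acc})}, computed from
#' midranks; ties count one half.
#'
#' @param metric numeric output metric.
#' @param truth truth labels.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(metric, truth) {
  truth <- normalizeTruth(truth)
  nE <- sum(truth); nA <- sum(!truth)
  if (nE == 0 || nA == 0) stop("both classes must be present")
  r <- rank(metric)
  (sum(r[truth]) - nE * (nE + 1) / 2) / (nE * nA)
}

#' Balanced evaluation subset by subsampling acceptable contours
#'
#' Selects \code{nPerOar} acceptable contours at random per OAR type and
#' merges them with all erroneous contours. Deterministic given \code{seed}.
#'
#' @param scores data.frame with columns \code{oar_type} and \code{truth}.
#' @param nPerOar acceptable contours to sample per OAR type (default 5).
#' @param seed RNG seed.
#' @return row indices of the evaluation subset.
#' @export
subsampleBalanced <- function(scores, nPerOar = 5, seed = 1) {
  truth <- normalizeTruth(scores$truth)
  set.seed(seed)
  accIdx <- integer()
  for (oar in sort(unique(scores$oar_type))) {
    pool <- which(!truth & scores$oar_type == oar)
    if (length(pool) < nPerOar) {
      warning("only ", length(pool), " acceptable '", oar,
              "' contours available; taking all")
      accIdx <- c(accIdx, pool)
    } else {
      accIdx <- c(accIdx, sort(sample(pool, nPerOar)))
    }
  }
  sort(c(accIdx, which(truth)))
}

#' Two-sided mid-p McNemar test for paired classifiers
#'
#' With \eqn{b} the contours classifier A gets right and B wrong, \eqn{c} the
#' reverse, \eqn{m = \min(b, c)} and \eqn{n = b + c}:
#' \eqn{p = 2 P(X \le m) - P(X = m)} for \eqn{X \sim Binomial(n, 1/2)};
#' \eqn{p = 1} when there are no discordant pairs.
#'
#' @param predA,predB logical predictions of the two classifiers.
#' @param truth truth labels.
#' @return mid-p value.
#' @export
mcnemarMidp <- function(predA, predB, truth) {
  truth <- normalizeTruth(truth)
  okA <- predA == truth
  okB <- predB == truth
  b <- sum(okA & !okB)
  c_ <- sum(!okA & okB)
  n <- b + c_
  if (n == 0) return(1)
  m <- min(b, c_)
  min(1, 2 * pbinom(m, n, 0.5) - dbinom(m, n, 0.5))
}
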