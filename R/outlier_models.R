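# Per-OAR one-class models on the single-contour features.
#
# All three model types are trained on acceptable contours only, after a
# robust MAD-based purge of questionable training rows. Output metrics are
# monotone outlier scores: maximum absolute feature z-score, squared
# Mahalanobis distance (as printed, no square root; thresholding is
# monotone-invariant), and the autoencoder's mean squared reconstruction
# error on z-scored features.

#' Per-feature robust and moment statistics of a training table
#'
#' @param featureTable data.frame/matrix with feature columns (rows =
#'   contours).
#' @param features feature names to use (default \code{\link{featureNames}}
#'   intersected with the columns).
#' @return data.frame with columns \code{feature}, \code{mean}, \code{sd},
#'   \code{median}, \code{mad} (unscaled median absolute deviation from the
#'   median; no 1.4826 consistency factor).
#' @export
computeFeatureStats <- function(featureTable, features = NULL) {
  X <- featureMatrix(featureTable, features)
  data.frame(
    feature = colnames(X),
    mean = colMeans(X),
    sd = apply(X, 2, sd),
    median = apply(X, 2, median),
    mad = apply(X, 2, function(v) median(abs(v - median(v)))),
    row.names = NULL, stringsAsFactors = FALSE)
}

featureMatrix <- function(featureTable, features = NULL) {
  if (is.null(features))
    features <- intersect(featureNames(), colnames(featureTable))
  X <- as.matrix(as.data.frame(featureTable)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Remove training rows that deviate from the median by more than k MAD
#'
#' A row is removed iff any feature satisfies |x - median| > k * MAD, using
#' the unscaled MAD; features with MAD = 0 are skipped. Refuses to proceed
#' when every row would be removed.
#'
#' @param featureTable training feature table (one OAR type).
#' @param k MAD multiplier (default 12).
#' @param features feature names to screen.
#' @return list with \code{kept} (the filtered table), \code{removed}
#'   (integer row indices removed) and \code{fraction_removed}.
#' @export
madFilter <- function(featureTable, k = 12, features = NULL) {
  X <- featureMatrix(featureTable, features)
  med <- apply(X, 2, median)
  madv <- apply(X, 2, function(v) median(abs(v - median(v))))
  use <- madv > 0
  dev <- abs(sweep(X[, use, drop = FALSE], 2, med[use]))
  bad <- rowSums(sweep(dev, 2, k * madv[use], ">")) > 0
  if (all(bad)) stop("MAD filter removed every training row; k too small")
  list(kept = as.data.frame(featureTable)[!bad, , drop = FALSE],
       removed = which(bad),
       fraction_removed = mean(bad))
}

# z-transform a feature matrix with stored stats; sd = 0 features map to 0
zTransform <- function(X, stats) {
  X <- X[, stats$feature, drop = FALSE]
  Z <- sweep(sweep(X, 2, stats$mean), 2, ifelse(stats$sd > 0, stats$sd, 1), "/")
  Z[, stats$sd == 0] <- 0
  Z
}

#' Maximum absolute feature z-score
#'
#' \eqn{z = |x - \mu| / \sigma} per feature; the output metric is the maximum
#' across features. Features with \eqn{\sigma = 0} contribute 0 when the
#' value equals the training mean and \code{Inf} otherwise (always flags).
#'
#' @param x feature vector, matrix or feature table (rows = contours).
#' @param stats output of \code{\link{computeFeatureStats}}.
#' @return numeric vector of max |z| per row.
#' @export
zscoreMetric <- function(x, stats) {
  X <- asFeatureRows(x, stats$feature)
  Z <- abs(sweep(X, 2, stats$mean))
  sdv <- stats$sd
  for (j in seq_along(sdv)) {
    if (sdv[j] > 0) Z[, j] <- Z[, j] / sdv[j]
    else Z[, j] <- ifelse(Z[, j] == 0, 0, Inf)
  }
  apply(Z, 1, max)
}

asFeatureRows <- function(x, features) {
  if (is.null(dim(x))) {
    x <- matrix(as.numeric(x[features]), nrow = 1,
                dimnames = list(NULL, features))
  } else {
    x <- featureMatrix(x, features)
  }
  x
}

#' Fit the Mahalanobis-distance model
#'
#' Column means and covariance with Ledoit-Wolf shrinkage toward the scaled
#' identity \eqn{(\mathrm{tr}\,\Sigma / d) I}. With tens of training
#' contours and 20 features the sample covariance badly underestimates its
#' smallest eigenvalues, so a plain (or near-plain) inverse wildly inflates
#' the distance for any direction unseen in training; the Ledoit-Wolf
#' intensity is estimated from the data and vanishes as n grows. A small
#' ridge \code{delta} additionally guarantees a finite inverse even for
#' rank-deficient tables (e.g. n = d).
#'
#' @param featureTable training feature table.
#' @param features feature names.
#' @param delta numerical ridge floor.
#' @return list with \code{mean}, \code{cov} (shrunk), \code{covInv} and
#'   the estimated shrinkage intensity \code{lambda}.
#' @export
fitMd <- function(featureTable, features = NULL, delta = 1e-6) {
  X <- featureMatrix(featureTable, features)
  if (any(!is.finite(X))) stop("non-finite feature values")
  n <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / n
  m <- sum(diag(S)) / d
  d2 <- sum((S - m * diag(d))^2)
  lambda <- 0
  if (d2 > 0 && n > 1) {
    b2 <- 0
    for (i in seq_len(n)) b2 <- b2 + sum((tcrossprod(Xc[i, ]) - S)^2)
    lambda <- min(b2 / n^2, d2) / d2
  }
  S <- (1 - lambda) * S + lambda * m * diag(d)
  S <- S + delta * m * diag(d)
  list(mean = mu, cov = S, covInv = solve(S), lambda = lambda)
}

#' Squared Mahalanobis distance output metric
#'
#' \eqn{D(x) = (x - \hat\mu)^T \Sigma^{-1} (x - \hat\mu)}, implemented in the
#' squared form as defined (no square root).
#'
#' @param x feature vector, matrix or table.
#' @param model output of \code{\link{fitMd}}.
#' @return numeric vector of squared distances.
#' @export
mdMetric <- function(x, model) {
  X <- asFeatureRows(x, names(model$mean))
  if (ncol(X) != length(model$mean)) stop("feature dimension mismatch")
  as.numeric(mahalanobis(X, model$mean, model$covInv, inverted = TRUE))
}

#' Train the autoencoder model
#'
#' A single-hidden-layer autoencoder (d inputs, 18 sigmoid hidden units,
#' linear outputs) trained by full-batch quasi-Newton optimization on
#' z-scored features, minimizing squared reconstruction error with an L2
#' weight penalty (coefficient 0.005), for at most 7000 epochs with early
#' stopping on relative loss change below 1e-9. Deterministic given
#' \code{seed}.
#'
#' @param featureTable training feature table (raw features).
#' @param stats feature statistics used for z-scoring (defaults to stats of
#'   \code{featureTable}).
#' @param hidden hidden-layer width (default 18).
#' @param decay L2 regularization coefficient (default 0.005).
#' @param maxit maximum epochs (default 7000).
#' @param seed RNG seed for weight initialization.
#' @param features feature names.
#' @return list with weight matrices \code{W1} (d x h), \code{b1}, \code{W2}
#'   (h x d), \code{b2}, plus the training configuration and final loss.
#' @export
fitAutoencoder <- function(featureTable, stats = NULL, hidden = 18,
                           decay = 0.005, maxit = 7000, seed = 1,
                           features = NULL) {
  X <- featureMatrix(featureTable, features)
  if (is.null(stats)) stats <- computeFeatureStats(featureTable, colnames(X))
  Z <- zTransform(X, stats)
  d <- ncol(Z)
  set.seed(seed)
  fit <- nnet::nnet(x = Z, y = Z, size = hidden, linout = TRUE,
                    decay = decay, maxit = maxit, reltol = 1e-9,
                    abstol = 1e-8, trace = FALSE, MaxNWts = 5000)
  if (any(!is.finite(fit$wts)))
    stop("autoencoder training diverged; lower the learning rate / decay")
  w <- fit$wts
  nW1 <- (d + 1) * hidden
  M1 <- matrix(w[seq_len(nW1)], nrow = d + 1)        # col = hidden unit
  M2 <- matrix(w[nW1 + seq_len((hidden + 1) * d)], nrow = hidden + 1)
  list(W1 = M1[-1, , drop = FALSE], b1 = M1[1, ],
       W2 = M2[-1, , drop = FALSE], b2 = M2[1, ],
       hidden = hidden, decay = decay, maxit = maxit, seed = seed,
       value = fit$value, features = colnames(Z))
}

aeForward <- function(Z, model) {
  H <- 1 / (1 + exp(-(sweep(Z %*% model$W1, 2, model$b1, "+"))))
  sweep(H %*% model$W2, 2, model$b2, "+")
}

#' Autoencoder mean squared reconstruction error (MSRE)
#'
#' \eqn{(1/d) \sum_d (\hat x_z - x_z)^2} on z-scored features.
#'
#' @param x feature vector, matrix or table (raw features).
#' @param model output of \code{\link{fitAutoencoder}}.
#' @param stats feature statistics used for z-scoring.
#' @return numeric vector of MSRE per row.
#' @export
aeMetric <- function(x, model, stats) {
  X <- asFeatureRows(x, stats$feature)
  Z <- zTransform(X, stats)
  Z <- Z[, model$features, drop = FALSE]
  rowMeans((aeForward(Z, model) - Z)^2)
}
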