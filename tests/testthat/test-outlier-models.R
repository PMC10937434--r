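# One-class single-contour feature models.

fakeTable <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- featureNames()[seq_len(ncol(X))]
  df
}

test_that("MAD filter removes only gross outliers", {
  set.seed(42)
  X <- matrix(rnorm(200 * 5), 200)
  tab <- fakeTable(X)
  flt <- madFilter(tab, k = 12, features = colnames(tab))
  expect_lte(flt$fraction_removed, 0.02)

  # one row displaced 20 MAD on one feature is removed, exactly that row
  med <- median(X[, 3]); madv <- median(abs(X[, 3] - med))
  tab2 <- tab
  tab2[17, 3] <- med + 20 * madv
  flt2 <- madFilter(tab2, k = 12, features = colnames(tab2))
  expect_identical(flt2$removed, 17L)

  # constant feature (MAD 0) triggers no removals
  tab3 <- tab
  tab3[, 2] <- 5
  flt3 <- madFilter(tab3, k = 12, features = colnames(tab3))
  expect_lte(flt3$fraction_removed, 0.02)

  expect_error(madFilter(fakeTable(matrix(c(0, 100), 2, 1)), k = 0.1,
                         features = "centroid_x"),
               "every training row")
})

test_that("max |z| metric with degenerate-sd rule", {
  stats <- data.frame(feature = c("f1", "f2", "f3"),
                      mean = c(10, 0, 1), sd = c(2, 1, 0),
                      median = c(10, 0, 1), mad = c(1, 1, 0))
  x <- c(f1 = 16, f2 = 0, f3 = 1)
  expect_equal(zscoreMetric(x, stats), 3)
  expect_equal(zscoreMetric(c(f1 = 10, f2 = 0, f3 = 1), stats), 0)
  # per-feature z = (1, -2, 0): the metric is the max absolute value
  expect_equal(zscoreMetric(c(f1 = 12, f2 = -2, f3 = 1), stats), 2)
  # sd = 0 feature off its mean always flags
  expect_identical(zscoreMetric(c(f1 = 10, f2 = 0, f3 = 2), stats), Inf)
})

test_that("Mahalanobis model fit and squared-distance metric", {
  set.seed(1)
  X <- matrix(rnorm(1e4 * 2), 1e4)
  tab <- fakeTable(X)
  fit <- fitMd(tab, features = colnames(tab))
  expect_equal(fit$cov, diag(2), tolerance = 0.05, ignore_attr = TRUE)

  # hand arithmetic: identity covariance, residual (3, 4) -> 25
  m1 <- list(mean = c(a = 0, b = 0), cov = diag(2), covInv = diag(2))
  expect_equal(mdMetric(c(a = 3, b = 4), m1), 25)
  # diag(4, 1), residual (2, 3) -> 4/4 + 9/1 = 10
  m2 <- list(mean = c(a = 0, b = 0), cov = diag(c(4, 1)),
             covInv = solve(diag(c(4, 1))))
  expect_equal(mdMetric(c(a = 2, b = 3), m2), 10)
  expect_equal(mdMetric(m1$mean, m1), 0)

  # n = d still yields a finite inverse through shrinkage
  Xs <- matrix(rnorm(9), 3)
  fs <- fitMd(fakeTable(Xs), features = featureNames()[1:3])
  expect_true(all(is.finite(fs$covInv)))

  # permutation of training rows leaves the model unchanged
  f1 <- fitMd(tab, features = colnames(tab))
  f2 <- fitMd(tab[sample(nrow(tab)), ], features = colnames(tab))
  expect_equal(f1$cov, f2$cov)
  expect_equal(f1$mean, f2$mean)
})

test_that("md metric equals the brute-force quadratic form", {
  set.seed(9)
  for (i in 1:100) {
    d <- sample(2:6, 1)
    n <- d + sample(5:30, 1)
    X <- matrix(rnorm(n * d), n)
    fit <- fitMd(fakeTable(X), features = featureNames()[seq_len(d)])
    x <- rnorm(d)
    names(x) <- featureNames()[seq_len(d)]
    brute <- as.numeric(t(x - fit$mean) %*% solve(fit$cov) %*% (x - fit$mean))
    expect_equal(mdMetric(x, fit), brute, tolerance = 1e-8)
  }
})

test_that("z-score and md metrics are invariant to feature reordering", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50)
  tab <- fakeTable(X)
  fn <- colnames(tab)
  stats <- computeFeatureStats(tab, fn)
  fit <- fitMd(tab, fn)
  x <- setNames(rnorm(4), fn)
  perm <- c(3, 1, 4, 2)
  statsP <- computeFeatureStats(tab[, perm], fn[perm])
  fitP <- fitMd(tab[, perm], fn[perm])
  expect_equal(zscoreMetric(x, stats), zscoreMetric(x[perm], statsP))
  expect_equal(mdMetric(x, fit), mdMetric(x[perm], fitP))
})

test_that("autoencoder reconstructs low-rank data and ranks outliers", {
  set.seed(11)
  t <- rnorm(60)
  dir <- rnorm(20)
  X <- outer(t, dir)               # rank-1, 20 features
  tab <- fakeTable(X)
  fn <- colnames(tab)
  stats <- computeFeatureStats(tab, fn)
  ae <- fitAutoencoder(tab, stats = stats, seed = 5, maxit = 3000,
                       features = fn)
  msre <- aeMetric(tab, ae, stats)
  expect_lt(mean(msre), 0.01)

  # same seed twice: identical weights
  ae2 <- fitAutoencoder(tab, stats = stats, seed = 5, maxit = 3000,
                        features = fn)
  expect_identical(ae$W1, ae2$W1)
  expect_identical(ae$b2, ae2$b2)

  # an off-manifold point reconstructs worse than the training 95th pct
  xo <- X[1, ]
  xo[3] <- xo[3] + 10 * sd(X[, 3])
  names(xo) <- fn
  expect_gt(aeMetric(xo, ae, stats), quantile(msre, 0.95))

  # and worse than the training median point
  xm <- apply(X, 2, median)
  names(xm) <- fn
  expect_gt(aeMetric(xo, ae, stats), aeMetric(xm, ae, stats))
})
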