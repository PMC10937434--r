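# Flag combination, threshold tuning, and evaluation statistics.

test_that("logical-OR combination", {
  expect_false(combineFlags(FALSE, FALSE, FALSE))
  expect_true(combineFlags(FALSE, TRUE, FALSE))
  expect_true(combineFlags(TRUE, TRUE, TRUE))
  expect_equal(combineFlags(c(TRUE, FALSE), c(FALSE, FALSE)), c(TRUE, FALSE))
})

test_that("threshold tuning maximizes combined balanced accuracy", {
  m <- c(0.1, 0.2, 0.8, 0.9)
  tr <- c(FALSE, FALSE, TRUE, TRUE)
  t1 <- tuneThreshold(m, tr)
  expect_equal(t1$ba, 1)
  expect_gt(t1$threshold, 0.2)
  expect_lt(t1$threshold, 0.8)

  # all metrics equal: the model is disabled (threshold +Inf) and BA comes
  # from the fixed flags alone
  fixed <- c(FALSE, FALSE, TRUE, FALSE)
  t2 <- tuneThreshold(rep(1, 4), tr, fixed)
  expect_identical(t2$threshold, Inf)
  expect_equal(t2$ba, 0.75)

  # a fixed CCR catch below threshold lets the tuner sit higher (the tie
  # break favors the more specific threshold)
  m3 <- c(1, 2, 3, 3.5, 9)
  tr3 <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  fx3 <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  tSolo <- tuneThreshold(m3, tr3)
  tComb <- tuneThreshold(m3, tr3, fx3)
  expect_gt(tComb$threshold, tSolo$threshold)
  expect_gte(tComb$ba, tSolo$ba)

  expect_error(tuneThreshold(m, rep(TRUE, 4)), "both classes")
})

test_that("threshold tuning equals exhaustive grid search", {
  set.seed(8)
  for (i in 1:20) {
    n <- 30
    m <- round(rnorm(n), 1)            # forces ties
    tr <- runif(n) < 0.3
    if (!any(tr) || all(tr)) next
    fixed <- runif(n) < 0.1
    got <- tuneThreshold(m, tr, fixed)
    grid <- c(-Inf, sort(unique(m)) + 1e-9, Inf)
    bas <- vapply(grid, function(t) {
      p <- (m > t) | fixed
      (mean(p[tr]) + mean(!p[!tr])) / 2
    }, numeric(1))
    expect_equal(got$ba, max(bas), tolerance = 1e-12)
  }
})

test_that("confusion metrics from counts", {
  cm <- metricsFromCounts(tp = 10, fn = 0, tn = 20, fp = 0)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$balanced_accuracy, 1)

  cm2 <- confusionMetrics(c(TRUE, TRUE, FALSE, FALSE),
                          c("erroneous", "acceptable", "acceptable",
                            "erroneous"))
  expect_equal(cm2$tp, 1); expect_equal(cm2$fp, 1)
  expect_equal(cm2$balanced_accuracy, 0.5)
  expect_error(confusionMetrics(logical(), logical()), "empty")
})

test_that("ROC AUC equals pairwise concordance", {
  expect_equal(rocAuc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(rocAuc(rep(5, 8), rep(c(FALSE, TRUE), 4)), 0.5)
  expect_equal(rocAuc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)), 0.75)

  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    m <- sample(round(rnorm(n), 1))    # with ties
    tr <- runif(n) < 0.4
    if (!any(tr) || all(tr)) next
    brute <- 0
    me <- m[tr]; ma <- m[!tr]
    for (x in me) brute <- brute + sum(x > ma) + 0.5 * sum(x == ma)
    brute <- brute / (length(me) * length(ma))
    expect_equal(rocAuc(m, tr), brute, tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  set.seed(17)
  m <- rnorm(120)
  tr <- runif(120) < 0.35
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(tr, m, direction = "<", quiet = TRUE))))
  expect_equal(rocAuc(m, tr), ref, tolerance = 1e-10)
})

test_that("balanced subsampling takes n acceptable per OAR plus all errors", {
  scores <- data.frame(
    oar_type = rep(c("a", "b"), each = 20),
    truth = rep(c(rep("acceptable", 15), rep("erroneous", 5)), 2))
  idx <- subsampleBalanced(scores, nPerOar = 5, seed = 4)
  sub <- scores[idx, ]
  expect_equal(sum(sub$truth == "acceptable" & sub$oar_type == "a"), 5)
  expect_equal(sum(sub$truth == "acceptable" & sub$oar_type == "b"), 5)
  expect_equal(sum(sub$truth == "erroneous"), 10)
  expect_identical(idx, subsampleBalanced(scores, nPerOar = 5, seed = 4))
  # n = 0 keeps only the erroneous contours
  expect_true(all(scores$truth[subsampleBalanced(scores, 0, 1)] == "erroneous"))
})

test_that("mid-p McNemar test", {
  # b = 1, c = 5: p = 2 P(X <= 1) - P(X = 1) = 0.125 exactly
  truth <- rep(TRUE, 6)
  predA <- c(TRUE, rep(FALSE, 5))
  predB <- c(FALSE, rep(TRUE, 5))
  expect_equal(mcnemarMidp(predA, predB, truth), 0.125)

  # b = c: symmetric, p = 1
  predA2 <- c(TRUE, TRUE, FALSE, FALSE)
  predB2 <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(mcnemarMidp(predA2, predB2, rep(TRUE, 4)), 1)

  # b = 0, c = 10: p = 1/1024
  expect_equal(mcnemarMidp(rep(FALSE, 10), rep(TRUE, 10), rep(TRUE, 10)),
               1 / 1024)

  # no discordant pairs
  expect_equal(mcnemarMidp(c(TRUE, FALSE), c(TRUE, FALSE), c(TRUE, FALSE)), 1)
})
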