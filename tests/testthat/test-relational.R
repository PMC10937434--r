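# CCR distribution bounds and the connectedness model.

test_that("degenerate and fitted CCR bounds", {
  # all training distances zero (touching organs): bounds [0, 2] mm
  b <- fitCcrBounds(rep(0, 30), "min_distance", "cord", "brainstem")
  expect_equal(b@lower, 0)
  expect_equal(b@upper, 2)

  # nested organs, overlap always 1: [0.98, 1]
  bo <- fitCcrBounds(rep(1, 30), "fractional_overlap", "lens_l", "eye_l")
  expect_equal(bo@lower, 0.98)
  expect_equal(bo@upper, 1)

  set.seed(2)
  g <- rgamma(5000, shape = 2, scale = 3)
  bg <- fitCcrBounds(g, "min_distance")
  expect_equal(bg@params[1], 2, tolerance = 0.1)
  expect_equal(bg@params[2], 3, tolerance = 0.1)

  bb <- fitCcrBounds(rbeta(5000, 2, 5), "fractional_overlap")
  expect_equal(bb@params[1], 2, tolerance = 0.15)
  expect_equal(bb@params[2], 5, tolerance = 0.15)
  # the expanded interval covers (nearly) all of a fresh sample
  fresh <- rbeta(2000, 2, 5)
  expect_gte(mean(fresh >= bb@lower & fresh <= bb@upper), 0.99)
})

test_that("CCR classification flags values outside the bounds", {
  b <- new("CcrBound", selectedOar = "a", comparisonOar = "b",
           feature = "fractional_overlap", params = c(2, 5),
           lower = 0.28, upper = 0.62)
  expect_false(ccrClassify(0.4, b))
  expect_true(ccrClassify(0, b))     # nested organ separated
  expect_true(ccrClassify(0.9, b))

  # distance lower bound clipped at the domain floor never flags contact
  bd <- fitCcrBounds(rep(0, 25), "min_distance")
  expect_false(ccrClassify(0, bd))
})

test_that("bound expansion is monotone: wider bounds flag no more values", {
  set.seed(5)
  v <- rgamma(500, 3, 1)
  b1 <- fitCcrBounds(v, "min_distance", expansion = 1)
  b2 <- fitCcrBounds(v, "min_distance", expansion = 3)
  probe <- seq(0, 15, by = 0.05)
  expect_true(all(ccrClassify(probe, b2) <= ccrClassify(probe, b1)))
})

test_that("parts threshold policies", {
  expect_identical(fitPartsThreshold(rep(1L, 50))$max_parts, 1L)

  t2 <- fitPartsThreshold(c(rep(1L, 95), rep(2L, 5)))
  expect_gte(t2$max_parts, 2L)

  # thyroid-like mixture: quantile at 0.9995 covers the observed maximum
  t3 <- fitPartsThreshold(c(rep(1L, 40), rep(2L, 40), rep(3L, 20)))
  expect_gte(t3$max_parts, 3L)

  expect_false(connectednessClassify(1, list(max_parts = 1)))
  expect_true(connectednessClassify(2, list(max_parts = 1)))
  expect_false(connectednessClassify(2, list(max_parts = 3)))
})

test_that("CCR matrix construction and CSV round trip", {
  M <- ccrMatrix(c("a", "b", "c"), pairs = rbind(c("a", "b"), c("b", "a")))
  expect_true(M["a", "b"] && M["b", "a"])
  expect_false(M["a", "c"])
  expect_true(all(M[, "body"]))
  expect_false(any(diag(M[, rownames(M)])))

  p <- file.path(tempdir(), "ccr.csv")
  writeCcrMatrix(M, p)
  expect_identical(readCcrMatrix(p), M)
})

test_that("validation calibration widens violated bounds only", {
  b <- new("OarModelBundle", oarType = "a", featureNames = character(),
           featureStats = data.frame(), mdModel = list(),
           repEigenvectors = list(), aeModel = list(),
           ccrBounds = list(
             new("CcrBound", selectedOar = "a", comparisonOar = "b",
                 feature = "min_distance", params = c(NA_real_, NA_real_),
                 lower = 1, upper = 4)),
           partsThreshold = list(max_parts = 1L), tunedThresholds = numeric())
  bundles <- list(a = b)
  pairs <- data.frame(set_id = c("s1", "s2"), selected = "a",
                      comparison = "b", min_distance = c(6, 2),
                      fractional_overlap = 0)
  out <- calibrateCcrBounds(bundles, pairs, acceptable = c(TRUE, TRUE))
  expect_equal(out$a@ccrBounds[[1]]@upper, 6.5)
  expect_equal(out$a@ccrBounds[[1]]@lower, 1)
  # erroneous rows never widen bounds
  out2 <- calibrateCcrBounds(bundles, pairs, acceptable = c(FALSE, TRUE))
  expect_equal(out2$a@ccrBounds[[1]]@upper, 4)
})
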