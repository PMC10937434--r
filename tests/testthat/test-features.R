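# Single-contour features of the Table-style feature set and CCR pair
# features.

test_that("relative centroid is referenced to the brainstem", {
  d <- c(30, 30, 30)
  bs <- Contour(singleVoxel(d, c(1, 1, 1)), "brainstem")
  ct <- Contour(singleVoxel(d, c(11, 1, 1)), "cord")
  ss <- StructureSet(list(bs, ct), setId = "t")
  expect_equal(relativeCentroid(ct, ss, spacing = c(1, 1, 1)), c(10, 0, 0))

  # two-voxel contour at x = 0 and 10: centroid is the mean of centers
  m <- array(FALSE, d); m[1, 1, 1] <- TRUE; m[11, 1, 1] <- TRUE
  two <- Contour(m, "eye_l")
  ss2 <- StructureSet(list(bs, two), setId = "t")
  expect_equal(relativeCentroid(two, ss2, spacing = c(1, 1, 1)), c(5, 0, 0))

  # the reference contour itself refers to the pituitary
  pit <- Contour(singleVoxel(d, c(5, 1, 1)), "pituitary")
  ss3 <- StructureSet(list(bs, pit), setId = "t")
  expect_equal(relativeCentroid(bs, ss3, spacing = c(1, 1, 1)), c(-4, 0, 0))
  # and with the pituitary check disabled it is its own zero offset
  expect_equal(relativeCentroid(bs, ss3, refOarForReference = NA,
                                spacing = c(1, 1, 1)), c(0, 0, 0))

  expect_error(relativeCentroid(ct, StructureSet(list(ct), setId = "x"),
                                spacing = c(1, 1, 1)), "missing")
})

test_that("extents use the voxel-center convention", {
  d <- c(20, 20, 20)
  expect_equal(maskExtents(Contour(singleVoxel(d, c(4, 4, 4)), "a")),
               c(0, 0, 0), ignore_attr = TRUE)
  m <- array(FALSE, d); m[3:10, 5, 5] <- TRUE
  expect_equal(maskExtents(Contour(m, "a"), c(1.27, 1, 1)),
               c(7 * 1.27, 0, 0), ignore_attr = TRUE)
  box <- mkBox(c(10, 20, 30))
  expect_equal(maskExtents(Contour(box, "b"), c(1, 1, 1)),
               c(9, 19, 29), ignore_attr = TRUE)
})

test_that("PCA shape and orientation on canonical solids", {
  # sphere: isotropic eigenvalues
  p <- pcaShapeOrientation(Contour(mkSphere(10), "s"))
  expect_equal(p$lambda2_ratio, 1, tolerance = 0.05)
  expect_equal(p$lambda3_ratio, 1, tolerance = 0.05)

  # thin tube along z: PC1 = +/- z-hat, small ratios
  d <- c(12, 12, 60)
  g <- mkGrid(d)
  tube <- (g$X - 5)^2 + (g$Y - 5)^2 <= 9 & g$Z >= 5 & g$Z <= 55
  pt <- pcaShapeOrientation(Contour(tube, "t"))
  expect_equal(abs(pt$pc1[3]), 1, tolerance = 1e-6)
  expect_lt(pt$lambda2_ratio, 0.1)

  # 40 x 20 x 10 solid box: eigenvalue ratios scale with side^2
  pb <- pcaShapeOrientation(Contour(mkBox(c(40, 20, 10)), "b"))
  expect_equal(pb$lambda2_ratio, 0.25, tolerance = 0.1)
  expect_equal(pb$lambda3_ratio, 0.0625, tolerance = 0.1)
})

test_that("representative eigenvector maximizes summed absolute dots", {
  v <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(representativeEigenvector(v), c(1, 0, 0))

  v2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(sqrt(.5), sqrt(.5), 0))
  expect_equal(representativeEigenvector(v2), c(sqrt(.5), sqrt(.5), 0))

  # orthogonal tie: lowest index wins
  v3 <- rbind(c(0, 1, 0), c(1, 0, 0))
  expect_equal(representativeEigenvector(v3), c(0, 1, 0))
})

test_that("eigenvector sign standardization", {
  r <- c(1, 0, 0)
  expect_equal(orientEigenvector(c(1, 0, 0), r), c(1, 0, 0))
  expect_equal(orientEigenvector(c(-1, 0, 0), r), c(1, 0, 0))
  # orthogonal vector (dot = 0) is returned unchanged
  expect_equal(orientEigenvector(c(0, 1, 0), r), c(0, 1, 0))
})

test_that("sphericity of canonical shapes", {
  # closed forms: sphere exactly 1, cube (pi/6)^(1/3)
  expect_equal(wadell(4 / 3 * pi * 10^3, 4 * pi * 10^2), 1, tolerance = 1e-12)
  expect_equal(wadell(16^3, 6 * 16^2), (pi / 6)^(1 / 3), tolerance = 1e-12)

  # voxelized
  expect_equal(sphericity(Contour(mkSphere(10), "s")), 1, tolerance = 0.05)
  expect_equal(sphericity(Contour(mkBox(c(16, 16, 16)), "c")),
               (pi / 6)^(1 / 3), tolerance = 0.05)

  # single voxel falls back to the voxel box
  sv <- Contour(singleVoxel(c(5, 5, 5), c(3, 3, 3)), "v")
  expect_equal(sphericity(sv, c(1, 1, 1)), wadell(1, 6), tolerance = 1e-9)
})

test_that("CT statistics within a contour", {
  d <- c(6, 6, 6)
  img <- ImageVolume(array(40, d))
  m <- array(FALSE, d); m[2:4, 2:4, 2:4] <- TRUE
  s <- ctStatistics(Contour(m, "a"), img)
  expect_equal(unname(s), c(40, 40, 40, 0))

  vox <- array(0, d); vox[2, 2, 2] <- 0; vox[3, 2, 2] <- 10; vox[4, 2, 2] <- 20
  m2 <- array(FALSE, d); m2[2:4, 2, 2] <- TRUE
  s2 <- ctStatistics(Contour(m2, "a"), ImageVolume(vox))
  expect_equal(unname(s2), c(0, 20, 10, 10))

  s3 <- ctStatistics(Contour(singleVoxel(d, c(2, 2, 2)), "a"), ImageVolume(vox))
  expect_equal(unname(s3[["ct_std"]]), 0)
  expect_error(ctStatistics(Contour(m, "a"), NULL), "no image")
})

test_that("fractional overlap is directional", {
  d <- c(20, 20, 20)
  a <- array(FALSE, d); a[3:6, 3:6, 3:6] <- TRUE
  expect_equal(fractionalOverlap(Contour(a, "a"), Contour(a, "b")), 1)
  b <- array(FALSE, d); b[10:12, 10:12, 10:12] <- TRUE
  expect_equal(fractionalOverlap(Contour(a, "a"), Contour(b, "b")), 0)
  # half of a inside c
  cc <- array(FALSE, d); cc[3:6, 3:6, 3:4] <- TRUE
  expect_equal(fractionalOverlap(Contour(a, "a"), Contour(cc, "c")), 0.5)
  expect_equal(fractionalOverlap(Contour(cc, "c"), Contour(a, "a")), 1)
})

test_that("overlap > 0 exactly when surface distance = 0 on phantom pairs", {
  ss <- generateStructureSet(phantomConfig(), seed = 3)
  sp <- c(1.27, 1.27, 2)
  pf <- extractPairFeatures(ss, defaultCcrMatrix(), spacing = sp)
  expect_gt(nrow(pf), 10)
  expect_true(all((pf$fractional_overlap > 0) == (pf$min_distance == 0)))
})

test_that("feature table is deterministic and translation-invariant", {
  cfg <- phantomConfig()
  sp <- cfg$spacing
  ss <- generateStructureSet(cfg, seed = 4)
  f1 <- extractFeatures(ss, spacing = sp)
  expect_identical(f1, extractFeatures(ss, spacing = sp))
  expect_identical(nrow(f1), length(contours(ss)))
  expect_true(all(featureNames() %in% colnames(f1)))

  # shift the whole set by a fixed voxel offset: relative centroids, shape
  # and CT features must not move
  shift <- c(3L, -2L, 1L)
  shifted <- lapply(contours(ss), function(ct)
    Contour(ContourQA:::shiftMask(mask(ct), shift), oarType(ct),
            setId = "shifted"))
  img <- imageVolume(ss)
  vox <- voxels(img)
  vs <- array(min(vox), dim(vox))
  d <- dim(vox)
  vs[(1 + shift[1]):d[1], 1:(d[2] + shift[2]), (1 + shift[3]):d[3]] <-
    vox[1:(d[1] - shift[1]), (1 - shift[2]):d[2], 1:(d[3] - shift[3])]
  ss2 <- StructureSet(shifted, image = ImageVolume(vs, spacing = sp),
                      setId = "shifted")
  f2 <- extractFeatures(ss2, spacing = sp)
  pcCols <- grep("^pc", featureNames(), value = TRUE)
  for (col in setdiff(featureNames(),
                      c("ct_min", "ct_max", "ct_mean", "ct_std", pcCols)))
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-8, label = col)
  # eigenvector signs are arbitrary until standardized against the per-OAR
  # representative direction, so compare them sign-insensitively
  for (col in pcCols)
    expect_equal(abs(f2[[col]]), abs(f1[[col]]), tolerance = 1e-6, label = col)
  # sphere volume sanity: r = 10 mm sphere is ~4.19 cc
  vol <- sum(mkSphere(10)) / 1000
  expect_equal(vol, 4.19, tolerance = 0.02)
})

test_that("greedy correlation pruning", {
  set.seed(7)
  n <- 1000
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X$dup <- X$a
  keep <- pruneCorrelated(X, 0.7)
  expect_length(intersect(c("a", "dup"), keep), 1)
  expect_true(all(c("b", "c") %in% keep))

  # negative correlation counts through the absolute value
  Y <- data.frame(x = rnorm(n))
  Y$negx <- -Y$x
  expect_length(pruneCorrelated(Y, 0.7), 1)

  # independent noise columns survive
  Z <- as.data.frame(matrix(rnorm(n * 6), n))
  expect_length(pruneCorrelated(Z, 0.7), 6)
})
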