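# Synthetic structure-set generator and the four-category error injector.

cfgT <- phantomConfig()
spT <- cfgT$spacing

test_that("generation is deterministic and anatomy constraints hold", {
  ss1 <- generateStructureSet(cfgT, seed = 7)
  ss2 <- generateStructureSet(cfgT, seed = 7)
  expect_identical(mask(ss1$brain), mask(ss2$brain))
  expect_identical(voxels(imageVolume(ss1)), voxels(imageVolume(ss2)))
  expect_identical(sort(contourNames(ss1)), sort(names(cfgT$roster)))

  # declared touching pair: cord abuts the brainstem
  expect_equal(minSurfaceDistance(ss1$cord, ss1$brainstem, spT), 0)
  # declared nested pairs: lenses inside eyes
  expect_equal(fractionalOverlap(ss1$lens_l, ss1$eye_l), 1)
  expect_equal(fractionalOverlap(ss1$lens_r, ss1$eye_r), 1)
  # parts by construction: two-lobed thyroid, single-part mandible
  expect_identical(countParts(ss1$thyroid), 2L)
  expect_identical(countParts(ss1$mandible), 1L)
  # every organ lies inside the body contour
  for (nm in contourNames(ss1))
    expect_equal(fractionalOverlap(ss1[[nm]], bodyContour(ss1)), 1,
                 label = nm)
})

test_that("position errors translate the centroid by the requested offset", {
  m <- mkSphere(8, pad = 32)
  ct <- Contour(m, "parotid_l")
  spec <- errorSpec("position", "major", seed = 1,
                    params = list(offset_mm = c(30, 0, 0)))
  out <- injectError(ct, spec = spec, spacing = c(1, 1, 1))
  c0 <- colMeans(which(m, arr.ind = TRUE))
  c1 <- colMeans(which(mask(out), arr.ind = TRUE))
  expect_equal(unname(c1 - c0), c(30, 0, 0))
  expect_identical(truthLabel(out), "erroneous")
  expect_identical(errorMeta(out)$category, "position")
})

test_that("ditzels add exactly one disconnected part at the required gap", {
  ss <- generateStructureSet(cfgT, seed = 9)
  for (oar in c("brain", "parotid_l", "cord")) {
    ct <- ss[[oar]]
    out <- injectError(ct, imageVolume(ss),
                       errorSpec("nonadjacent_slice", "moderate", seed = 3),
                       spacing = spT)
    expect_identical(countParts(out), countParts(ct) + 1L, label = oar)
    # the stray part keeps the configured clearance from the organ
    lab <- ContourQA:::labelComponents(mask(out))
    main <- which(mask(ct), arr.ind = TRUE)[1, ]
    mainLab <- lab[main[1], main[2], main[3]]
    stray <- lab > 0 & lab != mainLab
    expect_gte(minSurfaceDistance(Contour(stray, "stray"), ct, spT), 4.5)
  }
})

test_that("boundary errors grow or shrink the mask by the physical radius", {
  m <- mkSphere(10)
  ct <- Contour(m, "brainstem")
  out <- injectError(ct, spec = errorSpec("boundary", "moderate", seed = 2,
                                          params = list(radius_mm = 3,
                                                        direction = "dilate")),
                     spacing = c(1, 1, 1))
  expect_equal(sum(mask(out)) / sum(m), (13 / 10)^3, tolerance = 0.1)

  # erosion that would empty the mask is refused
  tiny <- Contour(mkSphere(2.5), "lens_l")
  expect_error(injectError(tiny,
                           spec = errorSpec("boundary", "major", seed = 1,
                                            params = list(radius_mm = 4,
                                                          direction = "erode")),
                           spacing = c(1, 1, 1)),
               "emptied")
})

test_that("volume errors add or remove the requested fraction", {
  m <- mkSphere(10)
  ct <- Contour(m, "parotid_l")
  add <- injectError(ct, spec = errorSpec("volume", "major", seed = 4,
                                          params = list(mode = "add",
                                                        fraction = 0.4)),
                     spacing = c(1, 1, 1))
  expect_gt(sum(mask(add)) / sum(m), 1.1)
  rem <- injectError(ct, spec = errorSpec("volume", "major", seed = 4,
                                          params = list(mode = "truncate",
                                                        fraction = 0.3)),
                     spacing = c(1, 1, 1))
  ratio <- sum(mask(rem)) / sum(m)
  expect_lt(ratio, 0.95)
  expect_gt(ratio, 0.2)
})

test_that("every injected contour differs and carries matching metadata", {
  ss <- generateStructureSet(cfgT, seed = 10)
  cats <- c("boundary", "volume", "nonadjacent_slice", "position")
  for (i in seq_along(cats)) {
    ct <- ss$parotid_r
    out <- injectError(ct, imageVolume(ss),
                       errorSpec(cats[i], "moderate", seed = 20 + i),
                       spacing = spT)
    expect_false(identical(mask(out), mask(ct)), label = cats[i])
    expect_identical(errorMeta(out)$category, cats[i])
    expect_identical(errorMeta(out)$severity, "moderate")
    # determinism of the injector
    out2 <- injectError(ct, imageVolume(ss),
                        errorSpec(cats[i], "moderate", seed = 20 + i),
                        spacing = spT)
    expect_identical(mask(out), mask(out2))
  }
})

test_that("error plans mirror the category mix and the per-OAR minimums", {
  set.seed(33)
  mix <- c(boundary = 74, volume = 99, nonadjacent_slice = 14, position = 40)
  plan <- ContourQA:::planErrors(sprintf("s%02d", 1:10), cfgT$roster, mix,
                                 minErrPaired = 4, minErrUnpaired = 5)
  counts <- table(plan$oar_type)
  paired <- vapply(cfgT$roster, function(o) isTRUE(o$paired), logical(1))
  for (oar in names(cfgT$roster))
    expect_gte(counts[[oar]], if (paired[[oar]]) 4 else 5)
  # category proportions match the mix to integer rounding
  catCounts <- table(factor(plan$category, names(mix)))
  expect_equal(as.numeric(catCounts) / nrow(plan),
               as.numeric(mix / sum(mix)), tolerance = 0.02)
  # thin organs never draw non-adjacent slice errors
  thin <- plan$oar_type %in% c("lens_l", "lens_r", "cochlea_l", "cochlea_r",
                               "pituitary", "eye_l", "eye_r", "thyroid",
                               "submandibular_l", "submandibular_r",
                               "oral_cavity")
  expect_false(any(plan$category[thin] == "nonadjacent_slice"))
})
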