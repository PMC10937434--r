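# 3D binary-mask geometry kernels against analytic solids.

test_that("voxel volume and surface area match analytic solids", {
  s <- mkSphere(10)
  expect_equal(sum(s), 4 / 3 * pi * 1000, tolerance = 0.02)

  A <- ContourQA:::maskSurfaceArea(s, c(1, 1, 1))
  expect_equal(A, 4 * pi * 100, tolerance = 0.05)

  # anisotropic grid, head-and-neck spacing
  sa <- mkSphere(10, c(1.27, 1.27, 2))
  Aa <- ContourQA:::maskSurfaceArea(sa, c(1.27, 1.27, 2))
  expect_equal(Aa, 4 * pi * 100, tolerance = 0.06)

  cube <- mkBox(c(16, 16, 16))
  Ac <- ContourQA:::maskSurfaceArea(cube, c(1, 1, 1))
  expect_equal(Ac, 6 * 16^2, tolerance = 0.07)
})

test_that("26-connected part counting", {
  s <- mkSphere(6)
  expect_identical(countParts(Contour(s, "s")), 1L)

  s2 <- s
  s2[2, 2, 2] <- TRUE
  expect_identical(countParts(Contour(s2, "s")), 2L)

  # two blobs sharing a single corner-adjacent voxel pair stay one part
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE
  m[5:7, 5:7, 5:7] <- TRUE
  expect_identical(countParts(Contour(m, "c")), 1L)
})

test_that("minimum surface distance", {
  d <- c(20, 20, 20)
  a <- Contour(singleVoxel(d, c(3, 3, 3)), "a")
  b <- Contour(singleVoxel(d, c(13, 3, 3)), "b")
  expect_equal(minSurfaceDistance(a, b, c(1, 1, 1)), 10)

  # overlapping masks have distance zero
  m1 <- array(FALSE, d); m1[3:8, 3:8, 3:8] <- TRUE
  m2 <- array(FALSE, d); m2[6:12, 6:12, 6:12] <- TRUE
  expect_equal(minSurfaceDistance(Contour(m1, "a"), Contour(m2, "b"),
                                  c(1, 1, 1)), 0)

  # r = 5 spheres, centers 20 mm apart: surface gap ~ 10 mm
  dd <- c(40, 18, 18)
  g <- mkGrid(dd)
  s1 <- (g$X - 8)^2 + (g$Y - 8)^2 + (g$Z - 8)^2 <= 25
  s2 <- (g$X - 28)^2 + (g$Y - 8)^2 + (g$Z - 8)^2 <= 25
  expect_equal(minSurfaceDistance(Contour(s1, "a"), Contour(s2, "b"),
                                  c(1, 1, 1)), 10, tolerance = 0.18)

  expect_error(minSurfaceDistance(a, Contour(array(FALSE, c(5, 5, 5)), "x")),
               "different grids")
})

test_that("mm-radius dilation and erosion behave like analytic offsets", {
  s <- mkSphere(10)
  dm <- ContourQA:::dilateMask(s, c(1, 1, 1), 3)
  expect_equal(sum(dm) / sum(s), (13 / 10)^3, tolerance = 0.05)
  em <- ContourQA:::erodeMask(s, c(1, 1, 1), 3)
  expect_equal(sum(em) / sum(s), (7 / 10)^3, tolerance = 0.05)
  # erosion and dilation are inverse-ordered: erode(dilate) covers the mask
  expect_true(all(s[ContourQA:::erodeMask(dm, c(1, 1, 1), 2.9) & !s] == 0))
})

test_that("integer mask translation preserves voxel count on-grid", {
  m <- singleVoxel(c(10, 10, 10), c(5, 5, 5))
  out <- ContourQA:::shiftMask(m, c(2, -1, 3))
  expect_identical(sum(out), 1L)
  expect_identical(which(out, arr.ind = TRUE)[1, ], c(dim1 = 7L, dim2 = 4L, dim3 = 8L))
})
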