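test_that("translation alignment is the centroid difference", {
  m <- array(0L, c(20, 20, 20))
  m[5:8, 5:8, 5:8] <- 1L
  fixed <- labelVolume(m, c(1, 1, 1))
  expect_equal(translation(translationAlign(fixed, fixed)), c(0, 0, 0))

  # moving = fixed shifted by +10 mm in x -> translation (-10, 0, 0)
  m2 <- array(0L, c(20, 20, 20))
  m2[15:18, 5:8, 5:8] <- 1L
  moving <- labelVolume(m2, c(1, 1, 1))
  expect_equal(translation(translationAlign(fixed, moving)), c(-10, 0, 0))

  # equal centroids, different shapes -> zero translation
  ball <- array(0L, c(20, 20, 20))
  ball[6:7, 5:8, 6:7] <- 1L  # same centroid (6.5, 6.5, 6.5) in voxels
  expect_equal(translation(translationAlign(fixed, labelVolume(ball))),
               c(0, 0, 0), tolerance = 1e-9)

  expect_error(translationAlign(fixed, labelVolume(array(0L, c(4, 4, 4)))),
               class = "lesiongraph_degenerate_error")
})

test_that("translation alignment is equivariant under mask shifts", {
  set.seed(12)
  m <- array(0L, c(24, 24, 24))
  m[cbind(sample(8:14, 5), sample(8:14, 5), sample(8:14, 5))] <- 1L
  fixed <- labelVolume(m, c(2, 2, 2))
  base <- translation(translationAlign(fixed, fixed))
  for (shift in list(c(1L, 0L, 0L), c(0L, 2L, 1L))) {
    shifted <- array(0L, c(24, 24, 24))
    idx <- which(m > 0L)
    ijk <- sweep(arrayInd(idx, dim(m)), 2L, shift, "+")
    shifted[ijk] <- 1L
    v <- shift * c(2, 2, 2)
    got <- translation(translationAlign(fixed, labelVolume(shifted,
                                                           c(2, 2, 2))))
    expect_equal(got, base - v, tolerance = 1e-9)
  }
})

test_that("label resampling is exact for identity and voxel shifts", {
  pair <- cachedPhantom("calm", calmSpec())
  lab <- pair$labels1
  out <- applyTransformLabels(lab, identityTransform(), lab)
  expect_identical(voxels(out), voxels(lab))

  # translation by exactly one voxel along x (content moves +x, so the
  # alignment offset applied to the moving content is +spacing)
  sp <- spacing(lab)
  shift <- translationTransform(c(sp[1], 0, 0))
  out <- applyTransformLabels(lab, shift, lab)
  d <- dim(lab)
  expected <- array(0L, d)
  expected[2:d[1], , ] <- voxels(lab)[1:(d[1] - 1), , ]
  expect_identical(voxels(out), expected)
  expect_true(all(voxels(out)[1, , ] == 0L))

  # nearest-neighbour never invents labels
  set.seed(3)
  t <- translationTransform(runif(3, -7, 7))
  out <- applyTransformLabels(lab, t, lab)
  expect_true(all(labelValues(out) %in% labelValues(lab)))
})

test_that("resampling through the phantom's true field recovers lesions", {
  pair <- cachedPhantom("calmDef", calmSpec(seed = 21L, amplitude = 5))
  warped <- applyTransformLabels(pair$labels2, pair$field, pair$labels1)
  # warped scan-2 lesions overlap their scan-1 counterparts
  m <- graphParts(pair$truth)$matches
  for (r in seq_len(nrow(m))) {
    a <- voxels(pair$labels1) == m[r, 1]
    b <- voxels(warped) == m[r, 2]
    expect_gt(sum(a & b) / sum(a), 0.5)
  }
})

test_that("deformable registration of identical images stays near identity", {
  pair <- cachedPhantom("reg", regSpec(), images = TRUE)
  tr <- deformableRegister(pair$ct1, pair$ct1, iterations = 20L,
                           levels = 2L)
  d <- dim(pair$ct1@voxels)
  pts <- voxelToPhys(pair$labels1,
                     as.matrix(expand.grid(seq(4, d[1] - 4, by = 9),
                                           seq(4, d[2] - 4, by = 9),
                                           seq(4, d[3] - 4, by = 7))))
  disp <- transformPoints(tr, pts) - pts
  expect_lt(mean(sqrt(rowSums(disp^2))), 0.5)
})

test_that("deformable registration recovers a smooth 8 mm deformation", {
  pair <- cachedPhantom("reg", regSpec(), images = TRUE)
  centres <- pair$info$centers1
  truthPts <- pair$info$deform(centres)
  before <- mean(sqrt(rowSums((centres - truthPts)^2)))
  tr <- deformableRegister(pair$ct1, pair$ct2)
  after <- mean(sqrt(rowSums((transformPoints(tr, centres) -
                                truthPts)^2)))
  expect_gt(before, 3)   # the deformation actually displaced the lesions
  expect_lte(after, 3)   # and registration brought them back
})

test_that("composite of a known translation and no deformation stays rigid", {
  pair <- cachedPhantom("reg", regSpec(), images = TRUE)
  off <- c(6, -4, 3)
  shifted <- imageVolume(pair$ct1@voxels, spacing(pair$labels1),
                         origin = origin(pair$labels1) + off)
  # fixed content sits +off from the moving content, so the alignment
  # shift applied to the moving image is +off
  init <- translationTransform(off)
  tr <- deformableRegister(shifted, pair$ct1, init = init,
                           iterations = 20L, levels = 2L)
  d <- dim(pair$ct1@voxels)
  pts <- voxelToPhys(shifted,
                     as.matrix(expand.grid(seq(6, d[1] - 6, by = 11),
                                           seq(6, d[2] - 6, by = 11),
                                           seq(6, d[3] - 6, by = 9))))
  resid <- transformPoints(tr, pts) - transformPoints(init, pts)
  expect_lt(mean(sqrt(rowSums(resid^2))), 0.5)
})

test_that("unsupported metric raises a capability error, disjoint images fail", {
  pair <- cachedPhantom("reg", regSpec(), images = TRUE)
  expect_error(deformableRegister(pair$ct1, pair$ct2, metric = "mi"),
               class = "lesiongraph_capability_error")
  far <- translationTransform(c(1e4, 0, 0))
  expect_error(deformableRegister(pair$ct1, pair$ct2, init = far),
               class = "lesiongraph_registration_error")
})
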