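test_that("a quiet phantom is the identity: no events, no deformation", {
  pair <- cachedPhantom("calm", calmSpec())
  n <- length(nodes1(pair$truth))
  expect_identical(voxels(pair$labels2), voxels(pair$labels1))
  expect_true(graphEqual(pair$truth,
                         buildGraph(seq_len(n), seq_len(n),
                                    cbind(seq_len(n), seq_len(n)))))
  expect_equal(max(abs(pair$field@field)), 0)
})

test_that("pDisappear = 1 empties scan 2", {
  spec <- phantomSpec(gridShape = c(48L, 48L, 32L), spacingMm = c(3, 3, 3),
                      nLesions = 3L, volumeRangeCm3 = c(0.3, 1),
                      pDisappear = 1, pNew = 0, pSplit = 0, pMerge = 0,
                      deformationAmplitudeMm = 0, minSeparationMm = 40,
                      seed = 9L)
  pair <- generatePhantomPair(spec, images = FALSE)
  expect_true(all(voxels(pair$labels2) == 0L))
  expect_setequal(edgeKeys(pair$truth),
                  paste0(1:3, "|DISAPPEARED"))
})

test_that("identical seeds generate bit-identical phantoms", {
  spec <- phantomSpec(gridShape = c(48L, 48L, 32L), spacingMm = c(3, 3, 3),
                      nLesions = 3L, volumeRangeCm3 = c(0.3, 1),
                      minSeparationMm = 40, seed = 14L)
  a <- generatePhantomPair(spec)
  b <- generatePhantomPair(spec)
  expect_identical(voxels(a$labels1), voxels(b$labels1))
  expect_identical(voxels(a$labels2), voxels(b$labels2))
  expect_identical(a$ct1@voxels, b$ct1@voxels)
  expect_identical(a$field@field, b$field@field)
  expect_true(graphEqual(a$truth, b$truth))
})

test_that("event bookkeeping matches the sentinel edges in the truth", {
  spec <- phantomSpec(nLesions = 12L, pDisappear = 0.3, pNew = 0.3,
                      pSplit = 0.2, pMerge = 0.2, seed = 27L)
  pair <- generatePhantomPair(spec, images = FALSE)
  p <- graphParts(pair$truth)
  roles <- pair$info$roles
  expect_length(p$disappeared, sum(roles == "disappear"))
  expect_length(p$new, pair$info$nNew)
  # each split parent has exactly two fragment edges
  for (i in which(roles == "split"))
    expect_length(which(p$matches[, 1] == i), 2)
  # merged pairs share one scan-2 lesion
  mp <- pair$info$mergePairs
  for (r in seq_len(NROW(mp))) {
    j1 <- p$matches[p$matches[, 1] == mp[r, 1], 2]
    j2 <- p$matches[p$matches[, 1] == mp[r, 2], 2]
    expect_identical(j1, j2)
  }
  expect_length(validateGraph(pair$truth), 0)
})

test_that("generated lesion volumes stay inside the requested band", {
  spec <- phantomSpec(nLesions = 10L, volumeRangeCm3 = c(0.05, 2),
                      seed = 41L)
  pair <- generatePhantomPair(spec, images = FALSE)
  vv <- voxelVolumeCm3(pair$labels1)
  vols <- lesionVolumes(lesionSet(pair$labels1))
  expect_true(all(vols >= 0.05 - vv))
  expect_true(all(vols <= 2 + vv))
})

test_that("infeasible packing raises a generation error", {
  spec <- phantomSpec(gridShape = c(24L, 24L, 16L), spacingMm = c(2, 2, 2),
                      nLesions = 40L, seed = 2L)
  expect_error(generatePhantomPair(spec),
               class = "lesiongraph_generation_error")
})

test_that("recovery is perfect without deformation and degrades beyond it", {
  # identity case: no events, no deformation, identity registration
  rep0 <- truthRecoveryScore(calmSpec(seed = 6L),
                             matchConfig(regMode = "identity"))
  expect_equal(rep0@f1, 1)
  expect_identical(rep0@nDifferences, 0L)

  # a deformation well beyond the dilation tolerance: with both scans'
  # lesions dilated the matcher's reach is about twice the dilation radius
  # plus the lesion radii, so 40 mm displacement against 10 mm dilation is
  # unrecoverable without registration, while the true field restores a
  # perfect score
  spec40 <- phantomSpec(gridShape = c(128L, 128L, 80L),
                        spacingMm = c(3, 3, 3), nLesions = 8L,
                        volumeRangeCm3 = c(0.2, 1),
                        pDisappear = 0, pNew = 0, pSplit = 0, pMerge = 0,
                        deformationAmplitudeMm = 40,
                        seed = 17L)
  repField <- truthRecoveryScore(spec40, matchConfig(regMode = "field",
                                                     dilationMm = 10))
  repIdent <- truthRecoveryScore(spec40, matchConfig(regMode = "identity",
                                                     dilationMm = 10))
  expect_gte(repField@f1 - repIdent@f1, 0.3)
})
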