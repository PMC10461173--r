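test_that("component labelling respects connectivity and raster order", {
  m <- array(0L, c(6, 6, 3))
  m[2, 2, 2] <- 1L
  m[5, 5, 2] <- 1L
  lab <- labelComponents(labelVolume(m))
  expect_setequal(labelValues(lab), 1:2)
  expect_identical(voxels(lab)[2, 2, 2], 1L)  # first in raster order

  # two voxels touching only diagonally
  m <- array(0L, c(4, 4, 4))
  m[2, 2, 2] <- 1L
  m[3, 3, 3] <- 1L
  v <- labelVolume(m)
  expect_length(labelValues(labelComponents(v, 26L)), 1)
  expect_length(labelValues(labelComponents(v, 6L)), 2)
  # edge-adjacent (two axes differ): joined at 18 but not at 6
  m2 <- array(0L, c(4, 4, 4))
  m2[2, 2, 2] <- 1L
  m2[3, 3, 2] <- 1L
  expect_length(labelValues(labelComponents(labelVolume(m2), 18L)), 1)
  expect_length(labelValues(labelComponents(labelVolume(m2), 6L)), 2)

  # empty mask
  empty <- labelComponents(labelVolume(array(0L, c(4, 4, 4))))
  expect_length(labelValues(empty), 0)
})

test_that("volume filtering is strict at the threshold", {
  arr <- array(0L, c(12, 12, 12))
  arr[1:4, 1:5, 1:5] <- 1L          # 100 voxels = 0.1 cm^3 at 1 mm iso
  arr[8:12, 8:12, 8:11] <- 2L       # 100 voxels
  arr[12, 12, 12] <- 2L             # +1 -> 101 voxels
  ls <- lesionSet(labelVolume(arr, c(1, 1, 1)))
  expect_equal(unname(lesionVolumes(ls)), c(0.100, 0.101))
  kept <- filterByVolume(ls, 0.1)
  expect_identical(kept@indices, 2L)      # 0.1 exactly is removed
  expect_length(filterByVolume(ls, 0), 2) # zero threshold keeps all
})

test_that("dilation matches brute-force physical-distance enumeration", {
  # single voxel, isotropic 1 mm, radius 2 mm -> 33 voxels
  m <- array(0L, c(9, 9, 9)); m[5, 5, 5] <- 1L
  ls <- dilateLesions(lesionSet(labelVolume(m, c(1, 1, 1))), 2)
  expect_identical(sum(ls@dilated[[1]]$mask), 33L)

  # same voxel, spacing (1, 1, 5): in-plane disk only -> 13 voxels
  ls <- dilateLesions(lesionSet(labelVolume(m, c(1, 1, 5))), 2)
  expect_identical(sum(ls@dilated[[1]]$mask), 13L)

  # radius 0 leaves masks unchanged
  ls <- dilateLesions(lesionSet(labelVolume(m, c(1, 1, 1))), 0)
  expect_identical(ls@dilated[[1]]$mask, ls@masks[[1]]$mask)

  # random blobs on an anisotropic grid vs the brute-force oracle
  set.seed(31)
  for (trial in 1:4) {
    d <- c(10, 9, 8)
    sp <- c(1.3, 0.9, 2.1)
    arr <- array(0L, d)
    arr[cbind(sample(3:8, 4), sample(3:7, 4), sample(3:6, 4))] <- 1L
    arr <- voxels(labelComponents(labelVolume(arr, sp)))
    lv <- labelVolume(arr, sp)
    ls <- dilateLesions(lesionSet(lv), 3.5)
    got <- Reduce(`|`, lapply(ls@dilated, fullMask, gridDim = d))
    expect_identical(got, bruteDilate(arr, sp, 3.5))
  }
})

test_that("mask invariant: dilated masks contain the original masks", {
  pair <- cachedPhantom("calm", calmSpec())
  ls <- dilateLesions(lesionSet(pair$labels1), 25)
  for (i in seq_along(ls@indices)) {
    a <- fullMask(ls@masks[[i]], ls@dim)
    b <- fullMask(ls@dilated[[i]], ls@dim)
    expect_true(all(b[a]))
  }
})

test_that("within-scan clustering groups lesions by dilated overlap", {
  d <- c(40, 12, 12)
  sp <- c(5, 5, 5)
  arr <- array(0L, d)
  arr[4, 6, 6] <- 1L    # x = 15 mm
  arr[6, 6, 6] <- 2L    # x = 25 mm: 10 mm gap -> one cluster at 25 mm
  arr[38, 6, 6] <- 3L   # x = 185 mm: 160 mm away -> singleton
  ls <- dilateLesions(lesionSet(labelVolume(arr, sp)), 25)
  cl <- clusterWithinScan(ls)
  expect_equal(cl$clusters, list(c(1L, 2L), 3L), ignore_attr = TRUE)

  # single lesion -> one singleton cluster
  one <- array(0L, c(8, 8, 8)); one[4, 4, 4] <- 1L
  cl1 <- clusterWithinScan(dilateLesions(lesionSet(labelVolume(one)), 5))
  expect_equal(cl1$clusters, list(1L), ignore_attr = TRUE)
})

test_that("intersection volumes equal direct voxel counting", {
  d <- c(16, 16, 8)
  a <- array(0L, d); a[3:12, 3:12, 3:6] <- 1L
  b <- array(0L, d); b[8:15, 8:15, 2:5] <- 1L
  lsa <- dilateLesions(lesionSet(labelVolume(a, c(1, 1, 1))), 0)
  lsb <- dilateLesions(lesionSet(labelVolume(b, c(1, 1, 1))), 0)
  m <- intersectionMatrix(clusterWithinScan(lsa), clusterWithinScan(lsb))
  expect_equal(m[1, 1], sum(a > 0 & b > 0) / 1000)

  # identical 500-voxel masks at 1 mm isotropic -> 0.5 cm^3
  c5 <- array(0L, d); c5[1:10, 1:10, 1:5] <- 1L
  lsc <- dilateLesions(lesionSet(labelVolume(c5, c(1, 1, 1))), 0)
  m2 <- intersectionMatrix(clusterWithinScan(lsc), clusterWithinScan(lsc))
  expect_equal(m2[1, 1], 0.5)

  # disjoint masks -> zero
  e <- array(0L, d); e[14:16, 14:16, 7:8] <- 1L
  lse <- dilateLesions(lesionSet(labelVolume(e, c(1, 1, 1))), 0)
  expect_equal(intersectionMatrix(clusterWithinScan(lsa),
                                  clusterWithinScan(lse))[1, 1], 0)

  # geometry mismatch is an error
  lsf <- dilateLesions(lesionSet(labelVolume(a, c(2, 1, 1))), 0)
  expect_error(intersectionMatrix(clusterWithinScan(lsa),
                                  clusterWithinScan(lsf)),
               class = "lesiongraph_validation_error")
})

test_that("assignment maximises overlap and forbids zero cells", {
  expect_equal(solveAssignment(matrix(2.0, 1, 1))$pairs,
               cbind(1L, 1L), ignore_attr = TRUE)

  # [[5,1],[2,3]]: diagonal total 8 beats 3
  w <- rbind(c(5, 1), c(2, 3))
  expect_equal(solveAssignment(w)$pairs, cbind(1:2, 1:2),
               ignore_attr = TRUE)

  # [[5,1],[4,0]]: (2,2) forbidden; totals tie at 5 and the
  # lexicographically smaller {(1,1)} wins, row 2 / col 2 unmatched
  w <- rbind(c(5, 1), c(4, 0))
  sol <- solveAssignment(w)
  expect_equal(sol$pairs, cbind(1L, 1L), ignore_attr = TRUE)
  expect_equal(sol$unmatchedRows, 2L)
  expect_equal(sol$unmatchedCols, 2L)
  expect_equal(sol$total, 5)
})

test_that("assignment agrees with exhaustive search on random matrices", {
  set.seed(99)
  for (trial in 1:60) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    w <- matrix(runif(nr * nc), nr, nc)
    w[runif(nr * nc) < 0.35] <- 0   # sprinkle forbidden cells
    sol <- solveAssignment(w)
    oracle <- exhaustiveAssignment(w)
    expect_equal(sol$total, oracle$total, tolerance = 1e-9)
    expect_equal(sol$pairs, oracle$pairs, ignore_attr = TRUE)
  }
})

test_that("assigned total is invariant under row/column permutation", {
  set.seed(77)
  for (trial in 1:20) {
    w <- matrix(runif(20), 4, 5)
    w[runif(20) < 0.3] <- 0
    base <- solveAssignment(w)$total
    pr <- sample(4); pc <- sample(5)
    expect_equal(solveAssignment(w[pr, pc])$total, base,
                 tolerance = 1e-9)
  }
})

test_that("cluster assignment expands to lesion edges (merge case)", {
  d <- c(60, 16, 16)
  sp <- c(2.5, 2.5, 2.5)
  a <- array(0L, d)
  a[10:13, 7:10, 7:10] <- 1L
  a[20:23, 7:10, 7:10] <- 2L   # 17.5 mm gap from lesion 1 -> same cluster
  b <- array(0L, d)
  b[10:23, 7:10, 7:10] <- 5L   # spans both: a merge
  ls1 <- dilateLesions(lesionSet(labelVolume(a, sp)), 25)
  ls2 <- dilateLesions(lesionSet(labelVolume(b, sp)), 25)
  c1 <- clusterWithinScan(ls1)
  c2 <- clusterWithinScan(ls2)
  sol <- solveAssignment(intersectionMatrix(c1, c2))
  g <- expandToLesionEdges(sol$pairs, ls1, ls2, c1, c2)
  expect_setequal(edgeKeys(g), c("1|5", "2|5"))

  # unmatched scan-2 singleton becomes NEW
  b2 <- b
  b2[50:54, 7:10, 7:10] <- 7L
  ls2b <- dilateLesions(lesionSet(labelVolume(b2, sp)), 25)
  c2b <- clusterWithinScan(ls2b)
  solb <- solveAssignment(intersectionMatrix(c1, c2b))
  gb <- expandToLesionEdges(solb$pairs, ls1, ls2b, c1, c2b)
  expect_true("NEW|7" %in% edgeKeys(gb))
  expect_length(validateGraph(gb), 0)
})

test_that("pipeline on an identical pair returns the identity graph", {
  pair <- cachedPhantom("calm", calmSpec())
  res <- matchPipeline(pair$labels1, pair$labels1)
  n <- length(nodes1(res$graph))
  expect_true(graphEqual(res$graph,
                         buildGraph(seq_len(n), seq_len(n),
                                    cbind(seq_len(n), seq_len(n)))))

  # deleting one lesion sends it to DISAPPEARED, rest unchanged
  arr <- voxels(pair$labels1)
  drop <- nodes1(pair$truth)[1]
  arr[arr == drop] <- 0L
  del <- labelVolume(arr, spacing(pair$labels1))
  res2 <- matchPipeline(pair$labels1, del)
  expect_true(paste0(drop, "|DISAPPEARED") %in% edgeKeys(res2$graph))
  others <- setdiff(nodes1(res2$graph), drop)
  expect_true(all(paste0(others, "|", others) %in% edgeKeys(res2$graph)))
})

test_that("pipeline handles empty scans and binary inputs", {
  zero <- labelVolume(array(0L, c(16, 16, 8)), c(3, 3, 3))
  res <- matchPipeline(zero, zero)
  expect_length(edgeKeys(res$graph), 0)
  expect_length(validateGraph(res$graph), 0)

  # binary input gets component-indexed (26-connectivity default)
  arr <- array(0L, c(24, 24, 8))
  arr[3:6, 3:6, 3:6] <- 1L
  arr[18:21, 18:21, 3:6] <- 1L
  bin <- labelVolume(arr, c(3, 3, 3))
  res <- matchPipeline(bin, bin)
  expect_setequal(edgeKeys(res$graph), c("1|1", "2|2"))
})

test_that("pipeline runs are deterministic and dilation is monotone", {
  pair <- cachedPhantom("calmDef", calmSpec(seed = 21L, amplitude = 5))
  cfg <- matchConfig(regMode = "field")
  r1 <- matchPipeline(pair$labels1, pair$labels2, field = pair$field,
                      config = cfg)
  r2 <- matchPipeline(pair$labels1, pair$labels2, field = pair$field,
                      config = cfg)
  expect_true(graphEqual(r1$graph, r2$graph))

  # growing the dilation never loses real-real edges on a fixed pair
  realEdges <- function(dil) {
    g <- matchPipeline(pair$labels1, pair$labels2, field = pair$field,
                       config = matchConfig(dilationMm = dil,
                                            regMode = "field"))$graph
    nrow(graphParts(g)$matches)
  }
  counts <- vapply(c(5, 15, 25, 35), realEdges, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("filtering before matching equals discarding edges afterwards", {
  # volumes straddle the threshold; identity pair, so no resampling can
  # flip a lesion across it and the filter/match order must commute
  pair <- cachedPhantom("straddle",
                        phantomSpec(gridShape = c(64L, 64L, 48L),
                                    spacingMm = c(3, 3, 3), nLesions = 5L,
                                    volumeRangeCm3 = c(0.02, 1.5),
                                    pDisappear = 0, pNew = 0, pSplit = 0,
                                    pMerge = 0, deformationAmplitudeMm = 0,
                                    seed = 33L))
  unfiltered <- matchPipeline(pair$labels1, pair$labels2,
                              config = matchConfig(minVolumeCm3 = 0))
  filtered <- matchPipeline(pair$labels1, pair$labels2,
                            config = matchConfig(minVolumeCm3 = 0.1))
  restricted <- restrictGraph(unfiltered$graph,
                              filtered$provenance$kept1,
                              filtered$provenance$kept2)
  expect_true(graphEqual(filtered$graph, restricted))
})

test_that("field mode without a field is a capability error", {
  zero <- labelVolume(array(0L, c(8, 8, 8)))
  expect_error(matchPipeline(zero, zero,
                             config = matchConfig(regMode = "field")),
               class = "lesiongraph_capability_error")
})
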