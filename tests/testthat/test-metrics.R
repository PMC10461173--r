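test_that("metric formulas match direct set arithmetic", {
  eA <- c("1|1", "2|2", "3|DISAPPEARED")
  eB <- c("1|1", "2|6", "3|DISAPPEARED")
  expect_equal(edgePrecision(eA, eB), 2 / 3)
  expect_equal(edgeRecall(eA, eB), 2 / 3)
  expect_equal(edgePrecision(eA, eA), 1)
  expect_equal(edgePrecision(c("1|1"), c("2|2")), 0)

  # |A n B| = 3, |B| = 5
  eA <- c("1|1", "2|2", "3|3")
  eB <- c("1|1", "2|2", "3|3", "4|4", "5|5")
  expect_equal(edgeRecall(eA, eB), 0.6)

  # |A n B| = 3, |A\B| = 1, |B\A| = 2 -> F = 6/9
  eA <- c("1|1", "2|2", "3|3", "9|9")
  eB <- c("1|1", "2|2", "3|3", "7|7", "8|8")
  expect_equal(edgeF1(eA, eB), 6 / 9)
  expect_equal(numDifferences(eA, eB), 3)
})

test_that("the disagreement pattern around one relocated lesion costs 3", {
  # reader A: lesion disappeared and a new one appeared; reader B: same
  # physical lesion matched across scans
  eA <- c("1|DISAPPEARED", "NEW|9")
  eB <- c("1|9")
  expect_equal(numDifferences(eA, eB), 3)
  expect_equal(edgePrecision(eA, eB), 0)
  expect_equal(edgeRecall(eA, eB), 0)
  expect_equal(edgeF1(eA, eB), 0)
})

# A second random matching over the same node sets as g.
randomGraphOver <- function(g) {
  n1 <- nodes1(g); n2 <- nodes2(g)
  m <- NULL
  for (i in n1)
    if (stats::runif(1) < 0.6 && length(n2))
      m <- rbind(m, c(i, pickOne(n2)))
  buildGraph(n1, n2, unique(m))
}

test_that("metric identities hold on random graph pairs", {
  set.seed(202)
  for (trial in 1:100) {
    gA <- randomGraph()
    gB <- buildGraph(nodes1(gA), nodes2(gA),
                     graphParts(randomGraphOver(gA))$matches)
    a <- edgeKeys(gA); b <- edgeKeys(gB)
    # symmetry of F1 and N_d; precision/recall swap
    expect_identical(edgeF1(a, b), edgeF1(b, a))
    expect_identical(numDifferences(a, b), numDifferences(b, a))
    expect_identical(edgePrecision(a, b), edgeRecall(b, a))
    expect_identical(edgeRecall(a, b), edgePrecision(b, a))
    # N_d = 0 <=> F1 = 1
    expect_identical(numDifferences(a, b) == 0L, edgeF1(a, b) == 1)
    # harmonic-mean route agrees with the set-cardinality route
    p <- edgePrecision(a, b); r <- edgeRecall(a, b)
    if (p + r > 0)
      expect_equal(edgeF1(a, b), 2 * p * r / (p + r), tolerance = 1e-12)
    # bounds
    expect_true(all(c(p, r, edgeF1(a, b)) >= 0))
    expect_true(all(c(p, r, edgeF1(a, b)) <= 1))
    expect_lte(numDifferences(a, b), length(a) + length(b))
    # dual route for N_d: edge-by-edge scan
    scan <- sum(!a %in% b) + sum(!b %in% a)
    expect_identical(numDifferences(a, b), scan)
  }
})

test_that("compareGraphs enforces identical node sets and swaps correctly", {
  gA <- buildGraph(1:3, 1:3, cbind(1:3, 1:3))
  gB <- buildGraph(1:3, 1:3, rbind(c(1L, 1L), c(2L, 3L)))
  rep <- compareGraphs(gA, gB)
  repSwap <- compareGraphs(gB, gA)
  expect_equal(rep@precision, repSwap@recall)
  expect_equal(rep@recall, repSwap@precision)
  expect_equal(rep@f1, repSwap@f1)
  expect_identical(rep@nDifferences, repSwap@nDifferences)

  same <- compareGraphs(gA, gA)
  expect_equal(c(same@precision, same@recall, same@f1), c(1, 1, 1))
  expect_identical(same@nDifferences, 0L)

  gC <- buildGraph(1:4, 1:3, cbind(1:3, 1:3))
  expect_error(compareGraphs(gA, gC), "different node sets",
               class = "lesiongraph_validation_error")
})

test_that("empty edge sets are flagged, not errors", {
  gE <- buildGraph(integer(0), integer(0), NULL)
  rep <- compareGraphs(gE, gE)
  expect_equal(rep@f1, 1)
  expect_true(all(c("empty_e_a", "empty_e_b") %in% rep@flags))
})

test_that("summarizeMetrics reports median and range per metric", {
  reports <- list(
    compareGraphs(buildGraph(1:2, 1:2, cbind(1:2, 1:2)),
                  buildGraph(1:2, 1:2, cbind(1:2, 1:2))),
    compareGraphs(buildGraph(1:2, 1:2, cbind(1:2, 1:2)),
                  buildGraph(1:2, 1:2, rbind(c(1L, 1L)))),
    compareGraphs(buildGraph(1:2, 1:2, cbind(1:2, 1:2)),
                  buildGraph(1:2, 1:2, rbind(c(1L, 2L)))))
  s <- summarizeMetrics(reports)
  expect_setequal(s$metric, c("precision", "recall", "f1", "n_differences"))
  f1s <- vapply(reports, function(r) r@f1, numeric(1))
  expect_equal(s$median[s$metric == "f1"], median(f1s))
  expect_equal(s$min[s$metric == "f1"], min(f1s))
  expect_equal(s$max[s$metric == "f1"], max(f1s))
})
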