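# Permutation cluster-mass statistic: observed maps, labeling, null
# distribution, corrected threshold and masked extraction.

test_that("observed t matches the hand-computed pooled toy case", {
  # per pixel: A = {1,2,3}, B = {4,5,6} -> diff -3, t = -3.674
  x <- array(rep(c(1, 2, 3, 4, 5, 6), each = 4), c(2, 2, 6))
  obs <- observedStats(x, rep(c("A", "B"), each = 3))
  expect_equal(obs$diff, matrix(-3, 2, 2))
  expect_equal(obs$t, matrix(-3 / sqrt(2 / 3), 2, 2), tolerance = 1e-9)
  expect_equal(round(obs$t[1, 1], 3), -3.674)
  expect_equal(obs$df, 4)
})

test_that("identical groups give identically zero maps", {
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  x2 <- array(c(x, x), c(3, 4, 10))
  obs <- observedStats(x2, rep(c("A", "B"), each = 5))
  expect_equal(obs$diff, matrix(0, 3, 4))
  expect_equal(obs$t, matrix(0, 3, 4))
})

test_that("t maps match the brute-force oracle on random arrays", {
  set.seed(7)
  for (k in 1:3) {
    x <- array(rnorm(8 * 8 * 20), c(8, 8, 20))
    gA <- rep(c(TRUE, FALSE), 10)
    labels <- ifelse(gA, "A", "B")
    obs <- observedStats(x, labels, groupA = "A")
    expect_equal(obs$t, bfTMap(x, gA), tolerance = 1e-10)
  }
})

test_that("relabeling trial order leaves observed statistics unchanged", {
  set.seed(8)
  x <- array(rnorm(5 * 6 * 30), c(5, 6, 30))
  labels <- rep(c("A", "B"), 15)
  prm <- sample(30)
  o1 <- observedStats(x, labels, groupA = "A")
  o2 <- observedStats(x[, , prm], labels[prm], groupA = "A")
  expect_equal(o1$t, o2$t, tolerance = 1e-12)
  expect_equal(o1$diff, o2$diff, tolerance = 1e-12)
})

test_that("connected components use 8-connectivity with stable labels", {
  m <- matrix(FALSE, 5, 5)
  expect_equal(findClusters(m)$n, 0)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE        # diagonal touch -> one cluster
  fc <- findClusters(m)
  expect_equal(fc$n, 1)
  expect_equal(fc$sizes, 2)
  # row-major discovery: the component seen first scanning rows is label 1
  m2 <- matrix(FALSE, 5, 6)
  m2[3, 1] <- TRUE                         # row 3
  m2[1, 5] <- TRUE                         # row 1 -> discovered first
  fc2 <- findClusters(m2)
  expect_equal(fc2$labels[1, 5], 1L)
  expect_equal(fc2$labels[3, 1], 2L)
})

test_that("labeling equals exhaustive flood fill on random masks", {
  set.seed(11)
  for (k in 1:20) {
    m <- matrix(runif(20 * 20) < 0.35, 20, 20)
    expect_identical(findClusters(m)$labels, bfFloodFill(m))
  }
})

test_that("constant master arrays produce an all-zero null", {
  x <- array(5, c(4, 4, 24))
  null <- suppressMessages(permutationNull(x, rep(c("A", "B"), 12),
                                           nPerm = 120, seed = 2))
  expect_equal(length(null), 120)
  expect_true(all(null == 0))
  expect_warning(permutationNull(x, rep(c("A", "B"), 12), nPerm = 50,
                                 seed = 1), "unstable")
})

test_that("the permutation null is deterministic given the seed", {
  set.seed(3)
  x <- array(rnorm(6 * 8 * 30), c(6, 8, 30))
  labels <- rep(c("A", "B"), 15)
  n1 <- permutationNull(x, labels, nPerm = 150, seed = 99)
  n2 <- permutationNull(x, labels, nPerm = 150, seed = 99)
  expect_identical(n1, n2)
  expect_false(identical(n1, permutationNull(x, labels, nPerm = 150,
                                             seed = 100)))
})

test_that("the corrected threshold uses the 100(1 - alpha/nRois) percentile", {
  null <- 1:1000
  th <- correctedThreshold(null, nRois = 3, alpha = 0.05)
  expect_equal(th$percentile, 98.3)
  expect_equal(th$threshold, 1000 * (1 - 0.05 / 3), tolerance = 1e-9)  # ~983.3
  expect_equal(correctedThreshold(null, nRois = 1)$percentile, 95)
  expect_error(correctedThreshold(null, nRois = 3, alpha = 0), "0, 1")
  expect_error(correctedThreshold(numeric(0)), "empty")
})

test_that("cluster masses and significance match the brute-force chain", {
  set.seed(12)
  x <- array(rnorm(8 * 8 * 20), c(8, 8, 20))
  x[2:4, 3:6, 1:10] <- x[2:4, 3:6, 1:10] + 3    # group effect
  labels <- rep(c("A", "B"), each = 10)
  cr <- clusterTest(x, labels, nPerm = 300, seed = 5)
  # oracle: flood-fill labels + direct mass sums on the brute-force t map
  tcrit <- qt(0.975, 18)
  bft <- bfTMap(x, labels == "A")
  lab <- bfFloodFill(abs(bft) > tcrit)
  expect_identical(cr@labels, lab)
  expect_equal(cr@mass, bfMasses(bft, lab), tolerance = 1e-10)
  expect_true(any(cr@significant))
  expect_true(all(cr@mass[cr@significant] >= cr@massThreshold))
  tab <- clusterTable(cr)
  expect_equal(nrow(tab), length(cr@mass))
  expect_true(all(tab$p[tab$significant] <= 0.05 / 3 + 1 / cr@nPerm))
})

test_that("no suprathreshold pixels yield an empty result", {
  x <- array(rnorm(4 * 4 * 40, sd = 0.01), c(4, 4, 40))
  obs <- observedStats(x, rep(c("A", "B"), 20))
  obs$t <- matrix(0.1, 4, 4)               # force subthreshold
  cr <- significantClusters(obs, null = rep(1, 200))
  expect_equal(length(cr@mass), 0)
  expect_false(any(cr@mask))
})

test_that("cluster mass grows with the injected effect size", {
  masses <- vapply(c(0, -2, -5, -10), function(d) {
    set.seed(31)
    x <- array(rnorm(20 * 25 * 60), c(20, 25, 60))
    x[5:10, 8:16, 1:30] <- x[5:10, 8:16, 1:30] + d
    obs <- observedStats(x, rep(c("A", "B"), each = 30))
    msk <- abs(obs$t) > qt(0.975, 58)
    if (!any(msk)) return(0)
    fc <- findClusters(msk)
    max(vapply(seq_len(fc$n), function(i) sum(abs(obs$t)[fc$labels == i]),
               numeric(1)))
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("masked power extraction reduces maps to per-subject scalars", {
  mask <- matrix(FALSE, 3, 4); mask[2, 3] <- TRUE
  maps <- list(s1 = matrix(1:12, 3, 4), s2 = matrix(0.5, 3, 4))
  expect_equal(extractMaskedPower(maps, mask),
               c(s1 = maps$s1[2, 3], s2 = 0.5))
  maskAll <- matrix(TRUE, 3, 4)
  expect_equal(unname(extractMaskedPower(maps, maskAll)[2]), 0.5)
  arr <- array(2, c(3, 4, 5))
  expect_equal(unname(extractMaskedPower(arr, mask)), rep(2, 5))
  expect_error(extractMaskedPower(maps, matrix(FALSE, 3, 4)), "empty")
  expect_error(extractMaskedPower(list(matrix(1, 2, 2)), mask), "mismatch")
})
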