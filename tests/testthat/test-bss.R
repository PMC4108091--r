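unitPts <- function() envelopePoints(c(0, 0.25, 0.5, 1), c(0, 0.25, 0.5, 1))

test_that("standardization maps each axis to [0,1] and is idempotent", {
  pts <- envelopePoints(c(0, 5, 10), c(3, 4, 9))
  std <- standardizeEnvelope(pts)
  expect_equal(std@x, c(0, 0.5, 1))
  expect_equal(range(std@y), c(0, 1))
  again <- standardizeEnvelope(std)
  expect_equal(again@x, std@x)
  expect_equal(again@y, std@y)
  expect_equal(attr(std, "mapping")$x, c(0, 10))
  expect_error(standardizeEnvelope(envelopePoints(c(1, 2, 3), c(1, 1, 1 + 1e-16))),
               "zero range|points")
})

test_that("triangle vertices follow the envelope geometry", {
  pts <- unitPts()
  lr <- triangleVertices(pts, "lower_right")
  expect_equal(unname(lr), rbind(c(0, 0), c(1, 1), c(1, 0)),
               ignore_attr = TRUE)
  expect_equal(unname(attr(lr, "hypotenuse")), rbind(c(0, 0), c(1, 1)))
  ll <- triangleVertices(pts, "lower_left")
  expect_equal(unname(attr(ll, "hypotenuse")), rbind(c(0, 1), c(1, 0)))
  # vertices always on the bounding rectangle
  set.seed(701)
  for (i in 1:5) {
    p <- envelopePoints(runif(10, -3, 7), runif(10, 2, 90))
    for (orient in c("lower_right", "lower_left")) {
      v <- triangleVertices(p, orient)
      expect_true(all(v[, 1] %in% range(p@x)) && all(v[, 2] %in% range(p@y)))
    }
  }
})

test_that("boundary distance is 0 inside/on and exact outside", {
  tri <- triangleVertices(unitPts(), "lower_right")
  expect_equal(boundaryDistance(c(0.5, 0.25), tri), 0)
  expect_equal(boundaryDistance(c(0.5, 0.5), tri), 0)   # on the hypotenuse
  expect_equal(boundaryDistance(c(0, 1), tri), sqrt(2) / 2, tolerance = 1e-12)
  # dense sampling of the segment confirms the perpendicular distance
  ts <- seq(0, 1, length.out = 20001)
  expect_equal(min(sqrt((0 - ts)^2 + (1 - ts)^2)),
               boundaryDistance(c(0, 1), tri), tolerance = 1e-7)
  ll <- triangleVertices(unitPts(), "lower_left")
  expect_equal(boundaryDistance(c(1, 1), ll), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(boundaryDistance(c(0.1, 0.1), ll), 0)
})

test_that("the BSS statistic averages power-transformed outside distances", {
  x <- c(0, 0.5, 1, 0)
  y <- c(0, 0.25, 1, 1)   # only (0,1) lies outside the lower-right triangle
  pts <- envelopePoints(x, y)
  s1 <- bssStatistic(pts, "lower_right", distancePower = 1)
  expect_equal(s1$nOutside, 1)
  expect_equal(s1$stat, sqrt(2) / 2)
  s2 <- bssStatistic(pts, "lower_right", distancePower = 2)
  expect_equal(s2$stat, 0.5)
  inside <- envelopePoints(c(0, 0.5, 1), c(0, 0.2, 1))
  expect_equal(bssStatistic(inside, "lower_right"),
               list(stat = 0, nOutside = 0L))
})

test_that("bssTest is deterministic under a seed and p sits on the add-one grid", {
  pts <- simulateEnvelope(30, constrained = FALSE, seed = 702)
  r1 <- bssTest(pts, nRandomizations = 199, seed = 7)
  r2 <- bssTest(pts, nRandomizations = 199, seed = 7)
  expect_identical(pValue(r1), pValue(r2))
  expect_identical(nullStats(r1), nullStats(r2))
  expect_gt(pValue(r1), 0)
  expect_equal(pValue(r1) * 200, round(pValue(r1) * 200))
  r3 <- bssTest(pts, nRandomizations = 199, seed = 8,
                nullModel = "uniform_rectangle")
  expect_s4_class(r3, "BssResult")
  expect_error(bssTest(envelopePoints(c(1, 2, 3, 4, 5), rep(2, 5))),
               "zero range|points")
  expect_warning(bssTest(envelopePoints(c(0, 1, 2), c(0, 2, 1)),
                         nRandomizations = 19, seed = 1), "fewer than 5")
})

test_that("the decision is invariant to positive affine transforms of x and y", {
  pts <- simulateEnvelope(40, constrained = TRUE, noiseSd = 0.1, seed = 703)
  base <- bssTest(pts, nRandomizations = 99, seed = 11)
  for (i in 1:3) {
    a <- runif(1, 0.5, 30); b <- runif(1, -10, 10)
    cc <- runif(1, 0.5, 5); d <- runif(1, -3, 3)
    shifted <- envelopePoints(a * pts@x + b, cc * pts@y + d, pts@labels)
    res <- bssTest(shifted, nRandomizations = 99, seed = 11)
    expect_equal(pValue(res), pValue(base), tolerance = 1e-12)
    expect_equal(observedStat(res), observedStat(base), tolerance = 1e-10)
  }
})

test_that("power rises as the planted envelope sharpens", {
  sds <- c(0.02, 0.1, 0.4)
  meanP <- vapply(sds, function(sd) {
    ps <- vapply(1:25, function(i) {
      pts <- simulateEnvelope(50, noiseSd = sd, constrained = TRUE,
                              seed = 7100 + i)
      pValue(bssTest(pts, nRandomizations = 199, seed = 7200 + i))
    }, 0)
    mean(ps)
  }, 0)
  expect_true(all(diff(meanP) > 0))
})

test_that("null p-values are near-uniform under the permutation null", {
  set.seed(704)
  ps <- vapply(1:300, function(i) {
    pts <- simulateEnvelope(30, constrained = FALSE, seed = 7300 + i)
    pValue(bssTest(pts, nRandomizations = 199, seed = 7400 + i))
  }, 0)
  grid <- seq(0.05, 0.95, by = 0.05)
  ksDist <- max(abs(vapply(grid, function(q) mean(ps <= q), 0) - grid))
  expect_lt(ksDist, 0.1)
})
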