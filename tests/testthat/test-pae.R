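test_that("fitchLength matches hand-derived cases", {
  m <- IncidenceMatrix(matrix(c(0, 0, 0, 0,   # absent everywhere
                                1, 1, 0, 0,   # cherry synapomorphy
                                1, 0, 1, 0),  # scattered: needs 2 changes
                              3, 4, byrow = TRUE,
                              dimnames = list(paste0("s", 1:3),
                                              LETTERS[1:4])))
  tr <- ape::read.tree(text = "((A,B),(C,D),ROOT_ALL_ABSENT);")
  one <- function(row) {
    sub <- IncidenceMatrix(presenceMatrix(m)[row, , drop = FALSE])
    fitchLength(tr, sub)
  }
  expect_identical(one(1), 0L)
  expect_identical(one(2), 1L)
  expect_identical(one(3), 2L)
  expect_identical(fitchLength(tr, m), 3L)
})

test_that("fitchLength equals brute-force minimal-change enumeration", {
  set.seed(501)
  for (i in 1:12) {
    nAreas <- sample(3:7, 1)
    m <- randomIncidence(8, nAreas)
    tr <- randomAreaTree(m)
    expect_identical(fitchLength(tr, m), bruteForceLength(tr, m))
  }
})

test_that("fitchLength is invariant to species order, area order and rooting", {
  set.seed(502)
  m <- randomIncidence(10, 6)
  tr <- randomAreaTree(m)
  ref <- fitchLength(tr, m)
  for (i in 1:5) {
    p <- presenceMatrix(m)
    perm <- IncidenceMatrix(p[sample(nrow(p)), sample(ncol(p)), drop = FALSE])
    expect_identical(fitchLength(tr, perm), ref)
  }
  rooted <- ape::root(tr, outgroup = areaIDs(m)[1], resolve.root = TRUE)
  expect_identical(fitchLength(rooted, m), ref)
})

test_that("fitchLength reports leaf/area mismatches symmetrically", {
  m <- randomIncidence(4, 4)
  tr <- ape::read.tree(text = "((A01,A02),(A03,WRONG),ROOT_ALL_ABSENT);")
  expect_error(fitchLength(tr, m), "WRONG")
  expect_error(fitchLength(tr, m), "A04")
})

test_that("stepwise addition is deterministic under a seed and near-optimal on nested data", {
  truth <- syntheticTruth(simulateAreaCladogram(8, seed = 503), seed = 504)
  m <- simulateIncidence(truth, 40)
  t1 <- stepwiseAddition(m, seed = 99)
  t2 <- stepwiseAddition(m, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # noise-free perfectly nested data: greedy insertion attains the analytic
  # minimum of one gain per species
  expect_identical(fitchLength(t1, m), nrow(presenceMatrix(m)))
  expect_error(stepwiseAddition(randomIncidence(3, 2)), "2 areas|at least")
})

test_that("TBR search only improves and respects the keep cap", {
  set.seed(505)
  m <- randomIncidence(20, 6)
  start <- stepwiseAddition(m, seed = 1)
  res <- tbrSearch(start, m, keep = 1, seed = 2)
  expect_length(searchTrees(res), 1)
  expect_lte(bestScore(res), fitchLength(start, m))
  resWide <- tbrSearch(start, m, keep = 50, seed = 2)
  expect_identical(bestScore(resWide), bestScore(res))
  for (tr in searchTrees(resWide))
    expect_identical(fitchLength(tr, m), bestScore(resWide))
})

test_that("TBR from an optimal start equals the exhaustive minimum", {
  set.seed(506)
  m <- randomIncidence(15, 5)
  ex <- exhaustiveSearch(m)
  res <- tbrSearch(searchTrees(ex)[[1]], m, keep = 10, seed = 3)
  expect_identical(bestScore(res), bestScore(ex))
})

test_that("exhaustive search enumerates (2n-5)!! topologies and bounds length", {
  m3 <- randomIncidence(5, 3)
  ex3 <- exhaustiveSearch(m3)
  expect_identical(attr(ex3, "nExamined"), 3)     # 4 leaves
  m5 <- randomIncidence(5, 5)
  ex5 <- exhaustiveSearch(m5)
  expect_identical(attr(ex5, "nExamined"), 105)   # 6 leaves
  nonEmpty <- sum(rowSums(presenceMatrix(m5)) > 0)
  expect_gte(bestScore(ex5), nonEmpty)
  big <- randomIncidence(4, 10)
  expect_error(exhaustiveSearch(big), "2,027,025")
})

test_that("heuristic search is seed-reproducible and pools across replicates", {
  set.seed(507)
  m <- randomIncidence(25, 6)
  a <- heuristicSearch(m, replicates = 2, keep = 10, seed = 42)
  b <- heuristicSearch(m, replicates = 2, keep = 10, seed = 42)
  expect_identical(a@keys, b@keys)
  expect_identical(bestScore(a), bestScore(b))
  expect_identical(vapply(searchTrees(a), ape::write.tree, ""),
                   vapply(searchTrees(b), ape::write.tree, ""))
  # pooled best is no worse than any single replicate
  singles <- vapply(1:4, function(s)
    bestScore(heuristicSearch(m, replicates = 1, keep = 5, seed = s)), 0L)
  pooled <- heuristicSearch(m, replicates = 4, keep = 5, seed = 507)
  expect_lte(bestScore(pooled), min(singles))
})

test_that("heuristic search agrees with phangorn's parsimony score", {
  skip_if_not_installed("phangorn")
  set.seed(508)
  m <- randomIncidence(20, 7)
  res <- heuristicSearch(m, replicates = 3, keep = 5, seed = 9)
  dat <- rbind(t(presenceMatrix(m)),
               matrix(0L, 1, nrow(presenceMatrix(m)),
                      dimnames = list(paeOutgroupLabel(), NULL)))
  pd <- phangorn::phyDat(dat, type = "USER", levels = c(0, 1))
  for (tr in searchTrees(res)[seq_len(min(3, length(searchTrees(res))))])
    expect_identical(as.integer(phangorn::parsimony(tr, pd)),
                     fitchLength(tr, m))
  # phangorn's own optimizer should not beat the exhaustive minimum either
  ex <- exhaustiveSearch(m)
  expect_identical(bestScore(res), bestScore(ex))
})

test_that("adding a clade-consistent species raises length by 1 without changing optima", {
  truth <- syntheticTruth(simulateAreaCladogram(6, seed = 509), seed = 510)
  m <- simulateIncidence(truth, 20)
  ex <- exhaustiveSearch(m)
  clade <- trueClades(truth)[[which.max(lengths(trueClades(truth)))]]
  p <- presenceMatrix(m)
  extra <- matrix(0L, 1, ncol(p), dimnames = list("extra", colnames(p)))
  extra[1, clade] <- 1L
  ex2 <- exhaustiveSearch(IncidenceMatrix(rbind(p, extra)))
  expect_identical(bestScore(ex2), bestScore(ex) + 1L)
  expect_setequal(ex2@keys, ex@keys)
  # a single-area endemic is topology-neutral: +1 on every tree
  endem <- matrix(0L, 1, ncol(p), dimnames = list("endem", colnames(p)))
  endem[1, 1] <- 1L
  m3 <- IncidenceMatrix(rbind(p, endem))
  ex3 <- exhaustiveSearch(m3)
  expect_identical(bestScore(ex3), bestScore(ex) + 1L)
  expect_setequal(ex3@keys, ex@keys)
  for (tr in searchTrees(ex)[seq_len(min(3, length(searchTrees(ex))))])
    expect_identical(fitchLength(tr, m3), fitchLength(tr, m) + 1L)
})
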