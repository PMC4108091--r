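test_that("readIncidence parses delimited text preserving order", {
  tf <- writeTempIncidence(c("species,AreaX,AreaY", "sp1,1,0", "sp2,0,1"))
  m <- readIncidence(tf)
  expect_identical(speciesIDs(m), c("sp1", "sp2"))
  expect_identical(areaIDs(m), c("AreaX", "AreaY"))
  expect_identical(unname(presenceMatrix(m)),
                   matrix(c(1L, 0L, 0L, 1L), 2, 2))
  # tab-delimited variant auto-detected
  tft <- writeTempIncidence(c("species\tA\tB", "sp1\t1\t0", "sp2\t0\t1"))
  expect_identical(unname(presenceMatrix(readIncidence(tft))),
                   unname(presenceMatrix(m)))
})

test_that("readIncidence rejects duplicates and non-binary cells", {
  dup <- writeTempIncidence(c("species,A,B",
                              "Notodiaptomus_iheringi,1,0",
                              "Notodiaptomus_iheringi,0,1"))
  expect_error(readIncidence(dup), "Notodiaptomus_iheringi")
  bad <- writeTempIncidence(c("species,A,B", "sp1,1,0", "sp2,0,2"))
  expect_error(readIncidence(bad), "row 2.*column 2")
  dupArea <- writeTempIncidence(c("species,A,A", "sp1,1,0", "sp2,0,1"))
  expect_error(readIncidence(dupArea), "duplicate area label: A")
})

test_that("richness equals a naive recount on random matrices", {
  m <- IncidenceMatrix(matrix(c(1L, 0L, 0L, 1L), 2, 2,
                              dimnames = list(c("s1", "s2"), c("A", "B"))))
  expect_identical(richness(m), c(A = 1, B = 1))
  zero <- IncidenceMatrix(matrix(c(1L, 1L, 0L, 0L), 2, 2,
                                 dimnames = list(c("s1", "s2"), c("A", "B"))))
  expect_identical(unname(richness(zero)["B"]), 0)
  set.seed(401)
  for (i in 1:10) {
    m <- randomIncidence(sample(3:12, 1), sample(3:9, 1))
    expect_equal(richness(m), naiveRichness(m), ignore_attr = FALSE)
    expect_equal(names(richness(m)), areaIDs(m))
    expect_equal(sum(richness(m)), sum(presenceMatrix(m)))
  }
})

test_that("round trip through CSV is lossless", {
  set.seed(402)
  m <- randomIncidence(8, 5)
  tf <- tempfile(fileext = ".csv")
  writeIncidence(m, tf)
  expect_identical(presenceMatrix(readIncidence(tf)), presenceMatrix(m))
})

test_that("dropUninformative removes only sub-2-area species, keeps areas", {
  p <- matrix(c(1, 0, 0,   # single-area endemic -> removed
                1, 1, 0,   # 2 areas -> retained
                0, 0, 0,   # absent everywhere -> removed
                1, 1, 1),  # widespread -> retained
              4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  m <- IncidenceMatrix(p)
  res <- dropUninformative(m)
  expect_setequal(res$removed, c("s1", "s3"))
  expect_identical(areaIDs(res$matrix), c("A", "B", "C"))
  expect_identical(presenceMatrix(res$matrix),
                   presenceMatrix(m)[c("s2", "s4"), ])
  # identity case: all informative
  all2 <- IncidenceMatrix(p[c(2, 4), ])
  res2 <- dropUninformative(all2)
  expect_length(res2$removed, 0)
  expect_identical(presenceMatrix(res2$matrix), presenceMatrix(all2))
})

test_that("NEXUS writer transposes areas as taxa and round-trips", {
  m <- IncidenceMatrix(matrix(c(1L, 0L, 0L, 1L), 2, 2,
                              dimnames = list(c("s1", "s2"), c("A", "B"))))
  nx <- writeNexus(m, includeOutgroup = TRUE)
  expect_true(any(grepl("NTAX=3 NCHAR=2", nx)))
  expect_true(any(grepl("ROOT_ALL_ABSENT\\s+00", nx)))
  nx2 <- writeNexus(m, includeOutgroup = FALSE)
  expect_true(any(grepl("NTAX=2", nx2)))
  # collision with the reserved outgroup name
  bad <- IncidenceMatrix(matrix(c(1L, 1L), 1, 2,
    dimnames = list("s1", c("ROOT_ALL_ABSENT", "B"))))
  expect_error(writeNexus(bad), "reserved outgroup")
  # round trip through an independent NEXUS reader, random matrices
  set.seed(403)
  for (i in 1:5) {
    m <- randomIncidence(sample(2:10, 1), sample(2:6, 1))
    tf <- tempfile(fileext = ".nex")
    writeNexus(m, tf, includeOutgroup = (i %% 2 == 0))
    parsed <- ape::read.nexus.data(tf)
    back <- t(vapply(parsed, as.integer, integer(nrow(presenceMatrix(m)))))
    areas <- setdiff(rownames(back), paeOutgroupLabel())
    expect_identical(unname(back[areas, , drop = FALSE]),
                     unname(t(presenceMatrix(m))))
    if (i %% 2 == 0)
      expect_true(all(back[paeOutgroupLabel(), ] == 0L))
  }
})

test_that("labels with spaces are quoted in NEXUS output", {
  m <- IncidenceMatrix(matrix(c(1L, 1L), 1, 2,
    dimnames = list("s1", c("Amazonas Lowlands", "Chaco"))))
  nx <- writeNexus(m)
  expect_true(any(grepl("'Amazonas Lowlands'", nx, fixed = TRUE)))
})

test_that("covariate validation enforces physical invariants", {
  cv <- simulateSpeciesArea(nAreas = 6, seed = 404)$covariates
  expect_silent(validateCovariates(cv))
  bad <- cv; bad$area[2] <- -5
  expect_error(validateCovariates(bad), "positive")
  bad2 <- cv; bad2$min_temp_coldest_month[1] <-
    bad2$max_temp_warmest_month[1] + 10
  expect_error(validateCovariates(bad2), bad2$area_id[1])
  bad3 <- cv; bad3$area_id[2] <- bad3$area_id[1]
  expect_error(validateCovariates(bad3), "duplicate")
})
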