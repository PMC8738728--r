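map <- fha_domain_map()

test_that("residues map to their domain or the linker", {
  expect_equal(assignDomain(51L, map), "FHA")
  expect_equal(assignDomain(101L, map), "FHA")
  expect_equal(assignDomain(320L, map), "phosphatase")
  expect_equal(assignDomain(130L, map), "linker")
  expect_equal(assignDomain(c(51L, 130L, 400L), map),
               c("FHA", "linker", "kinase"))
  expect_error(assignDomain(0L, map), "1\\.\\.")
  expect_error(assignDomain(522L, map), "1\\.\\.")
  expect_error(domainMap(100L, data.frame(name = c("a", "b"),
                                          first = c(1L, 40L),
                                          last = c(50L, 90L))),
               "overlap")
})

test_that("domain summary reports counts, fractions and means", {
  tab <- data.frame(
    position = c(rep(50L, 7), rep(200L, 4), rep(400L, 8)),
    score = c(rep(22.2, 7), rep(23.5, 4), rep(21.5, 8)))
  s <- domainSummary(tab, map)
  expect_equal(s$count[s$region == "FHA"], 7L)
  expect_equal(s$fraction[s$region == "FHA"], 7 / 19, tolerance = 1e-12)
  expect_equal(s$fraction[s$region == "phosphatase"], 4 / 19,
               tolerance = 1e-12)
  expect_equal(s$fraction[s$region == "kinase"], 8 / 19, tolerance = 1e-12)
  expect_equal(s$meanScore[s$region == "FHA"], 22.2)
  expect_equal(sum(s$fraction), 1)
  # single-region table
  one <- domainSummary(data.frame(position = c(50, 60), score = c(1, 2)),
                       map)
  expect_equal(one$fraction[one$region == "FHA"], 1)
  expect_error(domainSummary(data.frame(position = numeric(0),
                                        score = numeric(0)), map), "empty")
  # fractions over all regions plus linker always sum to 1
  set.seed(23)
  for (i in 1:10) {
    t2 <- data.frame(position = sample(521L, 25, replace = TRUE),
                     score = rnorm(25, 20))
    expect_equal(sum(domainSummary(t2, map)$fraction), 1, tolerance = 1e-12)
  }
})

test_that("score ANOVA across regions behaves at the extremes", {
  # identical values within groups, different means: F huge, p ~ 0
  tab <- data.frame(position = c(50, 51, 55, 200, 201, 205),
                    score = c(25, 25, 25, 10, 10, 10))
  a <- anovaRegions(tab, map)
  expect_lt(a$p, 1e-12)
  # all scores equal: F = 0, p = 1
  tab2 <- data.frame(position = c(50, 51, 200, 201), score = rep(7, 4))
  a2 <- anovaRegions(tab2, map)
  expect_equal(a2$F, 0)
  expect_equal(a2$p, 1)
  expect_error(anovaRegions(data.frame(position = c(50, 51),
                                       score = c(1, 2)), map), "2 regions")
})

test_that("null ANOVA p-values are uniform, separated means are detected", {
  pvals <- vapply(1:300, function(s) {
    tab <- simulateMissenseTable(c(FHA = 8L, kinase = 8L),
                                 c(FHA = 22, kinase = 22), 3, map, seed = s)
    anovaRegions(tab, map)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # means 5 sd apart: decisive rejection in >99% of runs
  hits <- vapply(1:60, function(s) {
    tab <- simulateMissenseTable(c(FHA = 8L, kinase = 8L),
                                 c(FHA = 22, kinase = 7), 3, map,
                                 seed = s + 1000)
    anovaRegions(tab, map)$p < 0.001
  }, logical(1))
  expect_gt(mean(hits), 0.99)
})

test_that("clustering bootstrap handles degenerate geometries exactly", {
  coords <- simulateStructure(100L, seed = 3L)
  # identical coordinates: minimal statistic, p = 1/(B+1)
  co <- coords
  co[1:5, ] <- matrix(rep(co[1, ], each = 5), nrow = 5)
  res <- clusteringTest(1:5, co, nBoot = 999L, seed = 9L)
  expect_equal(res@observedStat, 0)
  expect_equal(res@pValue, 1 / 1000)
  # positions = all residues: null is the observed statistic, p = 1
  resAll <- clusteringTest(1:100, coords, nBoot = 99L, seed = 1L)
  expect_equal(resAll@pValue, 1)
  expect_error(clusteringTest(c(1, 999), coords, seed = 1L), "999")
  expect_error(clusteringTest(1:5, coords, nBoot = 10L), ">= 99")
  expect_error(clusteringTest(5, coords), ">= 2")
})

test_that("clustering test is deterministic and rigid-motion invariant", {
  coords <- simulateStructure(80L, seed = 11L)
  r1 <- clusteringTest(c(3, 9, 20, 44), coords, nBoot = 199L, seed = 7L)
  r2 <- clusteringTest(c(3, 9, 20, 44), coords, nBoot = 199L, seed = 7L)
  expect_identical(r1@nullStats, r2@nullStats)
  expect_identical(r1@pValue, r2@pValue)
  # rotate + translate: distances unchanged, so stat and p unchanged
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(coords %*% R, 2, c(5, -3, 12), "+")
  rownames(moved) <- rownames(coords)
  r3 <- clusteringTest(c(3, 9, 20, 44), moved, nBoot = 199L, seed = 7L)
  expect_equal(r3@observedStat, r1@observedStat, tolerance = 1e-9)
  expect_equal(r3@pValue, r1@pValue)
})

test_that("a tightly planted cluster is called significant", {
  coords <- simulateStructure(100L,
    plantedCluster = list(center = c(0, 0, 0), radius = 1,
                          members = c(10, 20, 30, 40, 50)),
    seed = 21L)
  res <- clusteringTest(c(10, 20, 30, 40, 50), coords, nBoot = 999L,
                        seed = 4L)
  expect_lte(res@pValue, 1 / (999 + 1) * 5)  # essentially minimal
  expect_lt(res@observedStat, 2)
})

test_that("C-alpha PDB reading honors chain, altloc and insertion rules", {
  pdb <- tempfile(fileext = ".pdb")
  write_mini_pdb(pdb, list(
    list(serial = 1, name = "CA", resno = 1, x = 0, y = 0, z = 0),
    list(serial = 2, name = "CA", resno = 2, x = 3.8, y = 0, z = 0),
    list(serial = 3, name = "CA", resno = 3, x = 7.6, y = 0, z = 0)))
  co <- readPdbCa(pdb)
  expect_equal(nrow(co), 3L)
  expect_equal(rownames(co), c("1", "2", "3"))
  expect_equal(unname(co[2, "x"]), 3.8)
  expect_error(readPdbCa(pdb, chain = "Z"), "chain 'Z'")
  # altloc: A preferred over B
  write_mini_pdb(pdb, list(
    list(serial = 1, name = "CA", resno = 1, alt = "B", x = 9, y = 9, z = 9),
    list(serial = 2, name = "CA", resno = 1, alt = "A", x = 1, y = 1, z = 1),
    list(serial = 3, name = "CA", resno = 2, x = 5, y = 5, z = 5)))
  co2 <- readPdbCa(pdb)
  expect_equal(unname(co2["1", "x"]), 1)
  # insertion codes skipped with a warning
  write_mini_pdb(pdb, list(
    list(serial = 1, name = "CA", resno = 1, x = 0, y = 0, z = 0),
    list(serial = 2, name = "CA", resno = 1, icode = "A", x = 2, y = 2, z = 2),
    list(serial = 3, name = "CA", resno = 2, x = 4, y = 4, z = 4)))
  expect_warning(co3 <- readPdbCa(pdb), "insertion")
  expect_equal(nrow(co3), 2L)
  # no C-alpha atoms at all: empty map with a warning
  write_mini_pdb(pdb, list(
    list(serial = 1, name = "N", resno = 1, x = 0, y = 0, z = 0)))
  expect_warning(co4 <- readPdbCa(pdb), "no C-alpha")
  expect_equal(nrow(co4), 0L)
  unlink(pdb)
})

test_that("synthetic coordinates round trip through PDB", {
  coords <- simulateStructure(40L, seed = 2L)
  pdb <- tempfile(fileext = ".pdb")
  writeCaPdb(coords, pdb)
  back <- readPdbCa(pdb)
  expect_equal(nrow(back), 40L)
  expect_equal(unname(back), unname(round(coords, 3)), tolerance = 1e-9)
  unlink(pdb)
})
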