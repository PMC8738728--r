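test_that("PSI matches the worked inclusion ratio and its edge cases", {
  expect_equal(as.numeric(computePsi(30, 33, 24)), 31.5 / 55.5,
               tolerance = 1e-12)
  expect_equal(round(as.numeric(computePsi(30, 33, 24)), 3), 0.568)
  expect_equal(as.numeric(computePsi(17, 17, 0)), 1)
  expect_equal(as.numeric(computePsi(0, 0, 12)), 0)
  expect_error(computePsi(0, 0, 0), "zero")
  # one-sided evidence falls back to the single junction with a flag
  p <- computePsi(NA, 30, 30)
  expect_equal(as.numeric(p), 0.5)
  expect_true(attr(p, "oneSided"))
  expect_error(computePsi(NA, NA, 10), "inclusion")
})

test_that("PSI is invariant under rescaling all counts", {
  set.seed(7)
  for (i in 1:25) {
    u <- sample(1:200, 1); d <- sample(1:200, 1); s <- sample(0:200, 1)
    k <- sample(2:9, 1)
    expect_equal(as.numeric(computePsi(u * k, d * k, s * k)),
                 as.numeric(computePsi(u, d, s)), tolerance = 1e-12)
  }
})

test_that("equal-allele partition assigns the retention remainder", {
  m <- partitionEqualExpression(30, 33, 24)
  expect_equal(m@inclusionTranscripts, 31.5)
  expect_equal(m@retentionTranscripts, 7.5)
  expect_equal(m@retentionFraction, 7.5 / 63, tolerance = 1e-12)
  expect_equal(m@skipFraction, 24 / 63, tolerance = 1e-12)
  expect_length(m@notes, 0)
  # alleles already balanced -> no retention species needed
  expect_equal(partitionEqualExpression(20, 20, 20)@retentionTranscripts, 0)
  # skip > inclusion is inconsistent with equal expression: clamp + note
  m2 <- partitionEqualExpression(10, 10, 25)
  expect_equal(m2@retentionTranscripts, 0)
  expect_match(m2@notes, "clamped", all = FALSE)
  # fractions always sum to 1
  set.seed(11)
  for (i in 1:25) {
    mm <- partitionEqualExpression(sample(1:100, 1), sample(1:100, 1),
                                   sample(0:100, 1))
    tot <- mm@inclusionTranscripts + mm@skipTranscripts +
      mm@retentionTranscripts
    expect_equal(mm@inclusionTranscripts / tot + mm@skipFraction +
                   mm@retentionFraction, 1, tolerance = 1e-12)
  }
})

test_that("coverage ratio reproduces the intron/exon profile estimate", {
  expect_equal(coverageRetentionRatio(11, 69), 11 / 69, tolerance = 1e-12)
  expect_equal(round(coverageRetentionRatio(11, 69), 3), 0.159)
  expect_equal(coverageRetentionRatio(0, 50), 0)
  expect_equal(coverageRetentionRatio(50, 50), 1)
  expect_error(coverageRetentionRatio(5, 0), "> 0")
})

test_that("intron FPKM follows the standard normalization", {
  expect_equal(intronFpkm(100, 1000, 1e7), 10)
  expect_equal(intronFpkm(0, 500, 1e6), 0)
  expect_error(intronFpkm(10, 0, 1e6), "intronLength")
  expect_error(intronFpkm(10, 100, 0), "librarySize")
  set.seed(3)
  for (i in 1:20) {
    cnt <- sample(0:5000, 1); len <- sample(50:5000, 1)
    lib <- round(runif(1, 1e5, 1e8))
    expect_equal(intronFpkm(cnt, len, lib), cnt * 1e9 / (len * lib),
                 tolerance = 1e-12)
  }
})

test_that("box-plot rule flags the single retention carrier", {
  expect_equal(retentionOutlier(c(A = 1, B = 1.2, C = 1.1, D = 9)), "D")
  expect_equal(retentionOutlier(c(A = 2, B = 2, C = 2, D = 2)), character(0))
  expect_error(retentionOutlier(c(A = 1, B = 2)), "3 samples")
  # Monte-Carlo: carrier at 10x background flagged nearly always
  set.seed(19)
  hits <- vapply(1:100, function(i) {
    cnt <- c(rpois(7, 30), rpois(1, 300))
    names(cnt) <- c(paste0("ctrl", 1:7), "carrier")
    fpkm <- intronFpkm(cnt, 800, 2e7)
    "carrier" %in% retentionOutlier(fpkm)
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("allele read partition reports fraction and equality verdict", {
  p <- alleleReadPartition(10, 4, 6)
  expect_equal(p@retainedFractionOfAlt, 0.6)
  expect_equal(p@verdict, "about equally expressed")
  expect_gte(p@pBinomial, 0.05)
  expect_equal(alleleReadPartition(10, 10, 0)@retainedFractionOfAlt, 0)
  expect_equal(alleleReadPartition(35, 17, 18)@retainedFractionOfAlt,
               18 / 35, tolerance = 1e-12)
  expect_equal(alleleReadPartition(40, 5, 30)@verdict, "unbalanced")
  expect_error(alleleReadPartition(10, 0, 0), "no reads")
  expect_error(alleleReadPartition(5, 4, 6), "exceed")
})

test_that("SJ.out.tab and bedGraph files round trip through the readers", {
  model <- pnkp_like_model()
  sim <- simulateJunctionEvidence(model, pnkp_like_config())
  sj <- tempfile(fileext = ".tab"); bg <- tempfile(fileext = ".bedGraph")
  writeJunctionsSJ(sim$junctions, sj)
  writeBedGraphCoverage(sim$coverage, bg)
  back <- readJunctionsSJ(sj)
  expect_equal(back$uniqueReads, sim$junctions$uniqueReads)
  expect_equal(back$intronStart, sim$junctions$intronStart)
  cov <- readBedGraphCoverage(bg)
  expect_equal(sum(GenomicRanges::width(cov) * cov$score),
               sum(GenomicRanges::width(sim$coverage) * sim$coverage$score))
  # evidence reassembled from files matches the simulated evidence
  ev <- junctionEvidenceFromFiles(sj, bg, model, cassetteExon = 11L)
  expect_equal(ev@inclusionUp, sim$evidence@inclusionUp)
  expect_equal(ev@inclusionDown, sim$evidence@inclusionDown)
  expect_equal(ev@skip, sim$evidence@skip)
  expect_equal(ev@exonCov, sim$evidence@exonCov, tolerance = 1e-9)
  expect_equal(ev@intronCov, sim$evidence@intronCov, tolerance = 1e-9)
  unlink(c(sj, bg))
})

test_that("malformed junction files are rejected with context", {
  bad <- tempfile()
  writeLines("chr1\t10\t20", bad)
  expect_error(readJunctionsSJ(bad), "9")
  unlink(bad)
})

test_that("noiseless coverage equals the known retention fraction", {
  # coverage generated directly from a mixture without sampling noise
  frac <- 0.12
  expect_equal(coverageRetentionRatio(100 * frac, 100), frac,
               tolerance = 1e-12)
})
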