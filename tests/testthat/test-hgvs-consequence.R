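model <- pnkp_like_model()

test_that("exon-skip r-codes span the exon's c.-range, terminal exons error", {
  expect_equal(skipToRCode(model, 4L), "r.199_498del")
  expect_equal(skipToRCode(model, 11L), "r.937_1029del")
  expect_error(skipToRCode(model, 1L), "terminal")
  expect_error(skipToRCode(model, 12L), "terminal")
})

test_that("intron-retention r-codes use the flanking c.-positions", {
  expect_equal(retentionToRCode(model, 10L), "r.936_937ins936+1_937-1")
  expect_equal(retentionToRCode(model, 2L), "r.151_152ins151+1_152-1")
  expect_error(retentionToRCode(model, 0L), "out of range")
})

test_that("in-frame codon-aligned skips delete whole residue blocks", {
  c4 <- consequenceOfSkip(model, 4L)
  expect_equal(c4@pCode, "p.Leu67_Lys166del")
  expect_equal(c4@deletedAaCount, 100L)
  expect_equal(c(c4@firstResidue, c4@lastResidue), c(67L, 166L))
  expect_true(c4@inFrame)
  expect_equal(c4@kind, "inframe_del")
  c11 <- consequenceOfSkip(model, 11L)
  expect_equal(c11@pCode, "p.Phe313_Pro343del")
  expect_equal(c11@deletedAaCount, 31L)
  # residue count identity for codon-aligned in-frame skips
  expect_equal(c11@lastResidue - c11@firstResidue + 1L, c11@deletedAaCount)
})

test_that("non-codon-multiple skips shift the frame, rank from translation", {
  # 100-bp exon 1 of a toy: skip internal exon with span not divisible by 3
  cfg <- simulationConfig(nExons = 4L,
                          exonLengths = c(60L, 100L, 50L, 90L),
                          intronLengths = rep(40L, 3L), skipExon = 2L,
                          retentionIntron = 1L, seed = 5L)
  toy <- makeToyTranscript(cfg)
  cons <- consequenceOfSkip(toy, 2L)
  expect_equal(cons@kind, "frameshift")
  expect_false(cons@inFrame)
  oracle <- bf_skip(toy, 2L)
  expect_equal(cons@fsStopRank, oracle$rank)
  expect_match(cons@pCode, "fs\\*\\d+$|\\d+\\*$")
})

test_that("in-frame non-aligned skips produce a delins junction residue", {
  # exon 2 spans c.61..160 after a 60-bp exon 1? construct aligned case:
  # exon boundaries chosen so span %% 3 == 0 but start is mid-codon
  cfg <- simulationConfig(nExons = 4L,
                          exonLengths = c(61L, 99L, 50L, 90L),
                          intronLengths = rep(40L, 3L), skipExon = 2L,
                          retentionIntron = 1L, seed = 6L)
  toy <- makeToyTranscript(cfg)
  cons <- consequenceOfSkip(toy, 2L)
  expect_equal(cons@kind, "inframe_delins")
  expect_true(cons@inFrame)
  expect_match(cons@pCode, "delins")
  expect_equal(bf_skip(toy, 2L)$kind, "inframe_delins")
})

test_that("codon-aligned retention with an engineered stop gives ins*N", {
  cons <- consequenceOfRetention(model, 10L)
  expect_equal(cons@pCode, "p.Leu312_Phe313ins*18")
  expect_equal(cons@kind, "stop_insertion")
  expect_equal(cons@fsStopRank, 18L)
  expect_equal(c(cons@firstResidue, cons@lastResidue), c(312L, 313L))
  expect_equal(bf_retention(model, 10L)$rank, 18L)
})

test_that("mid-codon retention with the donor base exchange frameshifts", {
  cons <- consequenceOfRetention(model, 2L, snv = list(c_pos = 151, alt = "C"))
  # C at c.151 + the intron's GT donor rebuild codon 51 as CGT = Arg
  expect_match(cons@pCode, "^p\\.Val51Argfs\\*\\d+$")
  expect_equal(cons@kind, "frameshift")
  oracle <- bf_retention(model, 2L, snv = list(c_pos = 151, alt = "C"))
  expect_equal(cons@fsStopRank, oracle$rank)
})

test_that("a stop-free in-frame 3-bp intron is a single-residue insertion", {
  m <- TranscriptModel("mini", c(9L, 9L),
                       exonSeqs = c("ATGAAACCC", "GGGTTTTAA"),
                       intronSeqs = "CAT")
  cons <- consequenceOfRetention(m, 1L)
  expect_equal(cons@kind, "inframe_delins")
  expect_equal(cons@pCode, "p.Pro3_Gly4insHis")
})

test_that("SNV consequences cover missense, synonymous and stop-gain", {
  p101 <- consequenceOfSnv(model, 302L, "T")
  expect_equal(p101@pCode, "p.(Pro101Leu)")
  expect_equal(p101@kind, "missense")
  expect_equal(p101@rCode, "r.302c>u")
  # c.498 G>A: third base of the Lys166 AAG codon, synonymous
  syn <- consequenceOfSnv(model, 498L, "A")
  expect_equal(syn@pCode, "p.(=)")
  expect_equal(syn@kind, "synonymous")
  # reference base is a synonymous identity
  ref151 <- substr(cdsSequence(model), 151, 151)
  expect_equal(consequenceOfSnv(model, 151L, ref151)@kind, "synonymous")
  # engineering a stop: Gln50 codon CAA -> TAA by c.148 C>T
  stopg <- consequenceOfSnv(model, 148L, "T")
  expect_equal(stopg@kind, "stop_gain")
  expect_equal(stopg@pCode, "p.(Gln50*)")
  # RNA-confirmed SNVs are bare
  expect_equal(consequenceOfSnv(model, 302L, "T", confirmed = TRUE)@pCode,
               "p.Pro101Leu")
  expect_error(consequenceOfSnv(model, 99999L, "A"), "outside")
})

test_that("allele consequences combine into bracketed HGVS strings", {
  del <- consequenceOfSkip(model, 11L)
  ins <- consequenceOfRetention(model, 10L)
  comb <- combineAlleleConsequences(list(del, ins))
  expect_equal(comb$p, "p.[Phe313_Pro343del,Leu312_Phe313ins*18]")
  expect_equal(comb$r, "r.[937_1029del,936_937ins936+1_937-1]")
  mis <- consequenceOfSnv(model, 151L, "C", confirmed = TRUE)
  fs <- consequenceOfRetention(model, 2L, snv = list(c_pos = 151, alt = "C"))
  comb2 <- combineAlleleConsequences(list(mis, fs))
  expect_match(comb2$p, "^p\\.\\[Val51Leu,Val51Argfs\\*\\d+\\]$")
  expect_match(comb2$r, "^r\\.\\[151g>c,151_152ins151\\+1_152-1\\]$")
  single <- combineAlleleConsequences(list(consequenceOfSkip(model, 4L)))
  expect_equal(single$p, "p.Leu67_Lys166del")
  expect_error(combineAlleleConsequences(list()), "at least one")
})

test_that("rule-based consequences agree with the brute-force oracle", {
  for (seed in 1:200) {
    cfg <- random_toy_config(seed)
    toy <- makeToyTranscript(cfg)
    nEx <- exonCount(toy)
    set.seed(seed + 5000)
    k <- sample(2:(nEx - 1L), 1L)
    j <- sample(seq_len(nEx - 1L), 1L)
    skip <- consequenceOfSkip(toy, k)
    bs <- bf_skip(toy, k)
    expect_equal(skip@kind, bs$kind, info = paste("skip seed", seed))
    expect_equal(skip@fsStopRank, bs$rank, info = paste("skip seed", seed))
    if (bs$kind == "inframe_del")
      expect_equal(skip@deletedAaCount, bs$deleted)
    ret <- consequenceOfRetention(toy, j)
    br <- bf_retention(toy, j)
    expect_equal(ret@kind, br$kind, info = paste("retention seed", seed))
    expect_equal(ret@fsStopRank, br$rank, info = paste("retention seed", seed))
  }
})
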