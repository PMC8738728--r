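test_that("quantify run reports PSI, partition and coverage ratio", {
  outdir <- tempfile()
  cfg <- list(counts = list(inclusion_up = 30, inclusion_down = 33,
                            skip = 24, exon_cov = 69, intron_cov = 11),
              output_dir = outdir, seed = 1L)
  rep <- runQuantify(cfg)
  expect_equal(round(rep$psi, 3), 0.568)
  expect_equal(rep$retention_transcripts, 7.5)
  expect_equal(round(rep$retention_fraction, 3), 0.119)
  expect_equal(round(rep$coverage_retention_ratio, 3), 0.159)
  json <- jsonlite::read_json(file.path(outdir, "quantify.json"))
  expect_equal(round(as.numeric(json$psi), 3), 0.568)
  expect_equal(json$tool, "splicecraft")
  unlink(outdir, recursive = TRUE)
})

test_that("simulated files pipe end to end through the quantify run", {
  outdir <- tempfile()
  simCfg <- list(seed = 42L, output_dir = outdir,
                 simulation = list(depth = 4000, coverageDepth = 250))
  paths <- runSimulate(simCfg)
  expect_true(all(file.exists(unlist(paths))))
  truth <- jsonlite::read_json(file.path(outdir, "simulate.json"))$truth
  qcfg <- list(
    transcript = list(gtf = paths$gtf, fasta = paths$fasta,
                      id = "toy_seed42"),
    junctions = paths$sj, coverage = paths$bedgraph,
    event = list(cassette_exon = 11L), output_dir = outdir, seed = 42L)
  rep <- runQuantify(qcfg)
  expect_lt(abs(rep$psi - truth$psi), 0.05)
  expect_lt(abs(rep$retention_fraction - truth$retentionFraction), 0.05)
  expect_lt(abs(rep$coverage_retention_ratio - truth$retentionFraction),
            0.05)
  unlink(outdir, recursive = TRUE)
})

test_that("quantify errors on empty junction input", {
  outdir <- tempfile(); dir.create(outdir)
  empty <- file.path(outdir, "SJ.out.tab"); file.create(empty)
  model <- pnkp_like_model()
  gtf <- file.path(outdir, "t.gtf"); fa <- file.path(outdir, "t.fa")
  writeTranscriptGTF(model, gtf, fa)
  cfg <- list(transcript = list(gtf = gtf, fasta = fa, id = model@id),
              junctions = empty, coverage = empty,
              event = list(cassette_exon = 11L), output_dir = outdir)
  expect_error(runQuantify(cfg), "junction")
  unlink(outdir, recursive = TRUE)
})

test_that("characterize run reproduces the five-variant table rows", {
  model <- pnkp_like_model()
  outdir <- tempfile()
  cfg <- list(
    transcript = list(
      id = model@id,
      exon_widths = as.list(model@exonEnds - model@exonStarts + 1L),
      exon_seqs = as.list(model@exonSeqs),
      intron_seqs = as.list(model@intronSeqs)),
    variants = list(
      list(id = "c.302C>T",
           events = list(list(kind = "snv", c_pos = 302, alt = "T")),
           evidence = "PS4_MOD; PM1_SUP; PM2_SUP; PM3; PP3"),
      list(id = "c.498G>A",
           events = list(list(kind = "skip", exon = 4)),
           evidence = "PVS1_STR; PM1_SUP; PM2_SUP"),
      list(id = "c.311T>C",
           events = list(list(kind = "snv", c_pos = 311, alt = "C")),
           evidence = "PM2_SUP; PM3; PP3"),
      list(id = "c.1029+2T>C",
           events = list(list(kind = "skip", exon = 11),
                         list(kind = "retention", intron = 10)),
           evidence = "PVS1_STR; PM3_SUP; PS4_MOD; PM2_SUP"),
      list(id = "c.151G>C",
           events = list(
             list(kind = "snv", c_pos = 151, alt = "C", confirmed = TRUE),
             list(kind = "retention", intron = 2,
                  snv = list(c_pos = 151, alt = "C"))),
           evidence = "PM2_SUP; PM3; PP3")),
    output_dir = outdir)
  tab <- runCharacterize(cfg)
  expect_equal(tab$r_code[tab$variant == "c.498G>A"], "r.199_498del")
  expect_equal(tab$p_code[tab$variant == "c.498G>A"], "p.Leu67_Lys166del")
  expect_equal(tab$p_code[tab$variant == "c.302C>T"], "p.(Pro101Leu)")
  expect_equal(tab$r_code[tab$variant == "c.1029+2T>C"],
               "r.[937_1029del,936_937ins936+1_937-1]")
  expect_equal(tab$p_code[tab$variant == "c.1029+2T>C"],
               "p.[Phe313_Pro343del,Leu312_Phe313ins*18]")
  expect_match(tab$p_code[tab$variant == "c.151G>C"],
               "^p\\.\\[Val51Leu,Val51Argfs\\*\\d+\\]$")
  expect_equal(tab$tier_points,
               c("likely_pathogenic", "likely_pathogenic", "uncertain",
                 "likely_pathogenic", "uncertain"))
  expect_true(file.exists(file.path(outdir, "characterize.tsv")))
  # evidence-only variants get classification columns only
  tab2 <- runCharacterize(list(
    variants = list(list(id = "x", evidence = "PVS1; PS1")),
    output_dir = outdir))
  expect_true(is.na(tab2$r_code))
  expect_equal(tab2$tier_rules, "pathogenic")
  # events on a missing exon surface as errors
  expect_error(runCharacterize(list(
    transcript = cfg$transcript,
    variants = list(list(id = "bad",
                         events = list(list(kind = "skip", exon = 99)))),
    output_dir = outdir)), "out of range")
  unlink(outdir, recursive = TRUE)
})

test_that("cluster run ties domain summary, ANOVA and bootstrap together", {
  outdir <- tempfile(); dir.create(outdir)
  map <- fha_domain_map()
  tab <- simulateMissenseTable(c(FHA = 10L, kinase = 10L),
                               c(FHA = 26, kinase = 21), 2, map, seed = 3L)
  tsv <- file.path(outdir, "missense.tsv")
  writeVariantTable(tab, tsv)
  coords <- simulateStructure(110L,
    plantedCluster = list(center = c(0, 0, 0), radius = 2,
                          members = c(50, 51, 55, 66, 101, 104)),
    seed = 5L)
  pdb <- file.path(outdir, "structure_synthetic.pdb")
  writeCaPdb(coords, pdb)
  cfg <- list(
    domain_map = list(protein_length = 521L, regions = list(
      list(name = "FHA", first = 6L, last = 110L),
      list(name = "phosphatase", first = 145L, last = 336L),
      list(name = "kinase", first = 341L, last = 516L))),
    variant_table = tsv,
    structure = list(pdb = pdb, chain = "A",
                     positions = c(50, 51, 55, 66, 101, 104),
                     n_boot = 999L),
    seed = 7L, output_dir = outdir)
  rep <- runCluster(cfg)
  expect_lt(rep$clustering$p_value, 0.05)
  expect_equal(rep$clustering$n_boot, 999L)
  expect_equal(sum(rep$domain_summary$count), 20L)
  expect_true(file.exists(file.path(outdir, "cluster.json")))
  # missing structure file is an error
  cfg$structure$pdb <- file.path(outdir, "nope.pdb")
  expect_error(runCluster(cfg), "does not exist")
  unlink(outdir, recursive = TRUE)
})

test_that("CLI dispatcher runs subcommands from a config file", {
  outdir <- tempfile()
  cfgPath <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    counts = list(inclusion_up = 30, inclusion_down = 33, skip = 24,
                  exon_cov = 69, intron_cov = 11),
    output_dir = outdir), cfgPath)
  expect_equal(splicecraftMain(c("quantify", "--config", cfgPath)), 0L)
  json <- jsonlite::read_json(file.path(outdir, "quantify.json"))
  expect_equal(round(as.numeric(json$psi), 3), 0.568)
  # config hash and seed embedded; identical rerun is byte-identical
  f1 <- readLines(file.path(outdir, "quantify.json"))
  expect_false(is.null(json$configHash))
  splicecraftMain(c("quantify", "--config", cfgPath))
  expect_identical(readLines(file.path(outdir, "quantify.json")), f1)
  expect_error(splicecraftMain(character(0)), "usage")
  expect_error(splicecraftMain(c("frobnicate", "--config", cfgPath)),
               "unknown subcommand")
  unlink(c(outdir, cfgPath), recursive = TRUE)
})
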