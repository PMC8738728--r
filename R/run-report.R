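#' @include splice-quant.R hgvs-consequence.R acmg-engine.R missense-domain.R
#' @include synthetic-data.R
NULL

## Config handling -----------------------------------------------------------

#' Read a run configuration
#'
#' One structured YAML file per run; see the subcommand functions for the
#' blocks each consumes. The file's MD5 hash and the seed are embedded in
#' every JSON report so reruns are reproducible and auditable.
#'
#' @param path YAML file.
#' @return config list with attributes `configHash` and `configPath`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file '", path, "' does not exist")
  cfg <- yaml::read_yaml(path)
  attr(cfg, "configHash") <- unname(tools::md5sum(path))
  attr(cfg, "configPath") <- path
  cfg
}

.report_meta <- function(config, seed = NULL) {
  list(tool = "splicecraft",
       version = as.character(packageVersion("splicecraft")),
       configHash = attr(config, "configHash") %||% NA,
       seed = seed %||% config$seed %||% NA)
}

.write_report <- function(report, config, name) {
  outdir <- config$output_dir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  path <- file.path(outdir, paste0(name, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.load_model <- function(config) {
  tr <- config$transcript
  if (is.null(tr)) stop("config has no 'transcript' block")
  if (!is.null(tr$gtf)) {
    for (p in c(tr$gtf, tr$fasta))
      if (!file.exists(p)) stop("transcript input '", p, "' does not exist")
    readTranscriptGTF(tr$gtf, tr$fasta, tr$id)
  } else {
    transcriptModelFromConfig(tr)
  }
}

## Subcommands ---------------------------------------------------------------

#' Quantify aberrant splicing around one event
#'
#' Config blocks: `transcript` (gtf+fasta+id, or inline exon layout),
#' `event` (`cassette_exon`, optional `retained_intron`, `ref_exon`,
#' `library_size`), `junctions` (SJ.out.tab path) and `coverage` (bedGraph
#' path) — or a literal `counts` block (`inclusion_up`, `inclusion_down`,
#' `skip`, `exon_cov`, `intron_cov`) bypassing the files. Reports PSI, the
#' equal-allele-expression mixture, the coverage retention ratio, and FPKM
#' outliers when `fpkm_by_sample` is given.
#'
#' @param config list (see [readRunConfig()]) or YAML path.
#' @return report list, invisibly; JSON and TSV written to `output_dir`.
#' @export
runQuantify <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(config$counts)) {
    cn <- config$counts
    ev <- junctionEvidence(
      inclusionUp = cn$inclusion_up %||% NA_real_,
      inclusionDown = cn$inclusion_down %||% NA_real_,
      skip = cn$skip,
      exonCov = cn$exon_cov %||% NA_real_,
      intronCov = cn$intron_cov %||% NA_real_,
      intronLength = cn$intron_length %||% NA_real_,
      librarySize = cn$library_size %||% NA_real_)
  } else {
    model <- .load_model(config)
    evt <- config$event %||% stop("config has no 'event' or 'counts' block")
    ev <- junctionEvidenceFromFiles(
      config$junctions, config$coverage, model,
      cassetteExon = evt$cassette_exon,
      retainedIntron = evt$retained_intron %||% (evt$cassette_exon - 1L),
      refExon = evt$ref_exon %||% (evt$cassette_exon - 1L),
      librarySize = evt$library_size %||% NA_real_)
  }
  mix <- partitionEqualExpression(ev)
  report <- c(.report_meta(config), list(
    psi = as.numeric(computePsi(ev)),
    inclusion_transcripts = mix@inclusionTranscripts,
    skip_transcripts = mix@skipTranscripts,
    retention_transcripts = mix@retentionTranscripts,
    skip_fraction = mix@skipFraction,
    retention_fraction = mix@retentionFraction,
    warnings = as.list(mix@notes)))
  if (!is.na(ev@exonCov) && !is.na(ev@intronCov) && ev@exonCov > 0)
    report$coverage_retention_ratio <- coverageRetentionRatio(ev)
  if (!is.na(ev@intronLength) && !is.na(ev@librarySize))
    report$intron_fpkm <- intronFpkm(
      round(ev@intronCov * ev@intronLength / 100), ev@intronLength,
      ev@librarySize)
  if (!is.null(config$fpkm_by_sample))
    report$fpkm_outliers <- as.list(
      retentionOutlier(unlist(config$fpkm_by_sample)))
  if (!is.null(config$allele_reads)) {
    ar <- config$allele_reads
    part <- alleleReadPartition(ar$total, ar$spliced, ar$retained)
    report$allele_partition <- list(
      retained_fraction = part@retainedFractionOfAlt,
      binomial_p = part@pBinomial, verdict = part@verdict)
  }
  .write_report(report, config, "quantify")
  num <- vapply(report, is.numeric, logical(1))
  tsv <- data.frame(metric = names(report)[num],
                    value = unlist(report[num]), row.names = NULL)
  outdir <- config$output_dir %||% "."
  write.table(tsv, file.path(outdir, "quantify.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Derive per-variant consequences and ACMG classifications
#'
#' Config blocks: optional `transcript` (needed for r./p. codes) and
#' `variants`: a list of entries with `id`, optional `evidence` (semicolon
#' tokens) and optional `events` — each event a list with `kind`
#' (`skip`/`retention`/`snv`), `exon`/`intron`/`c_pos`+`alt`, optional
#' `snv` rider for retention, and `confirmed`. Evidence-only variants get
#' classification columns only.
#'
#' @param config list or YAML path.
#' @return data.frame of per-variant rows, invisibly; TSV + JSON written.
#' @export
runCharacterize <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  model <- if (!is.null(config$transcript)) .load_model(config) else NULL
  vars <- config$variants %||% stop("config has no 'variants' block")
  rows <- lapply(vars, function(v) {
    r_code <- p_code <- kinds <- NA_character_
    if (!is.null(v$events)) {
      if (is.null(model)) stop("variant '", v$id,
                               "' has events but no transcript was given")
      cons <- lapply(v$events, function(e) {
        conf <- e$confirmed %||% TRUE
        switch(e$kind,
          skip = consequenceOfSkip(model, e$exon, confirmed = conf),
          retention = consequenceOfRetention(model, e$intron,
            snv = e$snv, confirmed = conf),
          snv = consequenceOfSnv(model, e$c_pos, e$alt,
            confirmed = e$confirmed %||% FALSE),
          stop("unknown event kind '", e$kind, "'"))
      })
      comb <- combineAlleleConsequences(cons)
      r_code <- comb$r; p_code <- comb$p
      kinds <- paste(vapply(cons, slot, character(1), "kind"),
                     collapse = ",")
    }
    out <- data.frame(variant = v$id, r_code = r_code, p_code = p_code,
                      kinds = kinds, stringsAsFactors = FALSE)
    if (!is.null(v$evidence)) {
      codes <- parseEvidenceList(v$evidence)
      pt <- classifyPoints(codes); rl <- classifyRules(codes)
      out$evidence <- v$evidence
      out$points <- pt@points
      out$tier_points <- pt@tier
      out$tier_rules <- rl@tier
    } else {
      out$evidence <- NA_character_
      out$points <- NA_real_
      out$tier_points <- NA_character_
      out$tier_rules <- NA_character_
    }
    out
  })
  tab <- do.call(rbind, rows)
  outdir <- config$output_dir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write.table(tab, file.path(outdir, "characterize.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report <- c(.report_meta(config),
              list(variants = jsonlite::toJSON(tab, dataframe = "rows")))
  report$variants <- jsonlite::fromJSON(report$variants)
  .write_report(report, config, "characterize")
  invisible(tab)
}

#' Domain summary, score ANOVA and 3D clustering of missense variants
#'
#' Config blocks: `variant_table` (TSV path with `position` and `score`),
#' `domain_map` (`protein_length` + `regions` list of name/first/last),
#' `structure` (`pdb` path, `chain`, `positions` to test, `n_boot`) and
#' `seed`.
#'
#' @param config list or YAML path.
#' @return report list, invisibly; JSON written to `output_dir`.
#' @export
runCluster <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  dm <- config$domain_map %||% stop("config has no 'domain_map' block")
  map <- domainMap(dm$protein_length,
                   do.call(rbind, lapply(dm$regions, as.data.frame)))
  report <- .report_meta(config, seed = config$seed %||% 1L)
  if (!is.null(config$variant_table)) {
    tab <- readVariantTable(config$variant_table)
    report$domain_summary <- domainSummary(tab, map)
    an <- tryCatch(anovaRegions(tab, map), error = function(e) NULL)
    if (!is.null(an)) report$anova <- list(F = an$F, p = an$p)
  }
  if (!is.null(config$structure)) {
    st <- config$structure
    if (!file.exists(st$pdb)) stop("structure '", st$pdb, "' does not exist")
    coords <- readPdbCa(st$pdb, chain = st$chain %||% "A")
    res <- clusteringTest(unlist(st$positions), coords,
                          nBoot = st$n_boot %||% 999L,
                          seed = config$seed %||% 1L)
    report$clustering <- list(
      observed_mean_pairwise_A = res@observedStat,
      null_mean_A = mean(res@nullStats),
      p_value = res@pValue, n_boot = res@nBoot, seed = res@seed)
  }
  .write_report(report, config, "cluster")
  if (!is.null(report$domain_summary)) {
    outdir <- config$output_dir %||% "."
    write.table(report$domain_summary,
                file.path(outdir, "domain_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Simulate a full synthetic input set
#'
#' Writes, under `output_dir`: the toy transcript as GTF + FASTA, junction
#' counts as SJ.out.tab, coverage as bedGraph, a missense-variant TSV and a
#' synthetic C-alpha PDB, plus a ground-truth JSON.
#'
#' @param config list or YAML path; block `simulation` carries
#'   [simulationConfig()] arguments, `missense` and `structure` optional
#'   generator blocks.
#' @return list of written paths, invisibly.
#' @export
runSimulate <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outdir <- config$output_dir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  simArgs <- config$simulation %||% list()
  simArgs$seed <- config$seed %||% simArgs$seed %||% 1L
  sc <- do.call(simulationConfig, simArgs)
  model <- makeToyTranscript(sc)
  paths <- list(
    gtf = file.path(outdir, "transcript.gtf"),
    fasta = file.path(outdir, "genome.fa"),
    sj = file.path(outdir, "SJ.out.tab"),
    bedgraph = file.path(outdir, "coverage.bedGraph"))
  writeTranscriptGTF(model, paths$gtf, paths$fasta)
  sim <- simulateJunctionEvidence(model, sc)
  writeJunctionsSJ(sim$junctions, paths$sj)
  writeBedGraphCoverage(sim$coverage, paths$bedgraph)
  truth <- sim$truth
  if (!is.null(config$missense)) {
    ms <- config$missense
    map <- domainMap(ms$protein_length,
                     do.call(rbind, lapply(ms$regions, as.data.frame)))
    tab <- simulateMissenseTable(unlist(ms$n_per_domain),
                                 unlist(ms$score_means), ms$score_sd,
                                 map, seed = sc@seed)
    paths$variant_table <- file.path(outdir, "missense.tsv")
    writeVariantTable(tab, paths$variant_table)
  }
  if (!is.null(config$structure_sim)) {
    ss <- config$structure_sim
    coords <- simulateStructure(ss$n_residues,
                                plantedCluster = ss$planted_cluster,
                                seed = sc@seed)
    paths$pdb <- file.path(outdir, "structure_synthetic.pdb")
    writeCaPdb(coords, paths$pdb)
  }
  report <- c(.report_meta(config, seed = sc@seed),
              list(truth = truth, files = paths))
  .write_report(report, config, "simulate")
  invisible(paths)
}

## CLI dispatcher ------------------------------------------------------------

#' Command-line entry point
#'
#' `splicecraft <subcommand> --config <file> [--seed <int>]` with
#' subcommands `simulate`, `quantify`, `consequence`, `classify`,
#' `cluster`, `all`. A thin executable wrapper lives at
#' `system.file("scripts", "splicecraft", package = "splicecraft")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return 0 on success (invisibly); errors propagate with non-zero exit
#'   under `Rscript`.
#' @export
splicecraftMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: splicecraft <simulate|quantify|consequence|classify|cluster|all>",
    "--config <yaml> [--seed <int>]")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  sub <- args[1L]
  flags <- list()
  i <- 2L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i == length(args))
      stop(usage, call. = FALSE)
    flags[[substring(args[i], 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(flags$config)) stop(usage, call. = FALSE)
  config <- readRunConfig(flags$config)
  if (!is.null(flags$seed)) config$seed <- as.integer(flags$seed)
  run <- switch(sub,
    simulate = runSimulate,
    quantify = runQuantify,
    consequence = ,
    classify = runCharacterize,
    cluster = runCluster,
    all = function(cfg) {
      if (!is.null(cfg$simulation)) runSimulate(cfg)
      if (!is.null(cfg$counts) || !is.null(cfg$junctions)) runQuantify(cfg)
      if (!is.null(cfg$variants)) runCharacterize(cfg)
      if (!is.null(cfg$domain_map)) runCluster(cfg)
      invisible(NULL)
    },
    stop("unknown subcommand '", sub, "'\n", usage, call. = FALSE))
  run(config)
  invisible(0L)
}
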