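#' @include transcript-model.R transcript-io.R splice-quant.R utils.R
NULL

## Config --------------------------------------------------------------------

#' Study conditions for the synthetic-data generators
#'
#' The defaults reproduce the transcript architecture and transcript-species
#' mixture of the splice-donor event the analysis is built around: a
#' 12-exon, 1566-bp CDS whose exon 4 spans c.199..498 and exon 11 spans
#' c.937..1029; a heterozygous carrier whose wildtype allele is all normal
#' splicing while the variant allele splits 24:7.5 between exon-11 skipping
#' and intron-10 retention (pooled fractions 0.5 / 0.381 / 0.119); an
#' expected junction-spanning depth of 63 reads (so the mean inclusion and
#' skip counts sit near the observed 30/33 and 24) and per-base exon
#' coverage of 69.
#'
#' @param nExons number of exons.
#' @param exonLengths exon spans in bases (sum divisible by 3).
#' @param intronLengths intron lengths (>= 4; canonical GT..AG written in).
#' @param engineeredStop optional `c(intron_index, inserted_codon_rank)`:
#'   force the first stop of the retained-intron reading frame to sit
#'   exactly at that inserted-codon rank (rank >= 2; rank 1 is impossible
#'   because the donor GT dinucleotide never opens a stop codon).
#' @param plantedCodons named list mapping codon index to a fixed codon
#'   (e.g. `list("67" = "CTG")`); planted codons must not be stops.
#' @param mixture per-allele named proportion vectors over
#'   `normal`/`skip`/`retention`, each summing to 1.
#' @param skipExon,retentionIntron indices of the cassette exon and the
#'   candidate retained intron.
#' @param depth expected junction-spanning read count per species pool.
#' @param coverageDepth expected per-base coverage of a fully covered exon.
#' @param nmdSurvival survival factor applied to the PTC-bearing retention
#'   species (1 = no nonsense-mediated decay, the default model).
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nExons = 12L,
                             exonLengths = c(100L, 51L, 47L, 300L, 73L, 73L,
                                             73L, 73L, 73L, 73L, 93L, 537L),
                             intronLengths = rep(85L, nExons - 1L),
                             engineeredStop = NULL,
                             plantedCodons = list(),
                             mixture = list(
                               allele1 = c(normal = 1),
                               allele2 = c(skip = 24 / 31.5,
                                           retention = 7.5 / 31.5)),
                             skipExon = 11L, retentionIntron = 10L,
                             depth = 63, coverageDepth = 69,
                             nmdSurvival = 1, seed = 1L) {
  new("SimulationConfig",
      nExons = as.integer(nExons),
      exonLengths = as.integer(exonLengths),
      intronLengths = as.integer(intronLengths),
      engineeredStop = if (is.null(engineeredStop)) NULL
                       else as.integer(engineeredStop),
      plantedCodons = plantedCodons,
      mixture = mixture,
      skipExon = as.integer(skipExon),
      retentionIntron = as.integer(retentionIntron),
      depth = depth, coverageDepth = coverageDepth,
      nmdSurvival = nmdSurvival, seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.NONSTOP <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES)[, 3:1], 1L,
                          paste, collapse = ""), .STOPS)

## Toy transcript ------------------------------------------------------------

#' Generate a toy coding transcript from a SimulationConfig
#'
#' The coding sequence starts with ATG, ends with a stop codon and contains
#' no internal in-frame stop; introns carry canonical GT..AG ends. With
#' `engineeredStop = c(j, r)`, the reading frame of intron j, when retained,
#' reaches its first stop exactly at inserted-codon rank r (verified by
#' direct translation of the constructed mutant before returning).
#' Deterministic given `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return a [TranscriptModel-class] with exon and intron sequences.
#' @export
makeToyTranscript <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .with_seed(config@seed, .make_toy(config))
}

.make_toy <- function(config) {
  L <- sum(config@exonLengths)
  if (L < 9L) stop("CDS must hold at least 3 codons")
  ncod <- L %/% 3L
  ends <- cumsum(config@exonLengths)
  es <- config@engineeredStop
  if (!is.null(es)) {
    j <- es[1L]; r <- es[2L]
    if (j > config@nExons - 1L)
      stop("engineeredStop intron index ", j, " out of range")
    if (r < 2L)
      stop("engineered stop rank must be >= 2: the GT donor dinucleotide ",
           "never opens a stop codon")
    o <- ends[j] %% 3L
    if (3L * r - o + 2L > config@intronLengths[j])
      stop("intron ", j, " too short (", config@intronLengths[j],
           " nt) for an engineered stop at inserted codon ", r)
  }
  for (attempt in 1:50) {
    codons <- c("ATG", sample(.NONSTOP, ncod - 2L, replace = TRUE), "TAA")
    for (k in names(config@plantedCodons)) {
      cod <- toupper(config@plantedCodons[[k]])
      ki <- as.integer(k)
      if (cod %in% .STOPS && ki < ncod)
        stop("planted codon ", k, " is an internal stop")
      codons[ki] <- cod
    }
    cds <- paste(codons, collapse = "")
    introns <- vapply(config@intronLengths, function(len) {
      paste0("GT", paste(sample(.BASES, len - 4L, replace = TRUE),
                         collapse = ""), "AG")
    }, character(1))
    ok <- TRUE
    if (!is.null(es)) {
      eng <- .engineer_intron(cds, ends[es[1L]],
                              config@intronLengths[es[1L]], es[2L])
      if (is.null(eng)) { ok <- FALSE } else introns[es[1L]] <- eng
    }
    if (!ok) next
    exonSeqs <- substring(cds, c(1L, head(ends, -1L) + 1L), ends)
    model <- TranscriptModel(
      id = sprintf("toy_seed%d", config@seed),
      exonWidths = config@exonLengths,
      exonSeqs = exonSeqs, intronSeqs = introns)
    if (!is.null(es) &&
        .retained_stop_rank(model, es[1L]) != es[2L]) next
    return(model)
  }
  stop("could not construct a toy transcript honoring the constraints ",
       "(planted codons may conflict with the engineered stop)")
}

# Build intron j (after CDS position cl) whose retained reading frame stops
# first at inserted-codon rank r. Returns NULL when the exon tail makes the
# construction impossible for this CDS draw (caller resamples the CDS).
.engineer_intron <- function(cds, cl, len, r) {
  o <- cl %% 3L
  bases <- sample(.BASES, len, replace = TRUE)
  bases[1:2] <- c("G", "T")
  bases[(len - 1L):len] <- c("A", "G")
  need <- 3L * r - o                       # last intron position of codon r
  bases[(need - 2L):need] <- c("T", "A", "A")
  exon_tail <- if (o > 0L) substr(cds, cl - o + 1L, cl) else ""
  for (t in seq_len(r - 1L)) {
    p <- (3L * t - o - 2L):(3L * t - o)    # intron positions of codon t
    codon <- paste(ifelse(p >= 1L, bases[pmax(p, 1L)],
                          strsplit(exon_tail, "")[[1]][p + o]),
                   collapse = "")
    if (codon %in% .STOPS) {
      fixable <- p[p >= 3L & p <= len - 2L & (p < need - 2L | p > need)]
      if (length(fixable) == 0L) return(NULL)  # exon tail forces a stop
      bases[fixable[1L]] <- "C"
    }
  }
  paste(bases, collapse = "")
}

# Rank of the first stop of the retained-intron reading frame, counting the
# first changed codon as 1 (direct translation of the rebuilt mutant).
.retained_stop_rank <- function(model, intronIndex) {
  cds <- cdsSequence(model)
  cl <- model@exonEnds[intronIndex]
  mut <- paste0(substr(cds, 1L, cl), model@intronSeqs[intronIndex],
                substr(cds, cl + 1L, nchar(cds)))
  prot <- .translate_dna(mut)
  if (!endsWith(prot, "*")) return(NA_integer_)
  i <- (cl - cl %% 3L) %/% 3L              # intact residues before insertion
  nchar(prot) - i
}

## Junction / coverage simulation --------------------------------------------

.pooled_fractions <- function(config) {
  get0s <- function(a, nm) if (nm %in% names(a)) a[[nm]] else 0
  fN <- mean(vapply(config@mixture, get0s, numeric(1), "normal"))
  fS <- mean(vapply(config@mixture, get0s, numeric(1), "skip"))
  fR <- mean(vapply(config@mixture, get0s, numeric(1), "retention"))
  # optional NMD sensitivity: retention species partially degraded
  fR <- fR * config@nmdSurvival
  tot <- fN + fS + fR
  c(normal = fN / tot, skip = fS / tot, retention = fR / tot)
}

#' Simulate junction and coverage evidence for one splice event
#'
#' Junction-spanning read counts are Poisson with mean `depth` times the
#' pooled fraction of the generating transcript species; per-base coverage
#' is Poisson with mean `coverageDepth` times the fraction of species
#' covering the base. Inclusion junctions draw from the normally spliced
#' species; the skip junction from the exon-skipping species; coverage of
#' the candidate intron from the retention species. The ground-truth
#' mixture is returned alongside the observations for recovery tests.
#'
#' @param model a `TranscriptModel` (typically from [makeToyTranscript()]).
#' @param config a [SimulationConfig-class].
#' @return list with elements `evidence` ([JunctionEvidence-class]),
#'   `truth` (psi, skipFraction, retentionFraction, mixture), `junctions`
#'   (STAR SJ.out.tab-style data.frame over the pseudo-genome layout) and
#'   `coverage` (per-base `GRanges`).
#' @export
simulateJunctionEvidence <- function(model, config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  k <- config@skipExon
  j <- config@retentionIntron
  .check_exon_index(model, k)
  if (k == 1L || k == exonCount(model))
    stop("skipExon must be an internal exon")
  .check_intron_index(model, j)
  f <- .pooled_fractions(config)
  lay <- transcriptLayout(model)
  .with_seed(config@seed, {
    inclUp <- rpois(1L, config@depth * f[["normal"]])
    inclDown <- rpois(1L, config@depth * f[["normal"]])
    skip <- rpois(1L, config@depth * f[["skip"]])
    nIntron <- intronCount(model)
    sj <- lapply(seq_len(nIntron), function(i) {
      gi <- lay[lay$feature == "intron" & lay$index == i, ]
      cnt <- if (i == k - 1L) inclUp else if (i == k) inclDown
             else rpois(1L, config@depth)
      data.frame(chrom = gi$chrom, intronStart = gi$gStart,
                 intronEnd = gi$gEnd, strand = 1L, motif = 1L,
                 annotated = 1L, uniqueReads = cnt, multiReads = 0L,
                 maxOverhang = 50L, stringsAsFactors = FALSE)
    })
    up <- lay[lay$feature == "intron" & lay$index == k - 1L, ]
    down <- lay[lay$feature == "intron" & lay$index == k, ]
    sj <- c(sj, list(data.frame(
      chrom = up$chrom, intronStart = up$gStart, intronEnd = down$gEnd,
      strand = 1L, motif = 1L, annotated = 0L, uniqueReads = skip,
      multiReads = 0L, maxOverhang = 50L, stringsAsFactors = FALSE)))
    sj <- do.call(rbind, sj)
    # per-base coverage over the whole pseudo-genome
    glen <- max(lay$gEnd)
    frac <- numeric(glen)
    for (i in seq_len(nrow(lay))) {
      span <- lay$gStart[i]:lay$gEnd[i]
      frac[span] <- if (lay$feature[i] == "exon") {
        if (lay$index[i] == k) f[["normal"]] + f[["retention"]] else 1
      } else {
        if (lay$index[i] == j) f[["retention"]] else 0
      }
    }
    vals <- rpois(glen, config@coverageDepth * frac)
    runs <- rle(vals)
    ends <- cumsum(runs$lengths)
    cov <- GenomicRanges::GRanges(lay$chrom[1L],
      IRanges::IRanges(c(1L, head(ends, -1L) + 1L), ends),
      score = runs$values)
    ref <- lay[lay$feature == "exon" & lay$index == k - 1L, ]
    ri <- lay[lay$feature == "intron" & lay$index == j, ]
    evidence <- junctionEvidence(
      inclusionUp = inclUp, inclusionDown = inclDown, skip = skip,
      exonCov = mean(vals[ref$gStart:ref$gEnd]),
      intronCov = mean(vals[ri$gStart:ri$gEnd]),
      intronLength = ri$gEnd - ri$gStart + 1L,
      librarySize = sum(vals))
    list(evidence = evidence,
         truth = list(psi = f[["normal"]] / (f[["normal"]] + f[["skip"]]),
                      skipFraction = f[["skip"]],
                      retentionFraction = f[["retention"]],
                      mixture = config@mixture),
         junctions = sj, coverage = cov)
  })
}

## Missense table ------------------------------------------------------------

#' Simulate a missense-variant table over a domain map
#'
#' Residue positions are uniform within each region's interval (for
#' `"linker"`, uniform over the residues outside every region); scores are
#' normal with a per-region mean and common standard deviation.
#'
#' @param nPerDomain named integer vector: variants per region (regions with
#'   0 are absent from the table).
#' @param scoreMeans named numeric vector of per-region score means.
#' @param scoreSd common score standard deviation.
#' @param map a [DomainMap-class] (>= 1 region; >= 2 regions are needed for
#'   any downstream ANOVA).
#' @param seed integer seed.
#' @return data.frame with columns `variant`, `position`, `score`,
#'   `region` (ground truth).
#' @export
simulateMissenseTable <- function(nPerDomain, scoreMeans, scoreSd, map,
                                  seed = 1L) {
  stopifnot(is(map, "DomainMap"))
  if (length(nPerDomain) == 0L || is.null(names(nPerDomain)))
    stop("nPerDomain must be a non-empty named vector")
  linker <- setdiff(seq_len(map@proteinLength),
                    unlist(mapply(seq, map@regions$first, map@regions$last,
                                  SIMPLIFY = FALSE)))
  .with_seed(as.integer(seed), {
    rows <- lapply(names(nPerDomain), function(nm) {
      n <- nPerDomain[[nm]]
      if (n == 0L) return(NULL)
      if (nm == "linker") {
        if (length(linker) == 0L) stop("domain map has no linker residues")
        pos <- sample(linker, n, replace = TRUE)
      } else {
        ri <- match(nm, map@regions$name)
        if (is.na(ri)) stop("unknown region '", nm, "'")
        pos <- sample(seq(map@regions$first[ri], map@regions$last[ri]),
                      n, replace = TRUE)
      }
      if (!nm %in% names(scoreMeans))
        stop("no score mean for region '", nm, "'")
      data.frame(position = pos,
                 score = rnorm(n, scoreMeans[[nm]], scoreSd),
                 region = nm, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("all regions have zero variants")
    out <- cbind(variant = sprintf("v%03d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

## Residue coordinates -------------------------------------------------------

#' Simulate residue C-alpha coordinates with an optional planted cluster
#'
#' Residues are uniform in a sphere; planted cluster members are placed
#' uniformly within `radius` of `center`, giving a known spatial cluster
#' for power calibration of [clusteringTest()].
#'
#' @param nResidues number of residues (rownames 1..nResidues).
#' @param plantedCluster optional `list(center = c(x, y, z), radius =,
#'   members = residue positions)`.
#' @param seed integer seed.
#' @param sphereRadius radius of the uniform sphere (Angstrom, default 30).
#' @return n x 3 coordinate matrix with residue-number rownames.
#' @export
simulateStructure <- function(nResidues, plantedCluster = NULL, seed = 1L,
                              sphereRadius = 30) {
  nResidues <- as.integer(nResidues)
  .with_seed(as.integer(seed), {
    unif_sphere <- function(n, R, center = c(0, 0, 0)) {
      dir <- matrix(rnorm(3L * n), ncol = 3L)
      dir <- dir / sqrt(rowSums(dir^2))
      sweep(dir * (R * runif(n)^(1 / 3)), 2L, center, "+")
    }
    coords <- unif_sphere(nResidues, sphereRadius)
    if (!is.null(plantedCluster)) {
      m <- as.integer(plantedCluster$members)
      if (length(m) > nResidues || any(m < 1L) || any(m > nResidues))
        stop("planted cluster members exceed the residue range 1..",
             nResidues)
      coords[m, ] <- unif_sphere(length(m), plantedCluster$radius,
                                 plantedCluster$center)
    }
    dimnames(coords) <- list(seq_len(nResidues), c("x", "y", "z"))
    coords
  })
}

## Variant-table writer ------------------------------------------------------

#' Write a missense-variant table as TSV
#'
#' @param table data.frame (e.g. from [simulateMissenseTable()]).
#' @param path output path.
#' @export
writeVariantTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVariantTable
#' @export
readVariantTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
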