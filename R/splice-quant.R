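#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a JunctionEvidence object
#'
#' @param inclusionUp,inclusionDown reads spanning the upstream and
#'   downstream inclusion junctions (`NA` when only one side was measured).
#' @param skip reads spanning the exon-skipping junction.
#' @param exonCov,intronCov mean per-base coverage of a reference exon and of
#'   the candidate retained intron; either mean coverages or read counts may
#'   be supplied since only their ratio is used.
#' @param intronLength,librarySize intron length (bases) and total mapped
#'   reads, for FPKM.
#' @export
junctionEvidence <- function(inclusionUp, inclusionDown, skip,
                             exonCov = NA_real_, intronCov = NA_real_,
                             intronLength = NA_real_,
                             librarySize = NA_real_) {
  new("JunctionEvidence",
      inclusionUp = as.numeric(inclusionUp),
      inclusionDown = as.numeric(inclusionDown), skip = as.numeric(skip),
      exonCov = as.numeric(exonCov), intronCov = as.numeric(intronCov),
      intronLength = as.numeric(intronLength),
      librarySize = as.numeric(librarySize))
}

.mean_inclusion <- function(up, down) {
  avail <- c(up, down)
  avail <- avail[!is.na(avail)]
  if (length(avail) == 0L)
    stop("at least one inclusion junction count is required")
  list(I = mean(avail), oneSided = length(avail) == 1L)
}

## PSI -----------------------------------------------------------------------

#' Percent spliced in (PSI) of a cassette exon
#'
#' `PSI = I / (I + skip)` where `I` is the mean of the available inclusion
#' junction counts. The mean (not the sum) of the two inclusion junctions is
#' used because each inclusion transcript spans both junctions; summing
#' would double-count it. With only one inclusion junction measured, that
#' single count is used and the result carries attribute
#' `oneSided = TRUE`.
#'
#' @param x a [JunctionEvidence-class], or the upstream inclusion count.
#' @param inclusionDown,skip counts (numeric method).
#' @return PSI in \[0, 1\]; all-zero counts are an explicit error, never a
#'   silent 0.
#' @examples
#' computePsi(30, 33, 24)  # 0.5676, the 56.8% inclusion ratio
#' @export
setMethod("computePsi", "numeric", function(x, inclusionDown, skip, ...) {
  m <- .mean_inclusion(x, inclusionDown)
  if (is.na(skip)) stop("skip count is required")
  if (m$I + skip == 0)
    stop("PSI undefined: all junction counts are zero")
  structure(m$I / (m$I + skip), oneSided = m$oneSided)
})

#' @rdname computePsi-numeric-method
#' @export
setMethod("computePsi", "JunctionEvidence", function(x, ...)
  computePsi(x@inclusionUp, x@inclusionDown, x@skip))

# a bare NA for the missing inclusion side arrives as logical
#' @rdname computePsi-numeric-method
#' @export
setMethod("computePsi", "logical", function(x, inclusionDown, skip, ...)
  computePsi(as.numeric(x), inclusionDown, skip))

## Equal-allele-expression partition -----------------------------------------

#' Partition transcripts under equal allele expression and no NMD
#'
#' For a heterozygous carrier whose variant allele yields only exon-skipping
#' and intron-retaining transcripts while the wildtype allele yields only
#' normally spliced transcripts: with `I` = mean inclusion count and `S` =
#' skip count, the retention species is sized `R = max(0, I - S)` so that
#' both alleles contribute equally (no nonsense-mediated decay assumed).
#' When `S > I` the model is inconsistent with equal expression; `R` is
#' clamped to 0 and a warning is recorded in the result's `notes`.
#'
#' @param x a [JunctionEvidence-class] or the upstream inclusion count.
#' @param inclusionDown,skip counts (numeric method).
#' @param nmdSurvival optional survival factor in (0, 1] applied to the
#'   retention species before normalization (sensitivity analysis; 1 = the
#'   default no-NMD model).
#' @return a [TranscriptMixture-class].
#' @examples
#' m <- partitionEqualExpression(30, 33, 24)
#' m@retentionTranscripts   # 7.5
#' m@retentionFraction      # 0.119 (7.5/63)
#' @export
setMethod("partitionEqualExpression", "numeric",
  function(x, inclusionDown, skip, nmdSurvival = 1, ...) {
    m <- .mean_inclusion(x, inclusionDown)
    I <- m$I; S <- skip
    notes <- if (m$oneSided) "one-sided inclusion evidence" else character(0)
    R <- I - S
    if (R < 0) {
      R <- 0
      notes <- c(notes,
        "skip exceeds inclusion: retention clamped to 0 (model inconsistent with equal expression)")
    }
    R <- R * nmdSurvival
    total <- I + S + R
    new("TranscriptMixture",
        inclusionTranscripts = I, skipTranscripts = S,
        retentionTranscripts = R, psi = I / (I + S),
        retentionFraction = R / total, skipFraction = S / total,
        notes = notes)
  })

#' @rdname partitionEqualExpression-numeric-method
#' @export
setMethod("partitionEqualExpression", "logical",
  function(x, inclusionDown, skip, nmdSurvival = 1, ...)
    partitionEqualExpression(as.numeric(x), inclusionDown, skip,
                             nmdSurvival = nmdSurvival))

#' @rdname partitionEqualExpression-numeric-method
#' @export
setMethod("partitionEqualExpression", "JunctionEvidence",
  function(x, nmdSurvival = 1, ...)
    partitionEqualExpression(x@inclusionUp, x@inclusionDown, x@skip,
                             nmdSurvival = nmdSurvival))

setMethod("show", "TranscriptMixture", function(object) {
  cat(sprintf(
    "TranscriptMixture: I = %.3g, S = %.3g, R = %.3g\n  PSI = %.3f, skip fraction = %.3f, retention fraction = %.3f\n",
    object@inclusionTranscripts, object@skipTranscripts,
    object@retentionTranscripts, object@psi, object@skipFraction,
    object@retentionFraction))
  for (w in object@notes) cat("  note: ", w, "\n", sep = "")
})

## Coverage-based retention --------------------------------------------------

#' Intron/exon coverage ratio as a retention estimate
#'
#' The fraction of transcripts retaining the intron, estimated as
#' `intron coverage / exon coverage`. Mean coverages or raw read counts may
#' be used interchangeably; only the ratio matters.
#'
#' @param x a [JunctionEvidence-class] or the intron coverage.
#' @param exonCov reference-exon coverage (numeric method).
#' @examples
#' coverageRetentionRatio(11, 69)  # 0.159 (~15.9%)
#' @export
setMethod("coverageRetentionRatio", "numeric", function(x, exonCov, ...) {
  if (is.na(exonCov) || exonCov <= 0)
    stop("exon coverage must be > 0")
  if (is.na(x) || x < 0) stop("intron coverage must be >= 0")
  x / exonCov
})

#' @rdname coverageRetentionRatio-numeric-method
#' @export
setMethod("coverageRetentionRatio", "JunctionEvidence", function(x, ...)
  coverageRetentionRatio(x@intronCov, x@exonCov))

## FPKM and outliers ---------------------------------------------------------

#' Intron FPKM
#'
#' `FPKM = count * 1e9 / (intronLength * librarySize)` — the standard
#' fragments-per-kilobase-per-million normalization applied to intronic
#' reads, a simplified intron-retention quantifier.
#'
#' @param count intronic read count.
#' @param intronLength intron length in bases (> 0).
#' @param librarySize total mapped reads (> 0).
#' @examples
#' intronFpkm(100, 1000, 1e7)  # 10
#' @export
intronFpkm <- function(count, intronLength, librarySize) {
  if (any(is.na(c(count, intronLength, librarySize))))
    stop("count, intronLength and librarySize are all required")
  if (intronLength <= 0) stop("intronLength must be > 0")
  if (librarySize <= 0) stop("librarySize must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count * 1e9 / (intronLength * librarySize)
}

#' Flag intron-retention FPKM outliers across a cohort
#'
#' A sample is an outlier iff its value exceeds `Q3 + 1.5 * IQR` of the
#' remaining samples (the standard box-plot rule, computed leave-one-out so
#' a single extreme carrier cannot mask itself).
#'
#' @param fpkmBySample named numeric vector, one FPKM per sample (>= 3).
#' @param k whisker multiplier (1.5 = standard box-plot rule).
#' @return character vector of outlier sample names (possibly empty).
#' @examples
#' retentionOutlier(c(A = 1, B = 1.2, C = 1.1, D = 9))  # "D"
#' @export
retentionOutlier <- function(fpkmBySample, k = 1.5) {
  if (length(fpkmBySample) < 3L)
    stop("at least 3 samples are required")
  if (is.null(names(fpkmBySample)))
    names(fpkmBySample) <- paste0("sample", seq_along(fpkmBySample))
  out <- vapply(seq_along(fpkmBySample), function(i) {
    rest <- fpkmBySample[-i]
    fpkmBySample[i] > quantile(rest, 0.75, names = FALSE) + k * IQR(rest)
  }, logical(1))
  names(fpkmBySample)[out]
}

## Allele-tagged read partition ----------------------------------------------

#' Partition variant-allele reads between spliced and retained transcripts
#'
#' For reads carrying a variant base, splits them into correctly spliced and
#' intron-retaining origins and judges whether the two species from that
#' allele are about equally expressed: verdict "about equally expressed"
#' when the retained fraction lies in \[1/3, 2/3\]; a two-sided binomial
#' test against 0.5 is also reported.
#'
#' @param total total variant-allele reads.
#' @param spliced,retained reads assigned to each species
#'   (`spliced + retained <= total`; reads not informative for either
#'   species make up the difference).
#' @return an [AlleleReadPartition-class].
#' @examples
#' alleleReadPartition(10, 4, 6)  # retained fraction 0.6, about equal
#' @export
alleleReadPartition <- function(total, spliced, retained) {
  if (spliced + retained == 0)
    stop("no reads assigned to either species")
  if (any(c(total, spliced, retained) < 0)) stop("counts must be >= 0")
  frac <- retained / (spliced + retained)
  p <- binom.test(retained, spliced + retained, 0.5)$p.value
  new("AlleleReadPartition",
      altReadsTotal = total, altReadsSpliced = spliced,
      altReadsRetained = retained, retainedFractionOfAlt = frac,
      pBinomial = p,
      verdict = if (frac >= 1 / 3 && frac <= 2 / 3)
        "about equally expressed" else "unbalanced")
}

setMethod("show", "AlleleReadPartition", function(object) {
  cat(sprintf(
    "AlleleReadPartition: %g alt reads (%g spliced, %g retained)\n  retained fraction %.3f, binomial p = %.3g -> %s\n",
    object@altReadsTotal, object@altReadsSpliced, object@altReadsRetained,
    object@retainedFractionOfAlt, object@pBinomial, object@verdict))
})

## File dialects -------------------------------------------------------------

.sj_columns <- c("chrom", "intronStart", "intronEnd", "strand", "motif",
                 "annotated", "uniqueReads", "multiReads", "maxOverhang")

#' Read a STAR SJ.out.tab-style junction file
#'
#' Nine tab-separated columns: chromosome, 1-based first and last base of
#' the intron, strand code (0/1/2), motif code, annotation flag, unique read
#' count, multi-mapping read count, maximum overhang. Unique read counts are
#' the quantification currency.
#'
#' @param path junction file.
#' @return data.frame with named columns.
#' @export
readJunctionsSJ <- function(path) {
  sj <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read junction file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(sj) != 9L)
    stop("junction file '", path, "' has ", ncol(sj),
         " columns; the SJ.out.tab dialect has 9")
  names(sj) <- .sj_columns
  if (!is.numeric(sj$intronStart) || !is.numeric(sj$uniqueReads) ||
      any(sj$intronStart > sj$intronEnd))
    stop("junction file '", path, "' violates the SJ.out.tab dialect")
  sj
}

#' @rdname readJunctionsSJ
#' @param junctions data.frame as returned by [readJunctionsSJ()].
#' @export
writeJunctionsSJ <- function(junctions, path) {
  stopifnot(all(.sj_columns %in% names(junctions)))
  write.table(junctions[, .sj_columns], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-base coverage from a bedGraph file
#'
#' @param path bedGraph file (0-based half-open intervals, fourth column the
#'   coverage value).
#' @return a `GRanges` with a `score` column.
#' @export
readBedGraphCoverage <- function(path) {
  tryCatch(rtracklayer::import(path, format = "bedGraph"),
           error = function(e) stop("cannot read bedGraph '", path, "': ",
                                    conditionMessage(e)))
}

#' @rdname readBedGraphCoverage
#' @param cov `GRanges` with a `score` column.
#' @export
writeBedGraphCoverage <- function(cov, path) {
  rtracklayer::export(cov, path, format = "bedGraph")
  invisible(path)
}

# Mean coverage of a 1-based closed genomic interval from a coverage GRanges.
.mean_cov <- function(cov, chrom, gStart, gEnd) {
  target <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(gStart, gEnd))
  hits <- GenomicRanges::findOverlaps(cov, target)
  width_total <- gEnd - gStart + 1L
  if (length(hits) == 0L) return(0)
  piece <- GenomicRanges::pintersect(cov[S4Vectors::queryHits(hits)],
                                     target[S4Vectors::subjectHits(hits)])
  sum(GenomicRanges::width(piece) * cov$score[S4Vectors::queryHits(hits)]) /
    width_total
}

#' Assemble JunctionEvidence for one splice event from files
#'
#' Selects, on the model's pseudo-genome layout, the upstream and downstream
#' inclusion junctions of the cassette exon, the skip junction, and the
#' coverage of a reference exon and the candidate retained intron.
#'
#' @param sj junction data.frame ([readJunctionsSJ()]) or path.
#' @param cov coverage `GRanges` ([readBedGraphCoverage()]) or path.
#' @param model the `TranscriptModel` the files were laid out on.
#' @param cassetteExon index of the skipped exon.
#' @param retainedIntron index of the candidate retained intron (default:
#'   the intron upstream of the cassette exon).
#' @param refExon reference exon for the coverage denominator (default: the
#'   exon upstream of the cassette exon).
#' @param librarySize total mapped reads (for FPKM), optional.
#' @param chrom pseudo-chromosome name used in the files.
#' @export
junctionEvidenceFromFiles <- function(sj, cov, model, cassetteExon,
                                      retainedIntron = cassetteExon - 1L,
                                      refExon = cassetteExon - 1L,
                                      librarySize = NA_real_,
                                      chrom = "chrT") {
  if (is.character(sj)) sj <- readJunctionsSJ(sj)
  if (nrow(sj) == 0L) stop("junction table is empty")
  if (is.character(cov)) cov <- readBedGraphCoverage(cov)
  .check_exon_index(model, cassetteExon)
  if (cassetteExon == 1L || cassetteExon == exonCount(model))
    stop("cassette exon must be internal")
  lay <- transcriptLayout(model, chrom = chrom)
  gex <- function(i) lay[lay$feature == "exon" & lay$index == i, ]
  gin <- function(i) lay[lay$feature == "intron" & lay$index == i, ]
  jcount <- function(gStart, gEnd) {
    hit <- sj$chrom == chrom & sj$intronStart == gStart & sj$intronEnd == gEnd
    if (!any(hit)) 0 else sum(sj$uniqueReads[hit])
  }
  k <- cassetteExon
  up <- gin(k - 1L); down <- gin(k)
  inclUp <- jcount(up$gStart, up$gEnd)
  inclDown <- jcount(down$gStart, down$gEnd)
  skip <- jcount(up$gStart, down$gEnd)
  re <- gex(refExon); ri <- gin(retainedIntron)
  junctionEvidence(
    inclusionUp = inclUp, inclusionDown = inclDown, skip = skip,
    exonCov = .mean_cov(cov, chrom, re$gStart, re$gEnd),
    intronCov = .mean_cov(cov, chrom, ri$gStart, ri$gEnd),
    intronLength = ri$gEnd - ri$gStart + 1L,
    librarySize = librarySize)
}
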