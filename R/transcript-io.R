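#' @include transcript-model.R
NULL

## GTF + FASTA ---------------------------------------------------------------

#' Read a TranscriptModel from GTF + genome FASTA
#'
#' Uses the transcript's CDS features as coding exons (so c.1 is the first
#' CDS base), extracts exon and intron sequences from the genome, and
#' normalizes minus-strand transcripts to transcript orientation at parse
#' time: downstream code never sees strand.
#'
#' @param gtf path to a GTF file with CDS features carrying a
#'   `transcript_id` attribute.
#' @param fasta path to the genome FASTA.
#' @param transcriptId required transcript selector; an absent id is an
#'   error, never a silent first match.
#' @return a [TranscriptModel-class].
#' @export
readTranscriptGTF <- function(gtf, fasta, transcriptId) {
  stopifnot(length(transcriptId) == 1L)
  gr <- rtracklayer::import(gtf, format = "gtf")
  if (!"transcript_id" %in% names(S4Vectors::mcols(gr)))
    stop("GTF '", gtf, "' has no transcript_id attribute")
  cds <- gr[gr$type == "CDS" & gr$transcript_id %in% transcriptId]
  if (length(cds) == 0L)
    stop("transcript '", transcriptId, "' not found in '", gtf, "'")
  strand <- as.character(GenomicRanges::strand(cds)[1L])
  cds <- GenomicRanges::sort(cds, decreasing = (strand == "-"))
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(cds)[1L])
  if (!chrom %in% names(genome))
    stop("sequence '", chrom, "' not found in '", fasta, "'")
  fetch <- function(start, end) {
    s <- Biostrings::subseq(genome[[chrom]], start, end)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }
  st <- GenomicRanges::start(cds); en <- GenomicRanges::end(cds)
  exonSeqs <- unname(mapply(fetch, st, en))
  n <- length(cds)
  intronSeqs <- character(0)
  if (n > 1L) {
    # genomic gaps between consecutive CDS features, in transcript order
    if (strand == "+") {
      is_ <- en[-n] + 1L; ie_ <- st[-1L] - 1L
    } else {
      is_ <- en[-1L] + 1L; ie_ <- st[-n] - 1L
    }
    if (any(ie_ < is_)) stop("adjacent CDS features overlap or touch")
    intronSeqs <- unname(mapply(fetch, is_, ie_))
  }
  TranscriptModel(id = transcriptId,
                  exonWidths = en - st + 1L,
                  exonSeqs = exonSeqs, intronSeqs = intronSeqs,
                  cdsStartOffset = 0L, strand = strand)
}

#' Read a TranscriptModel from a self-contained structured config
#'
#' The config (a list, or a path to a YAML file) carries the exon layout and
#' sequences directly and produces the same `TranscriptModel` values as the
#' GTF + FASTA path. Fields: `id`, `exon_widths` (or `exon_seqs` alone, in
#' which case widths are their lengths), optional `intron_seqs`,
#' `cds_start_offset`, `strand`.
#'
#' @param config list or YAML path.
#' @export
transcriptModelFromConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seqs <- if (is.null(config$exon_seqs)) NULL else unlist(config$exon_seqs)
  widths <- if (is.null(config$exon_widths)) NULL
            else unlist(config$exon_widths)
  off <- config$cds_start_offset %||% 0L
  if (is.null(widths)) {
    if (is.null(seqs)) stop("config needs exon_widths or exon_seqs")
    widths <- nchar(seqs)
    widths[1L] <- widths[1L] - off
  }
  TranscriptModel(id = config$id %||% "transcript",
                  exonWidths = widths, exonSeqs = seqs,
                  intronSeqs = if (is.null(config$intron_seqs)) NULL
                               else unlist(config$intron_seqs),
                  cdsStartOffset = off, strand = config$strand %||% "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pseudo-genome layout and writers ------------------------------------------

# Genomic layout of a model on a single pseudo-chromosome: exons and introns
# laid out in transcript order starting at gStart. Requires intron sequences
# (their lengths define the gaps).
transcriptLayout <- function(model, chrom = "chrT", gStart = 1L) {
  n <- exonCount(model)
  if (n > 1L && length(model@intronSeqs) == 0L)
    stop("transcript '", model@id, "' needs intron sequences for a genomic layout")
  spans <- model@exonEnds - model@exonStarts + 1L
  spans[1L] <- spans[1L] + model@cdsStartOffset
  iw <- if (n > 1L) nchar(model@intronSeqs) else integer(0)
  widths <- integer(2L * n - 1L)
  widths[seq(1L, by = 2L, length.out = n)] <- spans
  if (n > 1L) widths[seq(2L, by = 2L, length.out = n - 1L)] <- iw
  ends <- gStart - 1L + cumsum(widths)
  starts <- c(gStart, head(ends, -1L) + 1L)
  feat <- rep(c("exon", "intron"), length.out = 2L * n - 1L)
  idx <- ifelse(feat == "exon", (seq_along(feat) + 1L) %/% 2L,
                seq_along(feat) %/% 2L)
  data.frame(chrom = chrom, feature = feat, index = idx,
             gStart = starts, gEnd = ends, stringsAsFactors = FALSE)
}

#' Write a TranscriptModel as GTF plus pseudo-genome FASTA
#'
#' Lays the transcript out on a single pseudo-chromosome (exons and introns
#' in order) and writes matching GTF (exon + CDS features) and FASTA files,
#' which [readTranscriptGTF()] reads back to an identical model.
#'
#' @param model a `TranscriptModel` with exon and intron sequences.
#' @param gtfPath,fastaPath output paths.
#' @param chrom pseudo-chromosome name.
#' @export
writeTranscriptGTF <- function(model, gtfPath, fastaPath, chrom = "chrT") {
  lay <- transcriptLayout(model, chrom = chrom)
  n <- exonCount(model)
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, by = 2L, length.out = n)] <- model@exonSeqs
  if (n > 1L)
    pieces[seq(2L, by = 2L, length.out = n - 1L)] <- model@intronSeqs
  genome <- paste(pieces, collapse = "")
  L <- nchar(genome)
  ex <- lay[lay$feature == "exon", ]
  # coding part of each exon (exon 1 carries the cdsStartOffset leader)
  cdsStart <- ex$gStart
  cdsStart[1L] <- cdsStart[1L] + model@cdsStartOffset
  cdsEnd <- ex$gEnd
  if (model@strand == "-") {
    # mirror transcript-orientation layout onto the written (plus) genome
    genome <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genome)))
    mirror <- function(p) L - p + 1L
    tmpS <- mirror(ex$gEnd); ex$gEnd <- mirror(ex$gStart); ex$gStart <- tmpS
    tmpS <- mirror(cdsEnd); cdsEnd <- mirror(cdsStart); cdsStart <- tmpS
  }
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', model@id, model@id)
  rows <- character(0)
  for (i in seq_len(nrow(ex))) {
    rows <- c(rows,
      paste(chrom, "splicecraft", "exon", ex$gStart[i], ex$gEnd[i], ".",
            model@strand, ".", attr_str, sep = "\t"),
      paste(chrom, "splicecraft", "CDS", cdsStart[i], cdsEnd[i], ".",
            model@strand, "0", attr_str, sep = "\t"))
  }
  writeLines(rows, gtfPath)
  writeLines(c(paste0(">", chrom), genome), fastaPath)
  invisible(list(gtf = gtfPath, fasta = fastaPath))
}
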