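#' @include AllClasses.R AllGenerics.R
NULL

## Translation ---------------------------------------------------------------

# Codon table: standard genetic code, DNA alphabet, from Biostrings.
.codon_table <- function() Biostrings::GENETIC_CODE

.translate_dna <- function(cdna) {
  n <- nchar(cdna)
  ncod <- n %/% 3L
  if (ncod == 0L) return("")
  codons <- substring(cdna, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
  aa <- unname(.codon_table()[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L])]
  paste(aa, collapse = "")
}

#' Translate a cDNA sequence with the standard genetic code
#'
#' Translates codon by codon from the first base, stops at and includes the
#' first stop codon (reported as `*`), and ignores a trailing partial codon.
#' `U` is accepted and treated as `T`.
#'
#' @param cdna nucleotide string (ACGT/ACGU), length >= 3.
#' @return amino-acid string in one-letter code, e.g. `"MK*"`.
#' @examples
#' translateCdna("ATGAAATAG")  # "MK*"
#' translateCdna("ATGCCT")     # "MP"
#' @export
translateCdna <- function(cdna) {
  stopifnot(is.character(cdna), length(cdna) == 1L)
  cdna <- chartr("u", "U", toupper(cdna))
  cdna <- chartr("U", "T", cdna)
  if (grepl("[^ACGT]", cdna))
    stop("cdna contains characters outside A, C, G, T/U")
  if (nchar(cdna) < 3L) stop("cdna must be at least one codon (3 bases) long")
  .translate_dna(cdna)
}

## Coordinate arithmetic -----------------------------------------------------

#' Map a CDS position to its codon and offset
#'
#' @param cPos 1-based c.-coordinate (>= 1).
#' @return named integer vector `c(codon = ..., offset = ...)` with
#'   `codon = floor((cPos - 1)/3) + 1` and `offset` in 1..3.
#' @examples
#' cToCodon(199)  # codon 67, offset 1
#' cToCodon(498)  # codon 166, offset 3
#' @export
cToCodon <- function(cPos) {
  if (!is.numeric(cPos) || length(cPos) != 1L || is.na(cPos) || cPos < 1)
    stop("cPos must be a single integer >= 1")
  cPos <- as.integer(cPos)
  c(codon = (cPos - 1L) %/% 3L + 1L, offset = (cPos - 1L) %% 3L + 1L)
}

## Construction --------------------------------------------------------------

#' Construct a TranscriptModel
#'
#' @param id transcript identifier.
#' @param exonWidths integer vector of exon spans in c.-coordinates; exon 1
#'   starts at c.1 and exons tile the CDS contiguously.
#' @param exonSeqs optional character vector (or `DNAStringSet`) of exon
#'   sequences; exon 1 may carry `cdsStartOffset` leader bases.
#' @param intronSeqs optional intron sequences (intron i between exon i and
#'   exon i+1).
#' @param cdsStartOffset transcript bases before the A of the ATG (default 0).
#' @param strand `"+"` (default) or `"-"`; annotation only.
#' @return a validated [TranscriptModel-class] object.
#' @export
TranscriptModel <- function(id, exonWidths, exonSeqs = NULL,
                            intronSeqs = NULL, cdsStartOffset = 0L,
                            strand = "+") {
  exonWidths <- as.integer(exonWidths)
  ends <- cumsum(exonWidths)
  starts <- c(1L, head(ends, -1L) + 1L)
  as_chr <- function(x) {
    if (is.null(x)) return(character(0))
    toupper(as.character(x))
  }
  new("TranscriptModel", id = as.character(id),
      exonStarts = starts, exonEnds = as.integer(ends),
      exonSeqs = as_chr(exonSeqs), intronSeqs = as_chr(intronSeqs),
      cdsStartOffset = as.integer(cdsStartOffset), strand = strand)
}

## Accessors -----------------------------------------------------------------

#' @describeIn TranscriptModel-class number of exons.
#' @param model a `TranscriptModel`.
#' @export
setMethod("exonCount", "TranscriptModel", function(model)
  length(model@exonStarts))

#' @describeIn TranscriptModel-class number of introns (exons - 1).
#' @export
setMethod("intronCount", "TranscriptModel", function(model)
  length(model@exonStarts) - 1L)

#' @describeIn TranscriptModel-class coding sequence (ATG..stop..end) as a
#'   single string; errors when sequences were not supplied.
#' @export
setMethod("cdsSequence", "TranscriptModel", function(model) {
  if (length(model@exonSeqs) == 0L)
    stop("transcript '", model@id, "' has no sequences")
  n <- length(model@exonEnds)
  substr(paste(model@exonSeqs, collapse = ""),
         model@cdsStartOffset + 1L,
         model@cdsStartOffset + model@exonEnds[n])
})

#' @describeIn TranscriptModel-class reference protein (one-letter, includes
#'   the terminal `*`).
#' @export
setMethod("refProtein", "TranscriptModel", function(model)
  .translate_dna(cdsSequence(model)))

#' @describeIn TranscriptModel-class closed 1-based c.-interval of an exon as
#'   `c(c_start = ..., c_end = ...)`.
#' @param exonIndex 1-based exon index.
#' @export
setMethod("exonCRange", "TranscriptModel", function(model, exonIndex) {
  .check_exon_index(model, exonIndex)
  c(c_start = model@exonStarts[exonIndex], c_end = model@exonEnds[exonIndex])
})

#' @describeIn TranscriptModel-class sequence of intron `intronIndex`.
#' @param intronIndex 1-based intron index.
#' @export
setMethod("intronSeq", "TranscriptModel", function(model, intronIndex) {
  .check_intron_index(model, intronIndex)
  if (length(model@intronSeqs) == 0L)
    stop("transcript '", model@id, "' has no intron sequences")
  model@intronSeqs[intronIndex]
})

.check_exon_index <- function(model, exonIndex) {
  n <- length(model@exonStarts)
  if (!is.numeric(exonIndex) || length(exonIndex) != 1L ||
      is.na(exonIndex) || exonIndex < 1L || exonIndex > n)
    stop("transcript '", model@id, "': exon index ", exonIndex,
         " out of range (1..", n, ")")
  invisible(TRUE)
}

.check_intron_index <- function(model, intronIndex) {
  n <- length(model@exonStarts) - 1L
  if (!is.numeric(intronIndex) || length(intronIndex) != 1L ||
      is.na(intronIndex) || intronIndex < 1L || intronIndex > n)
    stop("transcript '", model@id, "': intron index ", intronIndex,
         " out of range (1..", n, ")")
  invisible(TRUE)
}

setMethod("show", "TranscriptModel", function(object) {
  n <- length(object@exonStarts)
  cat("TranscriptModel '", object@id, "' (", object@strand, " strand)\n",
      sep = "")
  cat("  ", n, " exons, CDS c.1..c.", object@exonEnds[n], sep = "")
  if (length(object@exonSeqs)) {
    prot <- refProtein(object)
    cat(", protein ", nchar(prot) - as.integer(endsWith(prot, "*")),
        " aa + stop", sep = "")
  }
  cat("\n  exon boundaries (c.): ",
      paste(object@exonEnds, collapse = ", "), "\n", sep = "")
  if (length(object@intronSeqs))
    cat("  intron lengths: ",
        paste(nchar(object@intronSeqs), collapse = ", "), "\n", sep = "")
})
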