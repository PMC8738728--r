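#' @include transcript-model.R
NULL

## Amino-acid code formatting ------------------------------------------------

.aa_three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
               Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
               L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
               S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
               "*" = "*")

.aa_fmt <- function(aa1, letters3 = TRUE) {
  if (!letters3) return(aa1)
  paste(vapply(strsplit(aa1, "")[[1]], function(a) {
    if (!a %in% names(.aa_three)) stop("unknown amino acid '", a, "'")
    .aa_three[[a]]
  }, character(1)), collapse = "")
}

.wrap_pred <- function(code, confirmed) {
  # predicted-only consequences are parenthesized, RNA-confirmed ones bare
  if (confirmed) paste0("p.", code) else paste0("p.(", code, ")")
}

.rna_base <- function(b) chartr("ACGT", "acgu", toupper(b))

.new_consequence <- function(rCode, pCode, kind, firstResidue, lastResidue,
                             deletedAaCount = 0L, fsStopRank = 0L,
                             inFrame, confirmed) {
  new("Consequence", rCode = rCode, pCode = pCode, kind = kind,
      firstResidue = as.integer(firstResidue),
      lastResidue = as.integer(lastResidue),
      deletedAaCount = as.integer(deletedAaCount),
      fsStopRank = as.integer(fsStopRank),
      inFrame = inFrame, confirmed = confirmed)
}

setMethod("show", "Consequence", function(object) {
  cat("Consequence [", object@kind, "]\n", sep = "")
  cat("  ", object@rCode, " ; ", object@pCode, "\n", sep = "")
  cat("  residues ", object@firstResidue, "..", object@lastResidue,
      if (object@deletedAaCount > 0)
        paste0(" (", object@deletedAaCount, " aa deleted)") else "",
      if (object@fsStopRank > 0)
        paste0(", novel stop at rank ", object@fsStopRank) else "",
      ", ", if (object@inFrame) "in-frame" else "frame-shifting",
      if (object@confirmed) ", RNA-confirmed" else ", predicted",
      "\n", sep = "")
})

## r. codes ------------------------------------------------------------------

#' RNA-level code for skipping an internal exon
#'
#' `r.<c_start>_<c_end>del` over the exon's c.-range. Only internal exons
#' can be skipped (a skip junction needs both neighbors).
#'
#' @param model a `TranscriptModel`.
#' @param exonIndex index of the skipped exon.
#' @examples
#' # exon 4 at c.199..498 -> "r.199_498del"
#' @export
skipToRCode <- function(model, exonIndex) {
  .check_exon_index(model, exonIndex)
  if (exonIndex == 1L || exonIndex == exonCount(model))
    stop("transcript '", model@id, "': exon ", exonIndex,
         " is terminal; no skip junction exists")
  r <- exonCRange(model, exonIndex)
  sprintf("r.%d_%ddel", r[["c_start"]], r[["c_end"]])
}

#' RNA-level code for retaining an intron
#'
#' `r.<c_last>_<c_next>ins<c_last>+1_<c_next>-1` where `c_last` is the last
#' base of the upstream exon.
#'
#' @param model a `TranscriptModel`.
#' @param intronIndex index of the retained intron.
#' @examples
#' # intron 10 between c.936 and c.937 -> "r.936_937ins936+1_937-1"
#' @export
retentionToRCode <- function(model, intronIndex) {
  .check_intron_index(model, intronIndex)
  cl <- model@exonEnds[intronIndex]
  sprintf("r.%d_%dins%d+1_%d-1", cl, cl + 1L, cl, cl + 1L)
}

## Frameshift helper ---------------------------------------------------------

# Compare a mutant translation to the reference protein and build the
# p.<Aaa><pos><New>fs*<rank> code from the first differing residue. The
# novel stop counts the first substituted residue as rank 1.
.fs_code <- function(refProt, mutProt, confirmed, letters3 = TRUE) {
  refv <- strsplit(refProt, "")[[1]]
  mutv <- strsplit(mutProt, "")[[1]]
  nmin <- min(length(refv), length(mutv))
  diff <- which(refv[seq_len(nmin)] != mutv[seq_len(nmin)])
  pos <- if (length(diff)) diff[1L] else nmin + 1L
  if (pos > length(mutv))
    stop("mutant and reference proteins are identical; not a frameshift")
  refAa <- if (pos <= length(refv)) refv[pos] else "*"
  newAa <- mutv[pos]
  if (newAa == "*") {
    # frame shift whose very first novel codon is a stop: nonsense-style code
    code <- paste0(.aa_fmt(refAa, letters3), pos, "*")
    return(list(pCode = .wrap_pred(code, confirmed), pos = pos, rank = 1L))
  }
  stopIdx <- which(mutv == "*")
  stopIdx <- stopIdx[stopIdx >= pos]
  rank <- if (length(stopIdx)) stopIdx[1L] - pos + 1L else 0L
  code <- paste0(.aa_fmt(refAa, letters3), pos, .aa_fmt(newAa, letters3),
                 "fs*", if (rank > 0L) rank else "?")
  list(pCode = .wrap_pred(code, confirmed), pos = pos, rank = rank)
}

## Exon skipping -------------------------------------------------------------

#' Protein-level consequence of skipping an internal exon
#'
#' Codon-aligned in-frame skips (span divisible by 3, exon starting at codon
#' position 1) delete whole residues: `p.<Aaa><i>_<Bbb><j>del`. In-frame but
#' non-codon-aligned skips additionally create a new junction residue
#' (`delins`). Spans not divisible by 3 shift the frame; the mutant
#' transcript is rebuilt and translated to locate the first changed residue
#' and the rank of the novel stop (`fs*N`).
#'
#' @param model a `TranscriptModel` with sequences.
#' @param exonIndex internal exon to skip.
#' @param confirmed TRUE (default) when the skip is RNA-confirmed; bare
#'   p-code. FALSE wraps the code in `p.(...)`.
#' @param letters3 use three-letter amino-acid codes (default).
#' @return a [Consequence-class].
#' @export
consequenceOfSkip <- function(model, exonIndex, confirmed = TRUE,
                              letters3 = TRUE) {
  rCode <- skipToRCode(model, exonIndex)
  if (length(model@exonSeqs) == 0L)
    stop("transcript '", model@id, "' has no sequences; residue identities unavailable")
  r <- exonCRange(model, exonIndex)
  s <- r[["c_start"]]; e <- r[["c_end"]]
  span <- e - s + 1L
  inFrame <- span %% 3L == 0L
  cds <- cdsSequence(model)
  prot <- refProtein(model)
  protv <- strsplit(prot, "")[[1]]
  first <- cToCodon(s)[["codon"]]
  last <- cToCodon(e)[["codon"]]
  if (inFrame && (s - 1L) %% 3L == 0L) {
    code <- paste0(.aa_fmt(protv[first], letters3), first, "_",
                   .aa_fmt(protv[last], letters3), last, "del")
    return(.new_consequence(rCode, .wrap_pred(code, confirmed),
                            "inframe_del", first, last,
                            deletedAaCount = span %/% 3L,
                            inFrame = TRUE, confirmed = confirmed))
  }
  mut <- paste0(substr(cds, 1L, s - 1L), substr(cds, e + 1L, nchar(cds)))
  mutProt <- .translate_dna(mut)
  if (inFrame) {
    # junction codon is rebuilt from the two flanks
    newAa <- substr(mutProt, first, first)
    code <- paste0(.aa_fmt(protv[first], letters3), first, "_",
                   .aa_fmt(protv[last], letters3), last, "delins",
                   .aa_fmt(newAa, letters3))
    return(.new_consequence(rCode, .wrap_pred(code, confirmed),
                            "inframe_delins", first, last,
                            deletedAaCount = last - first + 1L,
                            inFrame = TRUE, confirmed = confirmed))
  }
  fs <- .fs_code(prot, mutProt, confirmed, letters3)
  .new_consequence(rCode, fs$pCode, "frameshift", fs$pos, fs$pos,
                   fsStopRank = fs$rank, inFrame = FALSE,
                   confirmed = confirmed)
}

## Intron retention ----------------------------------------------------------

#' Protein-level consequence of retaining an intron
#'
#' The intron sequence is inserted between its flanking exons. With a
#' codon-aligned insertion point, an in-frame stop within the retained
#' intron truncates the protein: `p.<Aaa><i>_<Bbb><i+1>ins*<N>` with `N` the
#' rank of the stop among the inserted codons. A stop-free in-frame intron
#' yields a plain peptide insertion. A mid-codon insertion point, or an
#' intron length that shifts the frame (without an upstream in-frame stop),
#' is a frameshift: `p.<Aaa><pos><New>fs*<N>` with `N` counting the first
#' changed residue as 1, determined by rebuilding and translating the
#' mutant transcript.
#'
#' @param model a `TranscriptModel` with intron sequences.
#' @param intronIndex intron to retain.
#' @param snv optional `list(c_pos =, alt =)` single-nucleotide change on
#'   the same allele, applied to the mutant transcript before translation
#'   (e.g. a last-exon-base substitution that also perturbs splicing).
#' @param confirmed,letters3 as in [consequenceOfSkip()].
#' @return a [Consequence-class].
#' @export
consequenceOfRetention <- function(model, intronIndex, snv = NULL,
                                   confirmed = TRUE, letters3 = TRUE) {
  rCode <- retentionToRCode(model, intronIndex)
  iseq <- intronSeq(model, intronIndex)
  cds <- cdsSequence(model)
  prot <- refProtein(model)
  protv <- strsplit(prot, "")[[1]]
  cl <- model@exonEnds[intronIndex]      # last exonic base before insertion
  if (!is.null(snv)) {
    stopifnot(!is.null(snv$c_pos), !is.null(snv$alt))
    substr(cds, snv$c_pos, snv$c_pos) <- toupper(snv$alt)
  }
  mut <- paste0(substr(cds, 1L, cl), iseq, substr(cds, cl + 1L, nchar(cds)))
  aligned <- cl %% 3L == 0L
  inFrame <- nchar(iseq) %% 3L == 0L
  if (aligned) {
    i <- cl %/% 3L
    intronAa <- .translate_dna(iseq)
    stopRank <- regexpr("*", intronAa, fixed = TRUE)
    if (stopRank > 0L) {
      code <- paste0(.aa_fmt(protv[i], letters3), i, "_",
                     .aa_fmt(protv[i + 1L], letters3), i + 1L,
                     "ins*", stopRank)
      return(.new_consequence(rCode, .wrap_pred(code, confirmed),
                              "stop_insertion", i, i + 1L,
                              fsStopRank = stopRank,
                              inFrame = inFrame, confirmed = confirmed))
    }
    if (inFrame) {
      code <- paste0(.aa_fmt(protv[i], letters3), i, "_",
                     .aa_fmt(protv[i + 1L], letters3), i + 1L,
                     "ins", .aa_fmt(intronAa, letters3))
      return(.new_consequence(rCode, .wrap_pred(code, confirmed),
                              "inframe_delins", i, i + 1L,
                              inFrame = TRUE, confirmed = confirmed))
    }
  }
  fs <- .fs_code(prot, .translate_dna(mut), confirmed, letters3)
  .new_consequence(rCode, fs$pCode, "frameshift", fs$pos, fs$pos,
                   fsStopRank = fs$rank, inFrame = inFrame,
                   confirmed = confirmed)
}

## Single-nucleotide variants ------------------------------------------------

#' Consequence of a single-nucleotide change in the CDS
#'
#' Mutates the base, retranslates the affected codon and reports missense,
#' synonymous (`p.(=)`) or stop-gain. Consequences derived without RNA
#' evidence default to the predicted, parenthesized form `p.(...)`.
#'
#' @param model a `TranscriptModel` with sequences.
#' @param cPos 1-based c.-position inside the CDS.
#' @param alt alternate base (ACGT).
#' @param confirmed FALSE (default): predicted form.
#' @param letters3 three-letter amino-acid codes (default).
#' @return a [Consequence-class].
#' @export
consequenceOfSnv <- function(model, cPos, alt, confirmed = FALSE,
                             letters3 = TRUE) {
  cds <- cdsSequence(model)
  if (!is.numeric(cPos) || cPos < 1L || cPos > nchar(cds))
    stop("transcript '", model@id, "': position c.", cPos,
         " outside the CDS (1..", nchar(cds), ")")
  alt <- toupper(alt)
  if (!alt %in% c("A", "C", "G", "T"))
    stop("alternate base must be one of A, C, G, T")
  ref <- substr(cds, cPos, cPos)
  cc <- cToCodon(cPos)
  i <- cc[["codon"]]
  codonStart <- (i - 1L) * 3L + 1L
  refCodon <- substr(cds, codonStart, codonStart + 2L)
  mutCodon <- refCodon
  substr(mutCodon, cc[["offset"]], cc[["offset"]]) <- alt
  refAa <- unname(.codon_table()[refCodon])
  mutAa <- unname(.codon_table()[mutCodon])
  rCode <- sprintf("r.%d%s>%s", cPos, .rna_base(ref), .rna_base(alt))
  if (refAa == mutAa) {
    return(.new_consequence(rCode, .wrap_pred("=", confirmed), "synonymous",
                            i, i, inFrame = TRUE, confirmed = confirmed))
  }
  if (mutAa == "*") {
    code <- paste0(.aa_fmt(refAa, letters3), i, "*")
    return(.new_consequence(rCode, .wrap_pred(code, confirmed), "stop_gain",
                            i, i, inFrame = TRUE, confirmed = confirmed))
  }
  code <- paste0(.aa_fmt(refAa, letters3), i, .aa_fmt(mutAa, letters3))
  .new_consequence(rCode, .wrap_pred(code, confirmed), "missense",
                   i, i, inFrame = TRUE, confirmed = confirmed)
}

## Bracketed multi-consequence notation --------------------------------------

#' Combine the consequences of one allele into bracketed HGVS strings
#'
#' A single consequence is returned as its bare code; several transcripts
#' from one allele are combined as `r.[a,b]` / `p.[a,b]`, preserving input
#' order (e.g. `p.[Phe313_Pro343del,Leu312_Phe313ins*18]`).
#'
#' @param consequences a list of [Consequence-class] objects (>= 1).
#' @return list with elements `r` and `p`.
#' @export
combineAlleleConsequences <- function(consequences) {
  if (length(consequences) == 0L)
    stop("at least one consequence is required")
  stopifnot(all(vapply(consequences, is, logical(1), "Consequence")))
  rs <- vapply(consequences, slot, character(1), "rCode")
  ps <- vapply(consequences, slot, character(1), "pCode")
  strip <- function(x, prefix) sub(paste0("^", prefix, "\\."), "", x)
  if (length(consequences) == 1L)
    return(list(r = rs, p = ps))
  list(r = paste0("r.[", paste(strip(rs, "r"), collapse = ","), "]"),
       p = paste0("p.[", paste(strip(ps, "p"), collapse = ","), "]"))
}
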