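#' @import methods
#' @importFrom stats aov binom.test quantile IQR rnorm rpois runif dist sd setNames
#' @importFrom utils read.table write.table packageVersion head tail
NULL

## ---------------------------------------------------------------------------
## TranscriptModel
## ---------------------------------------------------------------------------

#' TranscriptModel: a coding transcript in CDS (c.) coordinates
#'
#' Represents the exon/intron layout of one coding transcript together with
#' its sequences. All coordinates are 1-based, closed, CDS (c.) coordinates:
#' c.1 is the A of the initiator ATG and exon k+1 starts at exon k's end + 1,
#' so exon ranges tile `1..cdsLength` contiguously. Internal arithmetic uses
#' 0-based half-open offsets; every surface (constructors, accessors, HGVS
#' codes, error messages) speaks 1-based closed c.-coordinates.
#'
#' `cdsStartOffset` allows exon 1's sequence to carry that many leader bases
#' in front of the ATG; the coding sequence starts at position
#' `cdsStartOffset + 1` of the concatenated exon sequence. Exon 1's sequence
#' must then have `span + cdsStartOffset` bases; every other exon's sequence
#' length equals its span exactly. 5'/3' UTR c.-coordinates (negative, `*`)
#' are not modeled.
#'
#' @slot id transcript identifier.
#' @slot exonStarts,exonEnds integer vectors of 1-based closed c.-coordinates.
#' @slot exonSeqs character vector of exon nucleotide sequences (ACGT), or
#'   length 0 when sequences are not supplied.
#' @slot intronSeqs character vector of intron sequences; intron i lies
#'   between exon i and exon i+1. Length 0 when not supplied.
#' @slot cdsStartOffset integer, transcript bases before the A of the ATG.
#' @slot strand `"+"` or `"-"`; annotation only, all arithmetic is in
#'   transcript orientation.
#' @name TranscriptModel-class
#' @aliases TranscriptModel-class
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    id = "character",
    exonStarts = "integer",
    exonEnds = "integer",
    exonSeqs = "character",
    intronSeqs = "character",
    cdsStartOffset = "integer",
    strand = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msgs <- character(0)
  n <- length(object@exonStarts)
  if (length(object@exonEnds) != n)
    msgs <- c(msgs, "exonStarts and exonEnds must have equal length")
  if (n == 0L) msgs <- c(msgs, "at least one exon required")
  if (length(msgs) == 0L) {
    if (object@exonStarts[1L] != 1L)
      msgs <- c(msgs, "exon 1 must start at c.1")
    if (any(object@exonEnds < object@exonStarts))
      msgs <- c(msgs, "each exon must satisfy c_end >= c_start")
    if (n > 1L && any(object@exonStarts[-1L] != object@exonEnds[-n] + 1L))
      msgs <- c(msgs, "exon k+1 must start at exon k's c_end + 1")
  }
  if (length(object@cdsStartOffset) != 1L || is.na(object@cdsStartOffset) ||
      object@cdsStartOffset < 0L)
    msgs <- c(msgs, "cdsStartOffset must be a single integer >= 0")
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(object@exonSeqs) > 0L && length(msgs) == 0L) {
    if (length(object@exonSeqs) != n) {
      msgs <- c(msgs, "exonSeqs must have one sequence per exon")
    } else {
      spans <- object@exonEnds - object@exonStarts + 1L
      expect <- spans
      expect[1L] <- expect[1L] + object@cdsStartOffset
      if (any(nchar(object@exonSeqs) != expect))
        msgs <- c(msgs, "exon sequence lengths must equal exon spans (exon 1: span + cdsStartOffset)")
      if (any(grepl("[^ACGT]", object@exonSeqs)))
        msgs <- c(msgs, "exon sequences must contain only A, C, G, T")
      if (length(msgs) == 0L) {
        cds <- substr(paste(object@exonSeqs, collapse = ""),
                      object@cdsStartOffset + 1L,
                      object@cdsStartOffset + object@exonEnds[n])
        if (substr(cds, 1L, 3L) != "ATG")
          msgs <- c(msgs, "coding sequence must begin with ATG")
        else if (!grepl("\\*", .translate_dna(cds)))
          msgs <- c(msgs, "coding sequence must contain an in-frame stop codon")
      }
    }
  }
  if (length(object@intronSeqs) > 0L) {
    if (length(object@intronSeqs) != n - 1L)
      msgs <- c(msgs, "intronSeqs must have one sequence per intron (n_exons - 1)")
    if (any(grepl("[^ACGT]", object@intronSeqs)))
      msgs <- c(msgs, "intron sequences must contain only A, C, G, T")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Splice quantification containers
## ---------------------------------------------------------------------------

#' JunctionEvidence: junction counts and coverage around one splice event
#'
#' Read support for a cassette-exon / intron-retention event: counts of reads
#' spanning the upstream inclusion junction, the downstream inclusion
#' junction and the exon-skipping junction, plus mean per-base coverage of a
#' reference exon and of the candidate retained intron. `NA` marks a
#' quantity that was not measured (e.g. one-sided junction evidence).
#'
#' @slot inclusionUp,inclusionDown,skip junction-spanning read counts.
#' @slot exonCov,intronCov mean per-base coverage.
#' @slot intronLength length of the candidate retained intron in bases.
#' @slot librarySize total mapped reads (FPKM denominator).
#' @exportClass JunctionEvidence
setClass("JunctionEvidence",
  representation(
    inclusionUp = "numeric", inclusionDown = "numeric", skip = "numeric",
    exonCov = "numeric", intronCov = "numeric",
    intronLength = "numeric", librarySize = "numeric"
  ),
  prototype(exonCov = NA_real_, intronCov = NA_real_,
            intronLength = NA_real_, librarySize = NA_real_)
)

setValidity("JunctionEvidence", function(object) {
  msgs <- character(0)
  cnt <- c(object@inclusionUp, object@inclusionDown, object@skip)
  if (any(!is.na(cnt) & cnt < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (!is.na(object@intronLength) && object@intronLength <= 0)
    msgs <- c(msgs, "intronLength must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' TranscriptMixture: inferred proportions of transcript species
#'
#' Result of the equal-allele-expression / no-NMD partition: numbers of
#' normally spliced (inclusion), exon-skipping and intron-retaining
#' transcripts, with the derived PSI and species fractions. `notes` records
#' model warnings (e.g. retention clamped to zero when skip exceeds
#' inclusion).
#'
#' @exportClass TranscriptMixture
setClass("TranscriptMixture",
  representation(
    inclusionTranscripts = "numeric", skipTranscripts = "numeric",
    retentionTranscripts = "numeric", psi = "numeric",
    retentionFraction = "numeric", skipFraction = "numeric",
    notes = "character"
  ),
  prototype(notes = character(0))
)

setValidity("TranscriptMixture", function(object) {
  msgs <- character(0)
  if (object@psi < 0 || object@psi > 1) msgs <- c(msgs, "psi must lie in [0,1]")
  if (object@retentionTranscripts < 0) msgs <- c(msgs, "retention transcripts must be >= 0")
  total <- object@retentionFraction + object@skipFraction +
    object@inclusionTranscripts / (object@inclusionTranscripts +
      object@skipTranscripts + object@retentionTranscripts)
  if (abs(total - 1) > 1e-8) msgs <- c(msgs, "species fractions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' AlleleReadPartition: variant-allele reads split by splicing outcome
#'
#' @slot altReadsTotal total reads carrying the variant allele.
#' @slot altReadsSpliced,altReadsRetained reads from correctly spliced and
#'   intron-retaining transcripts of that allele.
#' @slot retainedFractionOfAlt retained / (spliced + retained).
#' @slot pBinomial two-sided binomial p against a 50:50 split.
#' @slot verdict `"about equally expressed"` when the retained fraction lies
#'   in \[1/3, 2/3\], otherwise `"unbalanced"`.
#' @exportClass AlleleReadPartition
setClass("AlleleReadPartition",
  representation(
    altReadsTotal = "numeric", altReadsSpliced = "numeric",
    altReadsRetained = "numeric", retainedFractionOfAlt = "numeric",
    pBinomial = "numeric", verdict = "character"
  )
)

setValidity("AlleleReadPartition", function(object) {
  if (object@altReadsSpliced + object@altReadsRetained > object@altReadsTotal)
    "spliced + retained must not exceed total" else TRUE
})

## ---------------------------------------------------------------------------
## HGVS consequence
## ---------------------------------------------------------------------------

#' Consequence: one RNA-level change paired with its protein-level effect
#'
#' @slot rCode HGVS r. code (e.g. `r.199_498del`).
#' @slot pCode HGVS p. code (e.g. `p.Leu67_Lys166del`); predicted-only
#'   consequences are wrapped `p.(...)`, RNA-confirmed ones are bare.
#' @slot kind one of `inframe_del`, `inframe_delins`, `frameshift`,
#'   `stop_insertion`, `missense`, `synonymous`, `stop_gain`.
#' @slot firstResidue,lastResidue affected residue range.
#' @slot deletedAaCount residues deleted (0 when not applicable).
#' @slot fsStopRank rank of the novel stop for `fs*N` / `ins*N` codes
#'   (0 when not applicable or when no downstream stop is reached).
#' @slot inFrame TRUE iff the affected nucleotide span is a multiple of 3.
#' @slot confirmed TRUE when the consequence is RNA-confirmed.
#' @exportClass Consequence
setClass("Consequence",
  representation(
    rCode = "character", pCode = "character", kind = "character",
    firstResidue = "integer", lastResidue = "integer",
    deletedAaCount = "integer", fsStopRank = "integer",
    inFrame = "logical", confirmed = "logical"
  )
)

.consequence_kinds <- c("inframe_del", "inframe_delins", "frameshift",
                        "stop_insertion", "missense", "synonymous",
                        "stop_gain")

setValidity("Consequence", function(object) {
  if (!object@kind %in% .consequence_kinds)
    paste("kind must be one of:", paste(.consequence_kinds, collapse = ", "))
  else TRUE
})

## ---------------------------------------------------------------------------
## ACMG
## ---------------------------------------------------------------------------

#' EvidenceCode: one ACMG criterion with an optional strength modifier
#'
#' @slot label criterion label, e.g. `"PVS1"`, `"PM2"`, `"BA1"`.
#' @slot baseStrength strength implied by the prefix (PVS/PS/PM/PP and
#'   BA/BS/BP).
#' @slot modifier normalized modifier (`"VS"`, `"STR"`, `"MOD"`, `"SUP"`) or
#'   `NA` when absent.
#' @slot effectiveStrength modifier if present, else baseStrength.
#' @slot direction `"pathogenic"` or `"benign"`.
#' @exportClass EvidenceCode
setClass("EvidenceCode",
  representation(
    label = "character", baseStrength = "character",
    modifier = "character", effectiveStrength = "character",
    direction = "character"
  )
)

#' Classification: combined five-tier ACMG call
#'
#' @slot tier one of `pathogenic`, `likely_pathogenic`, `uncertain`,
#'   `likely_benign`, `benign`.
#' @slot points total evidence points (point combiner; 0 for rule combiner
#'   unless also computed).
#' @slot ruleTrace data.frame of (code, points) contributions.
#' @slot conflict TRUE when pathogenic and benign rules both fired.
#' @slot combiner `"points"` or `"rules"`.
#' @exportClass Classification
setClass("Classification",
  representation(
    tier = "character", points = "numeric", ruleTrace = "data.frame",
    conflict = "logical", combiner = "character"
  ),
  prototype(conflict = FALSE, combiner = "points")
)

.acmg_tiers <- c("pathogenic", "likely_pathogenic", "uncertain",
                 "likely_benign", "benign")

setValidity("Classification", function(object) {
  if (!object@tier %in% .acmg_tiers)
    paste("tier must be one of:", paste(.acmg_tiers, collapse = ", "))
  else TRUE
})

## ---------------------------------------------------------------------------
## Missense / domain analysis
## ---------------------------------------------------------------------------

#' DomainMap: protein domain intervals
#'
#' Non-overlapping residue intervals over `1..proteinLength`; residues not
#' covered by any region belong to the implicit `"linker"` region.
#'
#' @slot proteinLength protein length in residues.
#' @slot regions data.frame with columns `name`, `first`, `last`.
#' @exportClass DomainMap
setClass("DomainMap",
  representation(proteinLength = "integer", regions = "data.frame")
)

setValidity("DomainMap", function(object) {
  msgs <- character(0)
  r <- object@regions
  if (!all(c("name", "first", "last") %in% names(r)))
    return("regions must have columns name, first, last")
  if (nrow(r)) {
    if (any(r$first < 1L) || any(r$last > object@proteinLength) ||
        any(r$first > r$last))
      msgs <- c(msgs, "regions must satisfy 1 <= first <= last <= proteinLength")
    o <- order(r$first)
    if (nrow(r) > 1L && any(r$first[o][-1L] <= r$last[o][-nrow(r)]))
      msgs <- c(msgs, "regions must not overlap")
    if (anyDuplicated(r$name)) msgs <- c(msgs, "region names must be unique")
    if ("linker" %in% r$name)
      msgs <- c(msgs, "'linker' is reserved for residues outside all regions")
  }
  if (length(msgs)) msgs else TRUE
})

#' ClusterTestResult: bootstrap test of 3D clustering of mutated residues
#'
#' Observed statistic is the mean pairwise C-alpha distance among the mutated
#' residues (Angstrom; lower = more clustered); the null resamples equal-size
#' residue sets uniformly without replacement from the resolved structure.
#' The p-value uses the +1 correction: `p = (1 + #\{null <= obs\}) / (1 + B)`.
#'
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(
    observedStat = "numeric", nullStats = "numeric", pValue = "numeric",
    nBoot = "integer", seed = "integer"
  )
)

setValidity("ClusterTestResult", function(object) {
  msgs <- character(0)
  if (object@pValue <= 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in (0, 1]")
  if (length(object@nullStats) != object@nBoot)
    msgs <- c(msgs, "nullStats must hold nBoot values")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Simulation config
## ---------------------------------------------------------------------------

#' SimulationConfig: study conditions for the synthetic-data generators
#'
#' See [simulationConfig()] for field semantics and defaults.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nExons = "integer", exonLengths = "integer", intronLengths = "integer",
    engineeredStop = "ANY",   # NULL or c(intron_index, inserted_codon_rank)
    plantedCodons = "list",   # named list: codon index -> codon string
    mixture = "list",         # per-allele named proportion vectors
    skipExon = "integer", retentionIntron = "integer",
    depth = "numeric", coverageDepth = "numeric",
    nmdSurvival = "numeric",  # survival factor for PTC species (1 = no NMD)
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (length(object@exonLengths) != object@nExons)
    msgs <- c(msgs, "exonLengths must have nExons entries")
  if (length(object@intronLengths) != object@nExons - 1L)
    msgs <- c(msgs, "intronLengths must have nExons - 1 entries")
  if (sum(object@exonLengths) %% 3L != 0L)
    msgs <- c(msgs, "total exon length must be a multiple of 3")
  if (any(object@intronLengths < 4L))
    msgs <- c(msgs, "introns need >= 4 bases (GT...AG)")
  for (al in object@mixture) {
    if (abs(sum(al) - 1) > 1e-8)
      msgs <- c(msgs, "per-allele mixture proportions must sum to 1")
    if (any(al < 0)) msgs <- c(msgs, "mixture proportions must be >= 0")
  }
  if (object@depth <= 0) msgs <- c(msgs, "depth must be > 0")
  if (object@coverageDepth <= 0) msgs <- c(msgs, "coverageDepth must be > 0")
  if (!is.null(object@engineeredStop) &&
      (length(object@engineeredStop) != 2L || any(object@engineeredStop < 1L)))
    msgs <- c(msgs, "engineeredStop must be c(intron_index, inserted_codon_rank)")
  if (length(msgs)) unique(msgs) else TRUE
})
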