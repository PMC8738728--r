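# Independent brute-force consequence oracle: rebuilds the full mutant cDNA,
# translates it codon by codon with its own loop, and classifies the effect
# from the raw translations. Shares no code with the rule-based engine.

bf_translate <- function(seq) {
  gc_tab <- Biostrings::GENETIC_CODE
  out <- character(0)
  i <- 1L
  while (i + 2L <= nchar(seq)) {
    aa <- gc_tab[[substr(seq, i, i + 2L)]]
    out <- c(out, aa)
    if (aa == "*") break
    i <- i + 3L
  }
  paste(out, collapse = "")
}

bf_cds <- function(model) {
  n <- length(model@exonEnds)
  substr(paste(model@exonSeqs, collapse = ""),
         model@cdsStartOffset + 1L, model@cdsStartOffset + model@exonEnds[n])
}

# First differing residue and rank of the first stop counting that residue
# as 1 (0 when the shifted frame never reaches a stop).
bf_fs_rank <- function(refProt, mutProt) {
  rv <- strsplit(refProt, "")[[1]]
  mv <- strsplit(mutProt, "")[[1]]
  nmin <- min(length(rv), length(mv))
  d <- which(rv[seq_len(nmin)] != mv[seq_len(nmin)])
  pos <- if (length(d)) d[1L] else nmin + 1L
  stops <- which(mv == "*")
  stops <- stops[stops >= pos]
  list(pos = pos, rank = if (length(stops)) stops[1L] - pos + 1L else 0L)
}

bf_skip <- function(model, k) {
  cds <- bf_cds(model)
  s <- model@exonStarts[k]; e <- model@exonEnds[k]
  span <- e - s + 1L
  mut <- paste0(substr(cds, 1L, s - 1L), substr(cds, e + 1L, nchar(cds)))
  refProt <- bf_translate(cds)
  mutProt <- bf_translate(mut)
  if (span %% 3L == 0L) {
    kind <- if ((s - 1L) %% 3L == 0L) "inframe_del" else "inframe_delins"
    return(list(kind = kind, rank = 0L, deleted = span %/% 3L))
  }
  fs <- bf_fs_rank(refProt, mutProt)
  # a frameshift whose first novel codon is already a stop is nonsense-style
  list(kind = "frameshift",
       rank = if (substr(mutProt, fs$pos, fs$pos) == "*") 1L else fs$rank,
       pos = fs$pos, deleted = 0L)
}

bf_retention <- function(model, j, snv = NULL) {
  cds <- bf_cds(model)
  cl <- model@exonEnds[j]
  iseq <- model@intronSeqs[j]
  if (!is.null(snv)) substr(cds, snv$c_pos, snv$c_pos) <- snv$alt
  mut <- paste0(substr(cds, 1L, cl), iseq, substr(cds, cl + 1L, nchar(cds)))
  refProt <- bf_translate(bf_cds(model))
  mutProt <- bf_translate(mut)
  if (cl %% 3L == 0L) {
    intronProt <- bf_translate(iseq)
    if (grepl("\\*", intronProt))
      return(list(kind = "stop_insertion", rank = nchar(intronProt)))
    if (nchar(iseq) %% 3L == 0L)
      return(list(kind = "inframe_delins", rank = 0L))
  }
  fs <- bf_fs_rank(refProt, mutProt)
  list(kind = "frameshift",
       rank = if (substr(mutProt, fs$pos, fs$pos) == "*") 1L else fs$rank,
       pos = fs$pos)
}

# Random toy transcript configuration for property sweeps: mixed exon spans
# (multiples and non-multiples of 3), total padded to a codon boundary.
random_toy_config <- function(seed) {
  set.seed(seed)
  nEx <- sample(4:8, 1L)
  widths <- sample(20:120, nEx, replace = TRUE)
  total <- sum(widths)
  widths[nEx] <- widths[nEx] + (3L - total %% 3L) %% 3L
  simulationConfig(nExons = nEx, exonLengths = widths,
                   intronLengths = sample(10:60, nEx - 1L, replace = TRUE),
                   skipExon = 2L, retentionIntron = 1L, seed = seed)
}
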