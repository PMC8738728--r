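# Toy transcript with the exon architecture the worked examples assume:
# 12 exons, CDS c.1..1566; exon 2 ends at c.151, exon 4 spans c.199..498,
# exon 10 ends at c.936, exon 11 spans c.937..1029. Codons relevant to the
# worked p-codes are planted (Leu67, Lys166, Pro101, Val51, Leu312, Phe313,
# Pro343); everything else is random but stop-free. Intron 10 carries an
# engineered in-frame stop at inserted codon rank 18.
pnkp_like_model <- function(seed = 1L) {
  cfg <- pnkp_like_config(seed)
  makeToyTranscript(cfg)
}

pnkp_like_config <- function(seed = 1L, ...) {
  simulationConfig(
    plantedCodons = list(
      "50" = "CAA",   # Gln50
      "51" = "GTG",   # Val51 (c.151 = G, last base of exon 2)
      "67" = "CTG",   # Leu67
      "101" = "CCA",  # Pro101
      "104" = "CTG",  # Leu104
      "166" = "AAG",  # Lys166 (c.498 = G, last base of exon 4)
      "312" = "CTG",  # Leu312
      "313" = "TTT",  # Phe313
      "343" = "CCA"), # Pro343
    engineeredStop = c(10L, 18L),
    seed = seed, ...)
}

# Domain map used in missense tests (FHA / phosphatase / kinase with linker
# gaps; boundaries are required config, chosen once for the fixtures).
fha_domain_map <- function() {
  domainMap(521L, data.frame(
    name = c("FHA", "phosphatase", "kinase"),
    first = c(6L, 145L, 341L),
    last = c(110L, 336L, 516L)))
}

# Minimal fixed-column PDB writer for reader tests (altloc / insertion-code
# corner cases included on demand).
write_mini_pdb <- function(path, records) {
  lines <- vapply(records, function(r) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
            r$serial, paste0(" ", r$name), r$alt %||% " ",
            r$res %||% "ALA", r$chain %||% "A", r$resno,
            r$icode %||% " ", r$x, r$y, r$z)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
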