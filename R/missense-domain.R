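#' @include AllClasses.R
NULL

#' Construct a DomainMap
#'
#' @param proteinLength protein length in residues.
#' @param regions data.frame with columns `name`, `first`, `last`
#'   (non-overlapping residue intervals); residues outside every region
#'   belong to the implicit `"linker"` region.
#' @export
domainMap <- function(proteinLength, regions) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  regions$first <- as.integer(regions$first)
  regions$last <- as.integer(regions$last)
  new("DomainMap", proteinLength = as.integer(proteinLength),
      regions = regions)
}

setMethod("show", "DomainMap", function(object) {
  cat("DomainMap over ", object@proteinLength, " residues\n", sep = "")
  r <- object@regions
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-12s %d..%d\n", r$name[i], r$first[i], r$last[i]))
})

#' Assign residue positions to domains
#'
#' @param position residue index (vectorized).
#' @param map a [DomainMap-class].
#' @return region name per position, `"linker"` for residues outside every
#'   region; out-of-range positions are an error.
#' @export
assignDomain <- function(position, map) {
  stopifnot(is(map, "DomainMap"))
  if (any(is.na(position)) || any(position < 1L) ||
      any(position > map@proteinLength))
    stop("positions must lie in 1..", map@proteinLength)
  r <- map@regions
  vapply(position, function(p) {
    hit <- which(r$first <= p & p <= r$last)
    if (length(hit)) r$name[hit[1L]] else "linker"
  }, character(1))
}

#' Per-domain counts, fractions and mean scores of a missense table
#'
#' @param table data.frame with columns `position` and `score` (one row per
#'   missense variant); must be non-empty.
#' @param map a [DomainMap-class].
#' @return data.frame with one row per region (named regions in map order,
#'   then `"linker"` when populated): `region`, `count`,
#'   `fraction` (denominator = all missense variants in the table) and
#'   `meanScore`.
#' @export
domainSummary <- function(table, map) {
  stopifnot(is(map, "DomainMap"))
  if (is.null(table) || nrow(table) == 0L)
    stop("missense table is empty")
  stopifnot(all(c("position", "score") %in% names(table)))
  region <- assignDomain(table$position, map)
  lev <- c(map@regions$name, if ("linker" %in% region) "linker")
  region <- factor(region, levels = lev)
  n <- nrow(table)
  out <- data.frame(
    region = lev,
    count = as.integer(table(region)[lev]),
    stringsAsFactors = FALSE)
  out$fraction <- out$count / n
  means <- tapply(table$score, region, mean)
  out$meanScore <- as.numeric(means[lev])
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of variant scores across domains
#'
#' Groups the table's scores by assigned region and fits a standard one-way
#' ANOVA. The table may hold observed variants only or an exhaustive
#' per-residue enumeration; the test treats whatever rows it is given as
#' the observations.
#'
#' @param table data.frame with `position` and `score`.
#' @param map a [DomainMap-class].
#' @param minPerRegion regions with fewer values are dropped (default 2);
#'   at least 2 regions must remain.
#' @return list with elements `F`, `p`, `df` and the fitted `aov` object.
#' @export
anovaRegions <- function(table, map, minPerRegion = 2L) {
  stopifnot(nrow(table) > 0L)
  region <- assignDomain(table$position, map)
  keep <- region %in% names(which(table(region) >= minPerRegion))
  dat <- data.frame(score = table$score[keep],
                    region = factor(region[keep]))
  if (nlevels(droplevels(dat$region)) < 2L)
    stop("need >= 2 regions with >= ", minPerRegion, " values each")
  fit <- aov(score ~ region, data = dat)
  s <- summary(fit)[[1]]
  Fval <- s[["F value"]][1L]
  pval <- s[["Pr(>F)"]][1L]
  if (is.nan(Fval)) {          # zero variance within and between groups
    Fval <- 0; pval <- 1
  }
  list(F = Fval, p = pval, df = s[["Df"]], fit = fit)
}

## 3D clustering bootstrap ---------------------------------------------------

.mean_pairwise <- function(xyz) mean(dist(xyz))

#' Bootstrap test for 3D clustering of mutated residues
#'
#' Observed statistic: mean pairwise C-alpha distance among the mutated
#' residues (Angstrom; smaller = more clustered). Null: the same statistic
#' for an equal-size sample of residues drawn uniformly without replacement
#' from all residues resolved in the structure, repeated `nBoot` times.
#' One-sided p-value with the +1 correction:
#' `p = (1 + #[null <= observed]) / (1 + nBoot)`.
#'
#' @param positions residue numbers of the mutated residues (>= 2).
#' @param coords residue coordinates: numeric matrix with 3 columns and
#'   residue numbers as rownames (see [readPdbCa()]).
#' @param nBoot number of bootstrap resamples (>= 99; default 999).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return a [ClusterTestResult-class].
#' @export
clusteringTest <- function(positions, coords, nBoot = 999L, seed = 1L) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  nBoot <- as.integer(nBoot)
  if (nBoot < 99L) stop("nBoot must be >= 99")
  if (length(positions) < 2L) stop("need >= 2 mutated positions")
  key <- as.character(positions)
  missing <- key[!key %in% rownames(coords)]
  if (length(missing))
    stop("positions without coordinates in the structure: ",
         paste(missing, collapse = ", "))
  obs <- .mean_pairwise(coords[key, , drop = FALSE])
  m <- length(positions)
  nres <- nrow(coords)
  nullStats <- .with_seed(as.integer(seed), {
    vapply(seq_len(nBoot), function(b) {
      .mean_pairwise(coords[sample.int(nres, m), , drop = FALSE])
    }, numeric(1))
  })
  new("ClusterTestResult",
      observedStat = obs, nullStats = nullStats,
      pValue = (1 + sum(nullStats <= obs)) / (1 + nBoot),
      nBoot = nBoot, seed = as.integer(seed))
}

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "Clustering bootstrap: observed mean pairwise distance %.2f A\n  null mean %.2f A (B = %d), p = %.4g (seed %d)\n",
    object@observedStat, mean(object@nullStats), object@nBoot,
    object@pValue, object@seed))
})

## PDB I/O -------------------------------------------------------------------

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one C-alpha coordinate per residue of a chain. Alternate
#' location A is preferred when present; residues with insertion codes are
#' skipped with a warning. A chain without C-alpha atoms yields an empty
#' map with a warning.
#'
#' @param path PDB file.
#' @param chain chain identifier (default `"A"`).
#' @return numeric matrix (n x 3, columns x/y/z) with residue numbers as
#'   rownames.
#' @export
readPdbCa <- function(path, chain = "A") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("chain '", chain, "' not found in '", path, "'")
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) {
    warning("chain '", chain, "' in '", path, "' has no C-alpha atoms")
    return(matrix(numeric(0), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  ins <- !is.na(ca$insert) & nzchar(ca$insert)
  if (any(ins)) {
    warning(sum(ins), " C-alpha atom(s) with insertion codes skipped")
    ca <- ca[!ins, , drop = FALSE]
  }
  # prefer altloc A, then the blank altloc, drop remaining duplicates
  alt <- ifelse(is.na(ca$alt) | !nzchar(ca$alt), "", ca$alt)
  ca <- ca[order(ca$resno, match(alt, c("A", ""), nomatch = 3L)), ,
           drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  out <- as.matrix(ca[, c("x", "y", "z")])
  rownames(out) <- ca$resno
  out
}

#' Write C-alpha coordinates as a (synthetic) PDB file
#'
#' Emits one ATOM record per residue (poly-alanine C-alpha trace), the
#' format [readPdbCa()] reads back. Intended for simulated coordinate sets.
#'
#' @param coords n x 3 matrix with residue-number rownames.
#' @param path output path.
#' @param chain chain identifier.
#' @export
writeCaPdb <- function(coords, path, chain = "A") {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  resno <- if (is.null(rownames(coords))) seq_len(nrow(coords))
           else as.integer(rownames(coords))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), chain, resno,
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
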