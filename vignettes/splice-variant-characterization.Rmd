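---
title: "Characterizing splice-disrupting variants from RNA-seq evidence"
author: "splicecraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing splice-disrupting variants from RNA-seq evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecraft)
```

## The problem

A single nucleotide change near a splice site can do several things at
once: leave a fraction of transcripts normally spliced, cause skipping of
the adjacent exon, and cause retention of the adjacent intron — all from
one allele of a heterozygous carrier. Clinical interpretation then needs
three linked analyses: *how much* of each aberrant species is present
(splice quantification), *what* each species does to the protein (HGVS
consequence derivation), and *how* the accumulated evidence combines into
a pathogenicity call (ACMG classification). For missense variants a fourth
question arises: do the affected residues cluster in 3D space on the
folded domain? splicecraft implements all four stages on explicit,
testable models, together with simulators that generate every input the
pipeline reads.

## Transcript models and coordinates

A `TranscriptModel` holds the exon/intron layout of one coding transcript
in CDS (c.) coordinates: c.1 is the A of the initiator ATG, exons tile the
CDS contiguously, and all protein arithmetic follows
`codon(c) = floor((c - 1)/3) + 1`. Internally the code works with 0-based
offsets; every surface — constructors, accessors, HGVS codes, error
messages — speaks 1-based closed c.-coordinates, the convention of the
nomenclature itself. UTR coordinates (negative and `*` positions) are not
modeled: every coordinate the analysis consumes is inside the CDS.
Minus-strand GTF input is reverse-complemented into transcript orientation
at parse time, so no downstream function ever sees strand. The GTF reader
demands an explicit `transcript_id` and refuses ambiguous or absent ids
rather than silently taking a first match.

## Splice quantification

All quantification reduces to ratio arithmetic on junction-spanning read
counts and per-base coverage:

- **PSI.** With inclusion junction counts $I_u$, $I_d$ and skip count $S$,
  $\mathrm{PSI} = I/(I+S)$ where $I = (I_u + I_d)/2$. The *mean* of the two
  inclusion junctions is used, never the sum: each inclusion transcript
  spans both junctions, so summing would count it twice. One-sided
  evidence (only one junction measurable) falls back to the single count
  and flags the result.
- **Equal-allele partition.** In a heterozygous carrier whose variant
  allele produces only skip and retention species, the wildtype allele
  contributes $I$ transcripts and the variant allele $S + R$. Assuming
  equal expression of both alleles and no nonsense-mediated decay,
  $R = \max(0, I - S)$. When $S > I$ the model is inconsistent; $R$ is
  clamped to zero and the inconsistency is recorded in the result rather
  than raised as an error, since real carriers can violate the model (for
  example through leaky splicing from the variant allele). An optional
  NMD survival factor rescales $R$ for sensitivity analysis; the default
  of 1 (no decay) is the model's stated assumption.
- **Coverage ratio.** Retention is independently estimated as intron
  coverage over reference-exon coverage. Whether the two numbers are mean
  coverages or read counts does not matter — only the ratio is used, and
  both interpretations are accepted.
- **Intron FPKM and outliers.** A simplified intron quantifier
  ($\mathrm{FPKM} = 10^9 c / (L N)$) feeds a cohort outlier rule: a sample
  is flagged iff it exceeds $Q_3 + 1.5\,\mathrm{IQR}$ of the *remaining*
  samples. The leave-one-out form prevents a single strong carrier from
  masking itself in a small cohort.
- **Allele-tagged reads.** Reads carrying a variant base can be split by
  splicing outcome; the two species are called "about equally expressed"
  when the retained fraction lies in $[\tfrac13, \tfrac23]$, and a
  two-sided binomial test against 0.5 is attached for reference.

```{r quant}
computePsi(30, 33, 24)
partitionEqualExpression(30, 33, 24)
coverageRetentionRatio(11, 69)
```

## HGVS consequence rules

Exon skipping and intron retention are rewritten as RNA codes
(`r.199_498del`, `r.936_937ins936+1_937-1`) and then translated into
protein codes by explicit rules:

- a skip whose span is divisible by 3 *and* codon-aligned deletes whole
  residues (`p.Leu67_Lys166del`);
- an in-frame but non-aligned skip additionally rebuilds one junction
  residue (`delins`);
- any other span shifts the frame; the mutant transcript is rebuilt and
  translated, and the code reports the first changed residue and the rank
  of the novel stop (`fs*N`, counting the changed residue as 1).

For retention, a codon-aligned insertion whose retained intron reaches an
in-frame stop truncates within the insertion (`ins*N`, `N` ranked inside
the inserted peptide) — this holds regardless of total intron length,
because translation never reads past the stop. Stop-free in-frame introns
insert peptide; everything else frameshifts. A single-nucleotide rider on
the same allele (e.g. a last-exon-base exchange that also weakens the
donor) can be applied before translation, which is how a mixed
missense/frameshift allele such as `p.[Val51Leu,Val51Argfs*N]` arises.
Predicted-only consequences are parenthesized `p.(...)`; RNA-confirmed
ones are bare — confirmation status is an explicit flag, never inferred.
Multiple transcripts from one allele combine as `p.[a,b]` in input order.

The rule-based path is continuously checked against a brute-force oracle
that rebuilds the complete mutant cDNA and translates it codon by codon;
the test suite sweeps 1000 random toy transcripts and requires exact
agreement of kind and stop rank.

## ACMG combination

Evidence tokens (`PVS1_STR`, `PM2_SUP`, ...) parse into a base strength
from the prefix and an effective strength from the modifier. Two
combiners are provided. The point system (supporting 1, moderate 2,
strong 4, very strong 8; benign negative; tiers at $\ge 10$, $6..9$,
$0..5$, $-6..-1$, $\le -7$) is the primary combiner because it reproduces
the five-tier outcomes of the study's variant table. The original
rule-table combiner is kept alongside, since automated tools built on it
can disagree with point-based calls; conflicts between pathogenic and
benign rules yield "uncertain" with a flag. Strengths arrive
pre-assigned: the package does not compute PVS1 downgrading or any other
evidence assignment.

## Missense domain and 3D clustering analysis

A `DomainMap` assigns residues to named domains, with uncovered residues
in an implicit linker. Per-domain counts, fractions (over all missense
variants) and mean scores summarize a variant table; a one-way ANOVA
(`stats::aov`) tests score differences across regions. The table may
contain observed variants only or an exhaustive enumeration of possible
ones — the test simply treats rows as observations, so the choice of
grouping is the caller's.

The clustering statistic is the mean pairwise C-alpha distance among
mutated residues, compared against a null built by resampling equal-sized
residue sets uniformly *without replacement* from the residues resolved in
the structure (unresolved residues have no coordinates and cannot enter
the null). The p-value uses the +1 correction,
$p = (1 + \#\{d_b \le d_{obs}\})/(1 + B)$, so $p \in (0, 1]$ and the test
is exact under the permutation null. This statistic is a deliberate,
documented stand-in for published complete-linkage clustering tools whose
internals are not specified; accordingly the package's claims are
calibration (uniform p-values under the null) and power (a planted 2 Å
cluster of 5 residues in a 30 Å sphere is detected at $p < 0.05$ in over
95% of seeds), not reproduction of any single printed p-value, which
depends on the exact deposited structure and tool internals.

## The simulators and what they do (not) show

`simulationConfig()` fixes the study conditions once:

- a 12-exon toy transcript with a 1566-bp CDS whose exon 4 spans
  c.199..498 and exon 11 spans c.937..1029 — the architecture of the
  splice events the worked examples concern;
- a two-allele mixture: wildtype allele all normal, variant allele
  splitting 24 : 7.5 between exon skipping and intron retention (pooled
  fractions 0.5 / 0.381 / 0.119, matching the worked partition);
- junction depth 63 (so expected inclusion/skip counts sit near the
  observed 30/33 and 24) and per-base exon coverage 69;
- Poisson sampling for counts and coverage. The underlying model is
  deterministic ratio arithmetic, so a one-parameter noise law suffices
  for recovery tests; an overdispersion extension would only widen the
  Monte-Carlo bands. No NMD by default, with a survival-factor hook.

Inclusion junctions draw only from the fully normally spliced species,
mirroring the partition model's accounting in which mean inclusion counts
the wildtype-allele transcripts; a retention transcript contributes
intronic coverage, not inclusion-junction reads at the event-local window.
Intron sequences carry canonical GT..AG ends, and an engineered-stop
constructor can force the retained-intron reading frame to hit its first
stop at a chosen inserted-codon rank (rank $\ge 2$; rank 1 is impossible
since the GT donor dinucleotide never opens a stop codon). Every
generator is a pure function of (config, seed) and returns ground truth
alongside the observations.

What passing tests show: the estimators invert the generative model they
assume (mean PSI error < 0.02 and retention error < 0.03 at depth 2000
over 200 replicates), the consequence rules agree with brute-force
translation, and the clustering test is calibrated. What they do not
show: robustness to mappability artifacts, overdispersed biological
replicates, partial NMD, or allele-specific library biases — none of
which the generators emulate.

## Numerical and design choices

- Problem sizes in the routine test run are chosen to keep the full suite
  under a minute while leaving Monte-Carlo margins wide: 200 replicates
  for recovery, 500 seeds for calibration, 1000 transcripts for the
  oracle sweep.
- `retentionOutlier` requires $\ge 3$ samples; the box-plot rule is
  meaningless below that.
- All-zero junction counts make PSI undefined and raise an error — a
  silent 0 would fabricate full skipping.
- Bootstrap p-values are never 0 by construction (+1 correction), and
  `clusteringTest` refuses `B < 99`.
- Seeded RNG is handled with a local save/restore, so library calls never
  perturb a caller's random stream.
- Domain boundaries are required configuration: published domain
  annotations are database-versioned, so none are baked in.
- The five-tier point thresholds and the rule table are both fixed
  constants of the classification systems, not tunables; accepted
  modifier dialects (`_SUP`/`_P`, `_MOD`/`_M`, `_STR`/`_S`, `_VS`) are
  normalized at parse because case literature mixes them.

## Limitations

The package quantifies events it is pointed at; it does not discover
aberrant junctions genome-wide, align reads, call variants, or predict
which aberrant transcript dominates beyond the equal-allele model.
Protein-level predictions stop at the HGVS code: no stability (ΔΔG),
steric, or conservation modeling is attempted, and external scores such
as CADD are treated purely as numeric inputs.
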