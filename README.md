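# splicecraft

Characterization of splice-disrupting and missense variants from RNA-seq
evidence, for clinical-genetics analysts who need to turn junction counts,
coverage profiles, evidence codes and structures into reproducible
per-variant calls.

A variant near a splice site in a heterozygous carrier can produce a
mixture of transcript species — normal splicing, exon skipping, intron
retention — all from one allele. splicecraft implements the four linked
analyses this situation requires:

1. **Splice quantification.** Percent spliced in from junction reads,
   `PSI = I/(I + S)` with `I` the *mean* of the two inclusion-junction
   counts; an equal-allele-expression, no-NMD partition that sizes the
   retention species as `R = max(0, I − S)`; an independent intron/exon
   coverage-ratio estimate of retention; a simplified intron FPKM
   (`10⁹·c/(L·N)`) with a leave-one-out box-plot outlier rule
   (`> Q3 + 1.5·IQR` of the remaining cohort); and an allele-tagged read
   partition with an equality verdict.
2. **HGVS consequences.** RNA (`r.199_498del`,
   `r.936_937ins936+1_937-1`) and protein codes for exon skips
   (`p.Leu67_Lys166del`), intron retentions (`p.Leu312_Phe313ins*18`,
   `p.Val51Argfs*N`) and SNVs (`p.(Pro101Leu)`, `p.(=)`), with bracketed
   multi-transcript alleles (`p.[a,b]`), all validated against a
   brute-force rebuild-and-translate oracle.
3. **ACMG classification.** Evidence tokens with strength modifiers
   (`PVS1_STR`, `PM2_SUP`, ...) combined by the point system
   (1/2/4/8, tiers at ≥10 / 6–9 / 0–5 / −6..−1 / ≤−7) and, in parallel,
   by the original combining-rule table.
4. **Missense domain & 3D clustering.** Per-domain counts/fractions/mean
   scores, one-way ANOVA across regions, and a bootstrap clustering test:
   observed mean pairwise Cα distance among mutated residues versus
   equal-size uniform resamples of resolved residues,
   `p = (1 + #{null ≤ obs})/(1 + B)`.

A synthetic-data module generates everything the pipeline reads — toy
coding transcripts (with optional engineered in-frame stops in retained
introns), STAR `SJ.out.tab` junction files, bedGraph coverage, GTF+FASTA
transcript models, missense tables and Cα PDB files — returning ground
truth alongside the observations.

## Worked example

The junction counts 30 and 33 (inclusion) and 24 (skip) around a cassette
exon, with coverage 69 over the reference exon and 11 over the candidate
intron:

```r
library(splicecraft)

computePsi(30, 33, 24)
#> [1] 0.5675676
```

56.8% of transcripts at this event include the exon. Under equal allele
expression without NMD, the wildtype allele accounts for the 31.5
inclusion transcripts, so the variant allele's 24 skip transcripts leave
7.5 transcripts to the retention species:

```r
partitionEqualExpression(30, 33, 24)
#> TranscriptMixture: I = 31.5, S = 24, R = 7.5
#>   PSI = 0.568, skip fraction = 0.381, retention fraction = 0.119

coverageRetentionRatio(11, 69)
#> [1] 0.1594203
```

The coverage profile independently estimates ~15.9% retention, consistent
with the partition's 11.9%. The same allele's two aberrant species map to
protein consequences and the evidence combines into a tier:

```r
cfg <- simulationConfig(
  plantedCodons = list("312" = "CTG", "313" = "TTT", "343" = "CCA"),
  engineeredStop = c(10L, 18L), seed = 1L)
model <- makeToyTranscript(cfg)

combineAlleleConsequences(list(consequenceOfSkip(model, 11L),
                               consequenceOfRetention(model, 10L)))
#> $r
#> [1] "r.[937_1029del,936_937ins936+1_937-1]"
#> $p
#> [1] "p.[Phe313_Pro343del,Leu312_Phe313ins*18]"

classifyPoints(parseEvidenceList("PVS1_STR; PM3_SUP; PS4_MOD; PM2_SUP"))
#> ACMG classification (points combiner): likely_pathogenic [8 points]
#>   PVS1_STR(+4) PM3_SUP(+1) PS4_MOD(+2) PM2_SUP(+1)
```

So the exon-11 skip deletes 31 residues in frame, the intron-10 retention
truncates 18 codons into the insertion, and the combined evidence reaches
likely pathogenic with 8 points. Spatial clustering on a structure:

```r
coords <- simulateStructure(110L,
  plantedCluster = list(center = c(0, 0, 0), radius = 2,
                        members = c(50, 51, 55, 66, 101, 104)),
  seed = 5L)
clusteringTest(c(50, 51, 55, 66, 101, 104), coords, nBoot = 999L, seed = 7L)
#> Clustering bootstrap: observed mean pairwise distance 1.83 A
#>   null mean 30.40 A (B = 999), p = 0.001 (seed 7)
```

A command-line wrapper (`inst/scripts/splicecraft`) exposes the stages as
subcommands (`simulate`, `quantify`, `consequence`, `classify`,
`cluster`, `all`) driven by one YAML config per run; every JSON report
embeds the config hash, seed and package version.

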