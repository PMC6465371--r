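---
title: "Detecting premature cleavage and polyadenylation: models and methods"
author: "pcpatools"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Detecting premature cleavage and polyadenylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pcpatools` detects premature cleavage and polyadenylation (PCPA) — early
transcription termination at cryptic intronic poly(A) sites — from two data
types: nascent-RNA coverage (TT-seq-style, strand-specific bedGraph tracks
with spike-ins) and poly(A) 3′-end sequencing peak candidates with
per-sample read counts. Alignment, peak calling and transcript
quantification are upstream of the package: coverage arrives as bedGraph,
peaks as a BED-like table, abundances as a TPM table. This vignette
explains the models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where several readings were defensible.

# The annotation model

Analysis operates on a *reduced* per-gene model: transcripts surviving the
abundance filter (gene TPM ≥ 2; transcript fraction ≥ 0.2 of the gene's
TPM unless the transcript's own TPM exceeds 5) are merged so that a gene is
a single span of merged exons with complementary introns. Coordinates are
held in `GRanges` (1-based, closed) throughout: the GTF/BED/bedGraph
conversions are then exactly the ones `rtracklayer` performs, and all
interval arithmetic (reduce, gaps, subtract, overlap) is delegated to
`GenomicRanges` rather than re-derived.

Protein-coding genes are stratified into quartiles of the length
distribution, with the shortest quartile further split at its 0.33/0.66
quantiles (six classes from `ultra_short` to `long`). Quantiles are type-7;
genes exactly on a boundary take the lower class. The boundaries are always
recomputed from the data at hand and reported alongside the labels —
published cut points (e.g. 9.9/26.4/64.5 kb) arise from a specific dataset
and are reproduced only given that dataset. Non-coding biotypes with at
least 20 members are split into long vs short non-coding by k-means (k = 2)
on log10 length. We run Lloyd's algorithm from fixed quantile centers,
which makes the split deterministic and invariant to gene order; the
cluster with the larger centroid is `long_noncoding`.

The representative isoform per gene is the transcript with the highest
3′UTR-assigned poly(A) read sum; ties fall back to the longer transcript,
then the lexicographically smaller identifier, so the choice is total and
reproducible.

# Coverage normalization and profiles

Spike-in size factors use the median-of-ratios construction: each sample's
factor is the median over spike-in species of its count divided by the
species' geometric mean across samples, using only species with positive
counts everywhere (a pseudocount option rescues degenerate tables).
Binning aggregates bedGraph signal by interval-length-weighted sums (value
= weighted sum / bin width / size factor), 100 bp for TT-seq and 50 bp for
3′-seq; a per-million scaling against the track's own signal mass is
optional so that raw integer read counts remain available for the count
tests below.

Metagene profiles resample each gene body (TSS→TES) into 50 equal bins by
area-weighted aggregation — robust for genes not divisible by 50 — with 2 kb
flanks in 100 bp bins; profiles are strand-aware (bin 1 at the TSS on both
strands), the sense curve uses the track matching the gene's strand and
the antisense curve the opposite one. Genes are averaged with equal weight
(expression weighting would let a few high expressors dominate the shape;
the flag is a config choice, not a separate code path). Genes overlapping
another gene's flank are kept by default.

TSS-proximal dynamics are computed in 50 bp bins over −500..+10000 bp of
the TSS: the *change* is the across-gene mean of treated-minus-control
density per bin; the *rate* is its first difference, linearly rescaled to
the range of the change values so that the two curves share one axis; loess
(span 0.2, degree 2) smooths both for presentation only — no decision in
the pipeline consumes the smoothed curves.

# Poly(A) peak filtering and annotation

A candidate peak is tested for (1) any of the 12 PAS hexamers (AATAAA,
ATTAAA, AGTAAA, TATAAA, AATATA, AATACA, CATAAA, GATAAA, AATGAA, ACTAAA,
AAGAAA, AATAGA) in the 100 bp window upstream of the cleavage base and (2)
a genomic A-stretch — any 25-mer with ≥ 22 adenines, i.e. up to 3
mismatches — in the 50 bp window downstream. Both windows are taken in the
transcript-sense direction of the peak's strand (on the minus strand the
upstream window lies at higher coordinates and a reference T-run reads as
an A-stretch), and are clipped at sequence ends; a window shorter than 25
bp cannot host an A-stretch. Peaks with an A-stretch but no PAS are
internal-priming artifacts (oligo-dT priming on genomic A-tracts) and are
removed; any PAS match protects a peak regardless of downstream content.
All 12 motifs are scanned and the first match in the order printed above is
recorded; since removal only depends on *any* match, the order is cosmetic.

Retained peaks are annotated hierarchically: first against strand-aware TES
windows (−200 bp upstream to +600 bp downstream of the TES along the
transcription direction) as `tes_utr`; remaining peaks overlapping a gene
become `exon` or `intron` by the reduced model; the rest are `intergenic`.
Overlap conflicts resolve protein-coding first, then longer gene, then
identifier. Condition-specific peaks require a −log10 q-score ≥ 5, a
log-ratio log2((a+1)/(b+1)) beyond ±1, and at least 64 reads — interpreted
as the *combined* count of the two compared samples (a per-sample reading
is available behind a flag).

# Per-gene scores

The intron-retention index is IR = log2[(intron ratio)/(exon ratio)] with
each ratio (treated + 1)/(control + 1) over the gene's reduced intronic or
exonic territory. "Coverage" here means summed integer read counts — the
Fisher's exact test on the 2×2 exon/intron × treated/control table requires
them. Genes qualify when either condition has ≥ 10 exonic and ≥ 5 intronic
reads; the two thresholds are paired within a condition. Retention (IR > 1)
or loss (IR < −1) additionally requires a BH-adjusted p < 0.05. BH is used
wherever an adjusted p-value appears in the package.

PCPA calls combine the exon-score (last-exon minus first-exon log2 fold
change) and the iQ-score (treated log2 ratio of the first to the last
quarter of the internal region between the first 5′ splice site and the
last 3′ splice site, quarters measured on the genomic span including
introns, strand-aware). A +1 pseudocount keeps both scores defined at zero
coverage; it can be disabled, in which case the scores are the raw log
ratios. A gene is PCPA when exon-score < −1 *and* iQ-score > 1; single-exon
genes are not assessable. iQ counts use raw treated reads — the score is a
within-sample contrast, so normalization cancels to first order.

Usage odds ratios per expressed gene (TPM > 1) compare intronic vs 3′UTR
poly(A) read sums across conditions with a Haldane–Anscombe 0.5 correction;
genes with zero intronic reads in both conditions are excluded. The OR is
defined as the treated intronic:UTR odds over the control odds (the
alternative per-sample odds reading is available by calling the function
once per sample); distributions from two contrasts are compared with a
two-sample Kolmogorov–Smirnov test on the log scale.

Differential expression is a deliberately simple negative-binomial Wald
test: per-gene method-of-moments dispersion pooled within conditions and
stabilized toward the cohort median (two replicates give noisy per-gene
estimates), a delta-method standard error on the log2 fold change, and BH
adjustment. Significance requires |log2 FC| > 1 and adjusted p < 0.1; genes
below 10 summed raw reads are reported untested and not significant. The
package validates this engine by recovery on simulated truth, not by
equality with any external implementation.

The gene-set z-score compares a set's mean expression change against the
means of 1000 random equal-sized sets drawn without replacement; the seed
is recorded in the result.

# Determinants and splice-site conservation

Per gene, along the sense strand from TSS to TES: overlapping occurrences
of the U1-binding motifs GGTGAG, GGTAAG, GTGAGT; occurrences of the
canonical PAS AATAAA; the GC fraction; plus first-intron length, intron
count, control-condition TPM (the expression determinant), and the count of
annotated intronic poly(A) peaks. The U1/PAS ratio is (U1 + 1)/(PAS + 1) so
motif-free genes stay finite. Group comparisons (all genes vs PCPA genes)
use the two-sided Wilcoxon rank-sum test and Cohen's d with pooled,
Bessel-corrected SD; d is positive when the determinant is larger in PCPA
genes, and results carry a small-sample flag below 10 group members.

The intronic-site-vs-length relationship is a degree-2 polynomial least
squares fit (raw coefficients, so they are directly interpretable), fitted
on all genes and on a gene set of interest; the per-gene difference of
predictions is tested with a Wilcoxon signed-rank test.

Splice-site PWMs are built from all canonical GT..AG introns: a 9-mer donor
window (3 exonic + 6 intronic bases — the field's standard 5′ss window,
anchored so intron +1/+2 are G/T) and the 15-mer ending at the intron's
last base for the acceptor. Column frequencies carry a 0.5 pseudocount per
base and sum to one. Scores are log2 odds against a uniform 0.25 background
(the standard PWM score; the reference never states a scoring function),
summed over both windows; introns shorter than 24 bp are excluded so the
windows cannot overlap.

# The synthetic-data generator

The generator builds a single chromosome (`chrS`) of 2–12-exon genes with
canonical splice sites, separated by 2 kb spacers (so flanking-window logic
is exercised), with log-normal lengths (median 4 kb, clamped to 1.5–30 kb,
on a 50 bp grid so bin arithmetic is exact). Defaults describe the study
conditions used throughout the tests: 200 genes; half of the longer
protein-coding genes carry a truncation at an intronic poly(A) site within
the first four introns with 10% of coverage surviving downstream; 40% of
the shorter half carry 4× intron retention or loss; 15% of the remainder a
−2 log2 fold change; treated samples gain a Gaussian 5′-proximal signal
(amplitude 2× the local rate, center +1000 bp, width 300 bp); 50
internal-priming decoys sit in spacers over planted ≥22A/25 bp runs with
PAS motifs scrubbed from their upstream windows. Truncated genes are built
with more intronic PAS hexamers, fewer U1 motifs and lower GC, and their
poly(A)-carrying introns get noisier splice sites — so determinant and
conservation analyses have planted signs to recover. Coverage noise is
Poisson per 50 bp chunk; poly(A) counts are multinomial allocations of
Poisson gene totals; spike-ins are Poisson around log-normal abundances
multiplied by the per-sample scaling. Two replicates per condition are
independent draws from one expectation.

The 5′ accumulation is *multiplicative* in the local rate: polymerase
density scales with the gene's own transcription, which preserves the
exon/intron balance (an additive gain would imprint spurious intron
retention near the TSS) and keeps planted expression changes recoverable.

What the generator does not emulate: mappability and GC bias, read-level
errors, overlapping genes and antisense transcription, 3′UTR extension
phenotypes, isoform mixtures (one transcript per gene), or biological
replicate variability beyond counting noise. Passing tests therefore show
that the statistics recover the effects they were designed for under clean
count noise at realistic depth — not that the pipeline is robust to every
artifact of real libraries.

Truncation and intron-retention calls interact by construction: a truncated
gene genuinely loses 3′ exonic coverage while its 5′ introns stay covered,
which shifts its IR index upward. This is a property of the biology being
modeled, not a defect; the intron-retention recovery checks therefore run
on cohorts without planted truncations.

# Numerical and design choices

- Degenerate inputs: constant tracks yield NA correlations; equal-length
  distributions put all genes in one class without error; motif-free genes
  get pseudocounted ratios; empty PCPA sets skip the determinant
  comparison; all such paths are tested.
- Fisher tests run only on genes passing the coverage minimum, and BH
  adjustment is computed across exactly the tested set.
- The pipeline recomputes every stage on each run: at the problem sizes the
  package targets (hundreds of genes, a few Mb of sequence) a full run
  takes on the order of a minute, and byte-identical determinism for a
  fixed config and seed makes stage caching unnecessary; the run log
  records thresholds, seeds and input checksums instead.
- Problem sizes in the shipped checks: the main simulated cohort is 200
  genes with 50 truncations and 50 decoy peaks; focused cohorts of 120–150
  genes isolate intron retention, dynamics localization and null
  calibration; calibration uses 100 z-score replicates of 1000-draw (tests:
  200-draw) permutation nulls.
- The command-line surface is the R API plus a thin wrapper
  (`inst/scripts/pcpa-pipeline.R`); an analysis package of this kind is
  driven from R scripts, so subcommand plumbing would duplicate
  `run_pipeline()`.

# Known limitations

The DE engine's dispersion moderation is a simple median blend — adequate
for recovery at the simulated depths, not a replacement for shrinkage
estimators on real data. The iQ region uses genomic quarters including
introns; for genes with extremely unbalanced intron placement the quarters
can cover very different exonic content. The internal-priming filter
inspects only the canonical 12-hexamer vocabulary and a fixed A-stretch
rule; organisms with divergent PAS usage need different motif sets (a
function argument). Finally, acceptance-style recovery rates are measured
on synthetic data; on real libraries, thresholds (notably the 64-read
minimum and the q-score cut) should be revisited against library depth.
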