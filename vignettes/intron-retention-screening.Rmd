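---
title: "Intron retention screening with IRscreen: models, parameters and design choices"
author: "IRscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron retention screening with IRscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IRscreen)
```

# Scope

`IRscreen` quantifies intron retention (IR) from spliced RNA-seq
alignments, counts per-sample IR events under cohort-level filters, calls
differentially retained introns (dIRs) between two sample groups by beta
regression, screens expression for IR-correlated and group-exclusive
genes, and tests RNA-binding-protein (RBP) motif enrichment in splice-site
flanking sequence. A synthetic-data generator produces genomes,
annotations, alignments, count matrices and planted motifs with recorded
ground truth, which is what the package's tests run against. This
vignette documents the models, every tunable parameter that matters, the
numerical choices, and what the generator does and does not emulate.

# Intron reference

Gene models come from an Ensembl-dialect GTF (`parseGTF`). Introns are the
gaps between consecutive exons of each transcript, pooled per gene
(union-consensus): introns contributed identically by several transcripts
are emitted once, and an intron overlapping *any* exon of its own gene is
excluded, since reads there cannot be attributed unambiguously to
retention. Annotation does not say which transcript set "defines" the
introns of a multi-isoform gene; union-consensus is this package's choice,
and constitutiveness of the flanking exons is enforced downstream,
empirically, by the SL/SR balance filter rather than by annotation. When
transcripts disagree on flank boundaries the *shortest* flanking exons are
recorded — a deterministic, conservative choice that matters only for
motif-region extraction. An intron with identical coordinates in two
overlapping genes is dropped entirely (cross-gene read misassignment).

Coordinates: GTF is 1-based inclusive on disk; in memory the reference is
an ordinary `GRanges` (1-based closed, the Bioconductor convention), and
BED output/intron identifiers use 0-based half-open coordinates, so
`chr1:100-200:+:g1` names the 100 bases after position 100. The BED writer
emits BED6 plus two extra columns carrying the outer flank boundaries so
the reference round-trips losslessly; BED consumers ignore the extras.

# Quantification model

For every intron and sample, `collectAlignments` computes:

* **ID** — the median per-base read depth over the whole intron, from
  aligned (M/`=`/X) CIGAR segments only; N gaps and deletions contribute
  no depth. The whole intron is used, with no edge trimming — a trimmed
  variant would discount spurious edge coverage but also genuine
  retention signal, and the untrimmed definition matches the metric as
  stated.
* **coverage** — the fraction of intronic positions with depth ≥ 1.
* **SL / SR** — junction (N-gap) reads anchored at the intron boundary
  whose far end lands in an exon of the same gene. "Left/right" is
  transcript 5′/3′: on minus-strand genes the genomic counters swap. An
  exact junction read (gap equal to the intron) counts towards SE *and*
  both SL and SR, because its two ends satisfy both flank definitions;
  the balance filter SL/SR is unaffected by this convention.
* **SE** — reads whose N gap matches the intron exactly.
* **IR ratio** — `ID / (ID + max(SL, SR))`, defined as 0 when both terms
  are 0.

Depth counts *reads*, not fragments: overlapping mates of a pair would be
double-counted, which is why the simulator is single-end. Duplicate,
secondary, supplementary and unmapped records are skipped by flag. SAM
input is converted to BAM on the fly via `Rsamtools`.

# Cohort filters and IR events

Four rules decide which introns are measurable in a cohort
(`applyCohortFilters`, thresholds in `filterParams`):

| rule | per-sample predicate | aggregation | default |
|---|---|---|---|
| balance | 0.7 ≤ SL/SR ≤ 1.3 (inclusive) | ≥ 50% of all samples | window [0.7, 1.3] |
| junction support | SL + SR > 10 (strict) | ≥ 50% of all samples | 10 |
| coverage | coverage > 0.5 (strict) | ≥ 50% of all samples | 0.5 |
| IR floor | IR ratio > 0.05 (strict) | ≥ 50% of at least one group | 0.05 |

The balance rule's cohort aggregation is not dictated by the per-sample
window itself; requiring it in ≥ 50% of samples mirrors the other rules
and is this package's choice. A sample with SR = 0 fails the balance
predicate — missing evidence is not passing evidence. Group labels beyond
normal/cancer are allowed; the IR-floor rule then needs ≥ 50% within at
least one designated group. An **IR event** is a filter-passing intron
with IR ratio strictly above 0.1 in that sample (`countIREvents`);
read-depth QC (`sampleQC`, default 40 million aligned reads, inclusive)
screens samples first. All strict/inclusive boundaries above are
deliberate and tested at their boundary values.

# Differential retention

Per intron, IR ratios across samples are modelled as beta-distributed
with logit mean link and constant precision:
logit(μ) = β₀ + β₁·group, shapes (μφ, (1−μ)φ). Observed ratios can sit at
0 or 1, where the beta density is undefined, so values are squeezed by
(y·(n−1) + 0.5)/n with n the number of samples — the standard proportion
transform, applied per intron. Fitting (`fitBetaRegression`) is BFGS on
(β₀, β₁, log φ) from moment-based starts (logits of the group means; φ
from the pooled variance via var = μ(1−μ)/(1+φ)), with one restart from a
perturbed start; the standard error of β₁ comes from the inverse numeric
Hessian (observed information) at the optimum. Inference is a two-sided
Wald test on β₁ — the default coefficient test of standard
beta-regression software, chosen over a likelihood-ratio test for that
reason — with Benjamini–Hochberg FDR across introns (`bhAdjust`, a
validated front end to `stats::p.adjust`). A non-converged fit reports
p = 1 rather than propagating an unstable estimate.

A dIR call (`callDIR`) requires |ΔIR| > 0.1 **and** q < 0.05, both
strict; ΔIR is the difference of *raw* group mean IR ratios (cancer −
normal), not model-fitted means, so the effect size is on the directly
interpretable scale. Only mask-passing introns are fitted when a mask is
supplied: filters exist to remove introns whose ratios are not
trustworthy, and fitting them anyway would only spend FDR budget. At
n = 20 per group the Wald test runs slightly hot (empirical type-I error
around 0.05–0.07 at nominal 0.05 in the package's own calibration runs) —
a known small-sample property of ML beta regression; the FDR step and the
ΔIR rule make the final calls robust to it.

For two-replicate designs the exact Audic–Claverie test is provided:
P(Y = y | x) = (N₂/N₁)^y (x+y)! / (x! y! (1+N₂/N₁)^{x+y+1}), computed in
log space with exactly summed tails; the two-sided p doubles the smaller
of P(Y ≤ y) and P(Y ≥ y), capped at 1. The test's classical formulation
is one-sided and does not fix a two-sidedness convention;
doubled-smaller-tail is chosen and documented here. Note this convention
is *not* symmetric under
swapping (x, N₁) with (y, N₂); what is exactly symmetric is the
complement identity P(Y ≤ y | x) + P(X ≤ x | y) = 1, which the tests
assert.

# Expression screens

Size factors are median-of-ratios over genes positive in all samples,
rescaled to unit geometric mean (`computeSizeFactors`; cross-checked in
the test suite against DESeq2's implementation). Log₂ fold changes use
normalised group means with a pseudocount of 1. Gene screening keeps
genes with mean raw count strictly above 10. Cohort-exclusive
differential genes are the reference condition's DE set minus the union
of all other conditions' sets, and each gene's specificity z-score is
(lfc_ref − mean)/sd over *all* conditions including the reference, with
the sample (n−1) standard deviation — including the reference is the
self-consistent reading of "z-score using the reference fold change as
the scored value"; an `excludeReference` switch provides the alternative.
Zero cross-condition variance yields z = 0 with a warning.

The IR-correlation screen is Pearson on log₁₀(x+1) of event counts vs
normalised counts — the log–log scale is the one on which the association
is plotted and approximately linear; the pseudocount handles zeros and
its effect vanishes at realistic counts. Extreme sets take the
ceiling(5%·n) most positive and most negative coefficients with ties
broken by gene id, so selections are reproducible.

# Motif enrichment

RBP motifs are read from MEME minimal or ATtRACT-style tab files into
probability matrices (columns A, C, G, T; U mapped to T) regularised by a
pseudocount (default 10⁻³) so log-odds scores are finite. Flank regions
(`extractFlanks`) are, per intron, the last 50 nt of the 5′ exon, first
50 nt of the intron, last 50 nt of the intron and first 50 nt of the 3′
exon, all in transcript orientation (minus-strand windows are mirrored
and reverse-complemented) — 100 nt of sequence per splice site, split
evenly across the exonic and intronic side; the width is configurable.
Short exons/introns yield truncated, flagged regions.

Scoring is log₂-odds against an i.i.d. background; N scores 0. The score
threshold is calibrated from the *exact* distribution of the score of a
background window, computed by dynamic programming over scores
discretised to 0.01-bit bins (per position, then convolved): the
threshold is the smallest score whose background tail probability is ≤
the target (default 10⁻⁴, the conventional motif-scanning significance
level; configurable, and documented here as an assumption of this
package). Because binning is per position, a window in the qualifying bin
can have a raw score up to L·binWidth/2 below the bin centre; the
returned threshold subtracts exactly that slack, so discretisation can
only admit borderline windows, never miss qualifying ones. A degenerate
consequence worth knowing: a near-consensus PWM of length L has maximum
score mass 4⁻ᴸ, so for L ≤ 6 even the consensus window cannot reach a
10⁻⁴ tail and the calibrated threshold correctly excludes everything.

Scanning (`scanRegion`) is sense-strand only, step 1: RBP motifs bind
RNA, so the antisense orientation is biologically meaningless here and a
default two-strand DNA scan would be wrong. Enrichment
(`regionEnrichment`) compares per-sequence hit counts between dIR-class
and non-dIR introns by a pooled-variance two-sample Student's t test;
"frequency" is hits per sequence, with a presence/absence mode behind
`binary = TRUE`. If both groups are constant: equal means give t = 0,
p = 1; different means are reported as p = 0 with an explicit
`degenerate` flag instead of a division-by-zero crash.

# The synthetic-data generator

`simulateGenome` emits one contig per gene (uniform i.i.d. sequence,
alternating +/− gene strands to exercise orientation handling) with a
regular exon/intron structure; defaults are 150 bp exons, 300 bp introns,
75 bp reads — compact but realistic enough that junction anchors,
flanking windows and depth statistics behave as in real data.
`simulateSampleReads` draws, per intron, a sample-level retention π from
a beta distribution with mean θ (the group truth) and precision `phiSim`,
then a Poisson(depth) number of junction-region fragments; each fragment
is unspliced with probability π. An unspliced fragment produces a single
M read covering the whole intron, so intronic depth equals the unspliced
count exactly and the downstream IR ratio is the binomial proportion of
unspliced fragments — a closed-form link between π and the estimate that
the consistency tests exploit (the estimate falls within three binomial
standard errors of π for ≥ 95% of introns at depth 500). A spliced
fragment produces one read whose N gap matches the intron, anchored half
a read length into each flanking exon. Cohort defaults are 20 + 20
samples with 5% retention floors and 0.1/0.2 event/effect thresholds
matching the analysis defaults. Library-size variation in the expression
simulator is log-normal with sd 0.3 — mild, realistic, and sufficient to
make size-factor recovery testable; expression counts are negative
binomial (size 20) with planted genes coupled to the standardised log₁₀
event count. `plantMotifs` writes a consensus at a uniform offset inside
a named flank region for a Bernoulli-selected subset of each intron
class, reverse-complementing into minus-strand genomes.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: partially spliced reads and recursive
splicing, GC and positional coverage bias, isoform complexity and
overlapping genes, paired-end mate overlap, sequencing error, alignment
artefacts, and mappability gaps. The generator validates the pipeline's
*logic* (counting, filtering, inference, calibration), not the biology of
any particular cohort.

# Determinism and problem sizes

Every generator is a pure function of (design, seed): RNG state is saved
and restored around each draw, per-sample seeds derive deterministically
from the design seed, and all outputs are plain text written with fixed
formatting, so a design and seed reproduce outputs byte for byte — the
end-to-end determinism test runs the full pipeline twice and compares
files. The test suite sizes its simulations to be informative yet quick:
50 introns at depth 500 for quantification fidelity, ~1000 reads for the
exhaustive counter oracle, 1000 introns at n = 20–30/group for
calibration and recovery, all-4ᴸ enumeration up to L = 8 for the PWM
distribution, and 100 sequences per class for motif enrichment. These
sizes were chosen as the smallest at which the binomial/asymptotic bounds
being asserted are comfortably informative.

# Known limitations

* The beta regression models constant precision and a single binary
  covariate; purity, batch or subtype covariates and variable-φ models
  are out of scope.
* The quantifier implements the six junction-anchored metrics only, not
  the full battery of auxiliary IR-detection parameters (mappability
  exclusions, trimmed depth variants) used by full-scale IR callers.
* Multi-mapping rescue and stranded-library inference are not attempted;
  alignments are trusted as given.
* The DE test behind the exclusivity screen is consumed as gene sets (or
  LFC-only screens); dispersion-based NB inference belongs to dedicated
  tools and is deliberately not reimplemented.
* Whole-scan q-values for motif hits, position-specific priors and
  higher-order background models are not provided.
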