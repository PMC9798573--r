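# IRscreen

Intron retention (IR) — an intron surviving splicing into the mature
transcript — is a regulated splicing outcome that is broadly dysregulated in
cancer, and breast tissue is a striking special case: normal breast has
unusually high IR, so tumours show an apparent *reduction* relative to their
matched normal tissue. Studying that pattern in patient cohorts requires a
reproducible path from spliced alignments to differential-retention calls.
`IRscreen` implements that path as a tested R/Bioconductor-style package for
transcriptomics researchers: intron-level quantification from SAM/BAM,
cohort-level event filtering, beta-regression differential retention,
expression screens for IR correlates and cohort-exclusive genes, and
RNA-binding-protein (RBP) motif enrichment around splice sites — plus a
synthetic-data generator with known ground truth, so every stage is testable
without access to protected patient data.

## The metrics and model

For each intron and sample, junction-anchored metrics are computed from the
spliced alignments:

- **ID** (intron depth): median per-nucleotide read depth across the intron;
- **coverage**: fraction of intronic nucleotides with ≥ 1 read;
- **SL / SR** (splice left/right): junction reads linking the 5′/3′ flanking
  exon to another exon of the same gene (transcript orientation);
- **SE** (splice exact): reads spanning exactly the excised-intron junction;
- **IR ratio** = ID / (ID + max(SL, SR)), the estimated fraction of
  transcripts retaining the intron.

An intron is counted as an **IR event** in a sample when its IR ratio
exceeds 0.1 and the intron passes four cohort-level filters: a balanced
junction ratio 0.7 ≤ SL/SR ≤ 1.3 (evidence of constitutive flanking exons),
junction support (SL+SR) > 10 in ≥ 50% of samples, coverage > 0.5 in ≥ 50%
of samples, and IR ratio > 0.05 in ≥ 50% of at least one sample group.

Differential retention between groups is modelled by **beta regression**:
IR ratios are proportions in (0, 1), so per intron the mean follows
logit(μ) = β₀ + β₁·group with constant precision φ, fitted by maximum
likelihood; the group effect is tested by a Wald test, corrected across
introns by Benjamini–Hochberg FDR, and an intron is called differentially
retained when |ΔIR| > 0.1 (difference of raw group mean IR ratios) and
q < 0.05. For two-replicate designs the exact Audic–Claverie library-count
test is provided. Downstream screens include median-of-ratios
normalisation, log₂ fold changes, cohort-exclusive differential genes with
a cross-condition specificity z-score, Pearson correlation of per-sample IR
event counts with gene expression (log₁₀ scale), and PWM scanning of
splice-site flanks (50 nt exonic + 50 nt intronic per splice site, sense
strand) at thresholds calibrated from the exact background score
distribution, compared between intron classes by Student's t test.

## Worked example

Simulate a 5 + 5 matched cohort of 16 introns where 4 introns jump from a
true retention of 0.2 in normals to 0.5 in tumours, then run the full
pipeline:

```r
library(IRscreen)

design <- simDesign(nGenes = 8, intronsPerGene = 2, nNormal = 5, nCancer = 5,
                    thetaNormal = rep(0.2, 16),
                    thetaCancer = c(rep(0.5, 4), rep(0.2, 12)),
                    depth = 100, phiSim = 25, seed = 21)
sim <- simulateCohort(design)
res <- runIRPipeline(setNames(sim$samples$sam, sim$samples$sample_id),
                     sim$samples$group, sim$ref$introns, sim$ref$exons)

res$events
#> normal_01 normal_02 normal_03 normal_04 normal_05 cancer_01 cancer_02 cancer_03
#>        13        14        13        15        14        14        14        14
#> cancer_04 cancer_05
#>        15        16

as.data.frame(res$dir[res$dir$significant,
                      c("intron_id", "mean_ir_normal", "mean_ir_cancer",
                        "delta_ir", "q")])
#>          intron_id mean_ir_normal mean_ir_cancer delta_ir        q
#>  chr1:160-460:+:g1          0.221          0.497    0.277 1.33e-06
#>  chr1:610-910:+:g1          0.174          0.457    0.283 1.73e-05
#>  chr2:160-460:-:g2          0.236          0.417    0.181 4.23e-07
#>  chr2:610-910:-:g2          0.193          0.486    0.293 1.30e-07
```

Nearly every intron is an IR event in every sample here (true retention 0.2
is above the 0.1 event threshold), and exactly the four planted introns are
called differentially retained: their estimated group means sit near the
simulated truth of 0.2 and 0.5, ΔIR exceeds the 0.1 rule, and the q values
come from the per-intron beta-regression Wald tests. The two-sample exact
test for low-replicate designs is available directly:

```r
audicClaverieTest(5, 25, 1e6, 1e6)
#> [1] 0.0003249142
```

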