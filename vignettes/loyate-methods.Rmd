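---
title: "Quantifying mosaic loss of chromosome Y and its transcriptional effects"
author: "loyate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mosaic loss of chromosome Y and its transcriptional effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loyate)
```

# Background

Mosaic loss of chromosome Y (LOY) is the most common acquired chromosomal
change in aging men: a clonal fraction of leukocytes loses the Y chromosome
entirely. `loyate` implements a complete analysis stack for LOY research:
estimating the LOY cell fraction from four independent data modalities, and
detecting LOY-Associated Transcriptional Effects (LATE) — genes, mostly
autosomal, whose expression shifts as a function of the LOY fraction.

Every estimator is driven by a synthetic-data generator with recorded ground
truth, so the whole pipeline is testable without access to cohort data.

# Gene and probe annotation

All LOY quantities hinge on a partition of genes into five region classes:
**MSY** (male-specific region of the Y; lost entirely with the chromosome),
**PAR** (pseudo-autosomal; one copy survives on the X), **X_NONPAR**,
**AUTOSOME**, and **MITO**. `classifyRegion()` assigns exactly one class per
gene. PAR boundaries are configuration values with GRCh37 defaults (PAR1
X:60001–2,699,520, PAR2 X:154,931,044–155,260,560 and their Y homologs).
A gene straddling a PAR boundary is classified by its midpoint — an explicit
tie-break; boundary-straddling protein-coding genes are rare enough that the
choice is inconsequential in practice. Coordinates are 1-based inclusive
throughout (SNP-array and GTF convention).

`buildFixtureAnnotation()` produces a synthetic annotation whose Y-chromosome
complement matches the human genome (45 protein-coding MSY genes, 19 PAR
genes, 13 mitochondrial genes); autosomal and X gene counts are free
parameters because only their totals, not identities, matter downstream.

# LOY from SNP arrays

For each sample the **mLRRY** is the median log R ratio over MSY probes
(`computeMlrry()`). Genotyping batches are de-biased by subtracting a
per-batch centre (`batchCorrectMlrry()`); the default centre is the batch
median, which removes the batch bias without assuming anything about its
shape. A running-median variant over processing order is available behind
`method = "running"` for settings where the bias drifts over time. Batches below
`min_batch = 3` samples fall back to the global median with a warning.

The percentage of cells retaining the Y is recovered by the closed form
`normal% = 100 * 2^(2 * mLRRY)`, clipped to [0, 100]: noise can push mLRRY
above zero, and the clipped value reads as "no detectable loss". The simulator draws MSY-probe LRRs from
Normal(log2(1 − f)/2, `noise_sd`), the ½ compression chosen so this
inversion is exact in expectation; real arrays attenuate platform-specifically,
and `noise_sd = 0.15` is a free parameter with no claim of realism.

# LOY from droplet digital PCR

Templates partition into ~20,000 droplets as Poisson, so a channel with a
fraction *p* of positive droplets carries λ = −ln(1 − *p*) templates per
droplet (`poissonConcentration()`). The AMELY/AMELX concentration ratio
estimates the fraction of genomes retaining the Y; LOY fraction = 1 − ratio,
clipped to [0, 1]. Poisson correction is applied by default — "amounts" in
ddPCR practice means Poisson-corrected concentration — with `raw_ratio =
TRUE` to disable it; at low positive fractions the two agree closely. The
channels are treated as independent, since the assay targets a 6-bp
difference with one probe per channel. A saturated channel (every droplet
positive) has no finite concentration and errors.

Precision note: with 20,000 droplets and a λ ≈ 0.2 X-channel load, the
delta method puts the standard deviation of the estimated LOY fraction at
about 0.017, so single-well estimates are reproducible to roughly ±0.03–0.05;
materially tighter precision requires higher template loads or merged wells.

# LOY from bulk RNA-seq

Counts are normalized by median-of-ratios size factors
(`computeSizeFactors()`). **Normalization policy:** inside every LOY-aware
analysis, size factors and the dispersion trend are computed from autosomal
genes only. MSY and PAR genes carry the dosage signal being tested, and in
compact gene panels they are a large enough share of the matrix to drag the
median ratio along with the LOY fraction, which corrupts normalization and
inflates false positives genome-wide.

The variance-stabilizing transformation is the closed form
`vst(K) = (2/ln 2) * asinh(sqrt(a0 * K))` for the dispersion-mean trend
α(μ) = a0 + a1/μ fitted by `fitDispersionTrend()` (trimmed least squares on
per-gene moment dispersions; negative estimates floored at a0 = 1e−4,
a1 = 0; near-constant gene means trigger a constant-trend fallback). The
transform maps 0 to 0, is strictly increasing, and approaches log2 K plus a
constant, which are the properties the downstream statistics rely on; exact
numerical agreement with any particular package's VST is a non-goal.

`bulkYFractionLoy()` computes, per sample, mean VST expression over MSY
genes divided by the mean over autosomal genes, min–max rescaled to [0, 100]
within each cell type (min–max is the simplest map onto that range and
avoids cell-type-specific expression biases). Because min–max has no absolute scale,
the LOY fraction is calibrated against non-LOY reference samples
(DNA-derived LOY fraction < 0.05 by default): 1 − stat/median(reference
stat), clipped to [0, 1].

"Normally expressed" bulk genes have ≥ 10 reads in strictly more than 75%
of the reference samples. `expressionVsLoyRegression()` divides per-sample
gene-set expression by its maximum and regresses on the LOY percentage;
ordinary linear least squares is the default and an exponential-decay fit is
available, since both are common summaries of dosage-response curves. On noise-free dosage data the MSY slope
is exactly −0.01 per %LOY and the PAR slope −0.005 — the factor-2 contrast
that reflects the retained X copy of PAR genes.

# LOY from single-cell RNA-seq

Cells pass QC with 800–2000 detected genes (inclusive bounds; "expressed"
means ≥ 1 UMI) and at most 5% mitochondrial UMIs. Cell types are assigned
per cluster by the argmax of mean normalized marker expression (ties broken
by name with a warning; zero-marker clusters labelled "unknown"). Cluster
labels are an input; `fallbackCluster()` (k-means on top principal
components of log-normalized counts) is a deterministic stand-in for
graph-based clustering, intended only to exercise the typing stage.

A cell is called **LOY** when it has more than 2500 UMIs (strict), at least
one autosomal UMI (excludes empty barcodes), and not a single MSY transcript;
any MSY UMI makes it NORMAL, and cells at or below the UMI threshold stay
UNCALLED. The false-positive rate for a normal cell with expected MSY UMIs
*m* is bounded by e^(−m); at the default simulation settings (0.2% of UMIs
from six expressed MSY genes, so *m* ≈ 5 at the threshold) it stays well
below 2%. The UMI filter is applied before computing per-sample LOY
fractions (`sampleLoyFraction()`, which excludes UNCALLED cells from both
numerator and denominator); applying it after is possible by calling
`callLoyCells()` with a lower threshold first.

"Normally expressed" single-cell genes have ≥ 1 UMI in at least 10% of a
type's NORMAL cells. Differential expression between LOY and NORMAL cells
(`scDifferentialExpression()`) is the NB regression below with a binary LOY
indicator and log total-UMI offset; MSY genes are excluded from testing
because they have no expression in cells without a Y. Effects are reported
as log2 (natural-log coefficients divided by ln 2) for cross-method
comparability.

# The LATE engine

`fitNbGlm()` fits a log-link negative-binomial GLM per gene with a log
size-factor offset. The LOY fraction enters as 20-percent bins coded 0–4
and used as a *numeric* covariate — effects are log2 fold changes per bin —
with the top bin closed at [80, 100]. Sequencing batch is a covariate.

Numerical scheme, in order: (1) Poisson IRLS for starting means; (2) moment
dispersion (floored at 1e−8, capped at 10); (3) Cox–Reid adjusted profile
ML dispersion given the fitted means — the CR term compensates the degrees
of freedom absorbed by the coefficients, without which small-sample
dispersions are biased low; (4) optional shrinkage toward the fitted trend
value on the log scale (default weight 0.25), stabilizing small-n fits;
(5) final IRLS and a Wald test using a **t reference with residual degrees
of freedom**. The t reference matters: with a few dozen samples the normal
tail is optimistic exactly in the region that determines FDR-level
discoveries, and the heavier tail restores FDR control without costing
sensitivity. A likelihood-ratio test is available (`test = "lrt"`) and is
also the automatic fallback when the Wald fit fails to converge.

Independent filtering (`independentFilter()`) scans mean-expression
quantile thresholds (0–95% by 1%) and keeps the one maximizing BH
rejections at α = 0.1; by construction this never reduces discoveries.
Filtered genes keep their p-value but receive no q-value. Three stringency
tiers classify results: nominal p < 0.05; BH FDR < 0.1; and FDR < 0.1 with
at least a 100-read average.

Cross-method comparisons are sign- and rank-based: `signConcordance()` runs
an exact binomial sign test on shared genes (zero effects excluded with a
warning), and `sharedFractionAnalysis()` contrasts within-cell-type LATE
fractions against pairwise-shared fractions with a one-way F statistic and
a label-permutation p-value, which makes no distributional assumption on
the small set of fractions being compared.

# LCL clone contrast

Lymphoblastoid cell-line clones are clonal — essentially 0% or 100% LOY —
so the LCL arm uses a two-level group factor rather than bins. The
subtraction logic: **List1** collects genes differentially expressed
between donors among non-LOY clones (union over per-donor contrasts);
**List2** intersects the within-donor LOY contrast (the single donor
carrying both LOY and non-LOY clones) with the overall LOY contrast; the
final LATE list is List2 \ List1. All contrasts use FDR < 0.1, for
symmetry with the sorted-cell pipeline; the threshold is a config value.

With 13 clones from 6 donors, the within-donor contrast compares two or
three clones. Per-gene dispersion is not estimable there, so the LCL
contrasts rely almost entirely on the trend (shrink 0.9) and use the
likelihood-ratio test: the Wald statistic degenerates for large effects in
tiny groups (Hauck–Donner effect), while the LRT retains power. The
donor-only specificity of the subtraction is unaffected.

# Co-expression contrast

Given an externally supplied ranking of autosomal genes by co-expression
with MSY genes (co-expression databases are out of scope), the top-k genes'
fold changes between LOY and NORMAL cells (per-cell counts scaled to equal
totals, pseudocount-guarded) are compared with a control set by a two-sided
Wilcoxon rank-sum test on |log2 FC|. Magnitudes are the default because the
scientific claim is about the *amount* of dysregulation, not its direction;
a signed variant is a flag.

# Cohort comparisons

The cohort table holds one row per subject and sorted leukocyte population.
Unadjusted group differences use the Wilcoxon rank-sum test — robust to the
zero-inflated LOY distributions the simulator produces (and cohort data
show). Adjusted analyses are logistic regressions of disease status on the
LOY fraction with age and smoking; odds ratios are reported per
10-percentage-point LOY increment so they are readable at realistic effect
sizes. Quasi-separation triggers a Firth-penalized (Jeffreys-prior) refit
with a warning. Smoking is modelled as a boolean, the simplest encoding
consistent with the available description.

# What the generators emulate — and what they do not

The simulators reproduce: MSY-probe LRR shifts with batch offsets; Poisson
droplet partitioning; NB bulk counts with MSY/PAR dosage, per-bin LATE
effects, batch offsets and an α(μ) = a0 + a1/μ dispersion trend (defaults
a0 = 0.05, a1 = 2, typical bulk values); multinomial single-cell profiles
with marker structure for four PBMC types, per-type LOY frequencies
(defaults NK 27%, monocytes 23%, B 7%, T 3%), Beta-distributed mitochondrial
content with a high-mito apoptotic component, log-normal UMI depths, and
doublets as summed cell pairs; the 13-clone/6-donor LCL design with all LOY
clones from one donor; and a zero-inflated Beta cohort with group-by-type
log-odds shifts at sample sizes 156/121/107.

They do not emulate: amplification or GC bias, ambient RNA, UMI collision,
gene–gene correlation beyond marker blocks, donor-level expression
heterogeneity outside the LCL arm, or array-specific LRR attenuation.
Passing tests therefore demonstrate correctness of the estimators under the
stated noise models, not robustness to every artefact of real data.

# Problem sizes and reproducibility

The test and acceptance workloads use fixtures of a few hundred to 3000
autosomal genes, 40-sample bulk designs spanning the five LOY bins, 200
replicates for the scalar estimators, and 20 replicates for the discovery
pipelines — sizes chosen so the full suite runs in minutes on one core
while keeping Monte-Carlo error well below the tested tolerances. All
generators are deterministic given a seed; the pipeline driver
(`runPipeline()`) derives per-stage seeds from one master seed and writes a
manifest of parameters and filter tallies next to its outputs.

# Known limitations

- The bulk LOY fraction is a relative, reference-calibrated quantity; with
  no true non-LOY samples in a cell type the calibration degrades gracefully
  (the most Y-expressing sample acts as reference) but is biased.
- Per-well ddPCR precision is physically bounded by droplet counting noise
  (see above); the package reports single-well estimates and does not pool
  wells.
- The NB engine assumes independent samples; repeated measures per subject
  are not modelled.
- The fallback clusterer is a stand-in; real analyses should provide their
  own cluster labels.
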