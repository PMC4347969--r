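---
title: "Gradient heat-stress analysis: models, design choices and limits"
author: "heatgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient heat-stress analysis: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatgrad)
```

# The analysis in one paragraph

`heatgrad` analyses experiments in which a panel of genotypes (inbred
lines) is exposed to a *gradient* of stress levels — here heat: a control
and two elevated temperature regimes — and both multi-trait phenotypes and
RNA-seq expression are recorded.  The analysis has two stages.  The first
stage condenses the phenotypes into a single per-genotype *heat
susceptibility index* (HSI): adjusted entry means per trait and level are
computed from randomized-complete-block mixed models, a PCA across traits
summarizes overall plant performance, and the HSI of a genotype is the
slope of its first-component score over the metric-coded heat levels.  The
second stage regresses gene expression on the same metric heat coding with
negative-binomial (NB) generalized linear models — pooled across genotypes
to find *overall heat responsive* genes, and per genotype to obtain
genotype-specific expression slopes — and then regresses those
per-genotype slopes on the HSI to find *heat tolerance* genes: genes whose
transcriptional reaction to heat depends on how susceptible the genotype
is phenotypically.

# Phenotype models

For one trait at one heat level the observation of genotype $i$ in block
$k$ is modelled as

$$Y_{ik} = \mu + I_i + R_k + e_{ik},$$

with the genotype effect $I_i$ fixed (the lines are a deliberate
selection) and the block effect $R_k$ random (blocks are a sample of
possible replications).  `adjustedEntryMeans()` reports the best linear
unbiased estimates (BLUEs) $\mu + I_i$.  For balanced complete data the
BLUEs equal the arithmetic genotype means for *any* value of the block
variance, so the balanced path computes them exactly without iterative
fitting; unbalanced data are fitted by REML via `lme4`.  The unit tests
verify the REML path against both the arithmetic result and a brute-force
GLS fit whose variance ratio is found by grid search.

Refitting the same model with $I_i$ random yields the variance components
$\sigma^2_I$ and $\sigma^2_e$ and the repeatability of entry means over
$n$ replications,

$$H^2 = \frac{\sigma^2_I}{\sigma^2_I + \sigma^2_e / n},$$

computed by `varianceComponents()` and `repeatability()`.  On balanced
data the package uses the exact ANOVA expected-mean-square solution
(identical to REML away from the boundary); negative estimates are
truncated at zero, and the degenerate all-identical input returns zero
variances with a warning rather than failing.

The combined model across levels,

$$Y_{ijk} = \mu + I_i + H_j + (IH)_{ij} + R_{jk} + e_{ijk},$$

tests genotype, heat level and their interaction with the replication
nested in level as a random block.  `combinedModelTests()` fits this with
`lmerTest` (Satterthwaite denominator df) or, for balanced complete data,
via the classical blocked ANOVA, whose F statistics the mixed-model Wald F
provably equals in that case; we use Satterthwaite rather than containment
df because the two coincide on the balanced designs this analysis
targets.  A Monte-Carlo test confirms the interaction test holds its
nominal 5% type-I error.

# Metric heat coding and the HSI

Temperatures are mapped affinely onto $[0, 1]$:
$x = (T - T_{\min}) / (T_{\max} - T_{\min})$, so 25/32/38&nbsp;°C becomes
$0, 7/13, 1$ (`metricHeatCoding()`).  One unit of $x$ spans the whole
gradient, which makes every slope below interpretable as a change *across
the full heat range*.

`pcaMeans()` performs the PCA of the (genotype × level) × trait matrix of
adjusted means.  Three design choices were genuinely open:

* **Standardization.** Traits are scaled to unit variance by default:
  they carry incommensurable units (cm, g, SPAD, °C), and without
  scaling the trait with the largest numeric range would dominate the
  index.  The flag `standardize = FALSE` restores covariance PCA.
* **Scores, not loadings.** The HSI needs one value per genotype–level
  combination, which is a PC1 *score*; loadings attach to traits.
  `computeHSI()` therefore regresses the per-genotype PC1 scores on the
  metric codes and reports the OLS slope.
* **Sign orientation.** A PCA sign is arbitrary, so PC1 is oriented such
  that the mean score increases from the lowest to the highest heat
  level.  "High HSI = heat susceptible" is then deterministic; a test
  confirms that flipping the sign convention would flip all HSI values,
  and that the orientation rule removes that ambiguity.

The HSI x-axis uses the metric coding rather than °C or an ordinal
1/2/3, for consistency with the expression models; `computeHSI()` accepts
any coding vector if another convention is wanted.  Note the *absolute*
scale of the HSI depends on this choice and on the PCA standardization —
rankings do not.

# Expression models

Counts are first cleaned and calibrated with standard machinery: genes
need at least 2 counts per million in at least 2 samples
(`cpmFilter()`; "at least" is inclusive on both thresholds),
library-composition factors come from TMM (`tmmFactors()`, delegating to
edgeR with the conventional 30%/5% trims), and a single common NB
dispersion $\phi$ is estimated by maximizing the Cox–Reid adjusted
profile likelihood over all genes on the one-way genotype-by-level
layout (`commonDispersion()`).  The Cox–Reid adjustment matters: with
only two replicates per cell, unadjusted maximum likelihood profiles out
half the degrees of freedom and underestimates $\phi$ by roughly a factor
of two.  The biological coefficient of variation is
$\mathrm{BCV} = \sqrt{\phi}$; simulations at BCV 0.26 (a typical value
for biological replicates of an inbred line) recover it within ±0.03,
and the estimate agrees with edgeR's common dispersion in a cross-check
test.

The overall dose–response model per gene is the NB regression

$$\log \mu_{ijk} = \mu + x_j \, \beta_{\ln} + \log(\text{effective library size}),$$

fitted by iteratively reweighted least squares (tolerance $10^{-8}$,
at most 50 iterations), with $\phi$ held fixed at the common estimate.
`fitDoseResponse()` reports the slope in log2 units,
$\beta = \beta_{\ln} / \ln 2$, i.e. the log2 fold change across the full
gradient, with a likelihood-ratio $\chi^2_1$ test of $\beta = 0$ and
Benjamini–Hochberg FDR across genes.  At $\phi = 0$ the fit equals a
Poisson GLM to $10^{-6}$, which is tested gene by gene against `glm()`.
A gene is called *overall heat responsive* iff FDR $< 0.05$ **and**
$|\beta| > 2$, both strict; the fold-change criterion is read as "the
slope, expressed in log2 units, exceeds 2" (a 4-fold change across the
gradient).

Per-genotype slopes $\gamma_i$ come from the same model with
genotype-specific slopes.  As printed, the genotype-specific model shares
one intercept across genotypes; because baseline expression demonstrably
differs between inbred lines, the default mode gives each genotype its
own intercept, which makes the joint fit separable into per-genotype
subset fits (and exactly reproducible by `fitDoseResponse()` on the
subset — a tested reduction).  The literal shared-intercept joint fit is
available as `mode = "shared-intercept"`.  Calls per genotype use the
same strict double threshold, with FDR computed within genotype, and
`overlapSets()` intersects the per-genotype up- and down-sets to define
the *common heat responsive* genes and any group-wise overlaps
(pools, tolerance classes).

# The tolerance test

For each gene, `toleranceRegression()` fits

$$\gamma_i = \mu + h_i \, \delta + e_i$$

by OLS over genotypes, where $h_i$ is the HSI.  The two-sided p-value
uses the t distribution with $n_\text{genotypes} - 2$ df and is **not**
adjusted for multiple testing: with eight genotypes the test is
low-powered in the way an association scan is, and adjusting would
eliminate what power remains.  This is a deliberate, documented departure
from the FDR logic of the first-stage tests.  A gene is a *heat
tolerance* gene iff $p < 0.05$ and $|\delta| > 2$, both strict; the
boundary case $\delta = 2$ exactly is not called (tested).  Called genes
are clustered on their $\gamma$ vectors (Euclidean distance, complete
linkage, tree cut at $k = 2$), which separates genes upregulated in
susceptible lines from genes upregulated in tolerant lines.

Because $\delta$ is a slope *per HSI unit*, its scale inherits the HSI
scale.  The simulators keep the two coherent (see below), but when the
package is applied to real data with a differently scaled index, the
$|\delta| > 2$ default should be revisited.

# Enrichment

`hypergeomEnrich()` tests each annotation term by the upper-tail
hypergeometric probability of observing at least $k$ term genes in the
study set, with BH FDR across terms and the enrichment fold
$(k/K)/(n/N)$.  The universe is the set of genes surviving the CPM
filter — the only defensible background when the analysis itself only
ever sees those genes.  Terms with $k = 0$ are reported with $p = 1$
rather than dropped, keeping the output schema stable.  No ontology
graph propagation is performed.  The implementation is verified against
exhaustive enumeration of all draws for universes up to $N = 12$.

# What the simulators emulate — and what they do not

The generators in `simulatePhenotypes()`, `simulateCounts()` and
`simulateFastq()` reproduce the statistical structure the analysis
assumes, with planted ground truth for every downstream stage:

* **Phenotypes**: 8 genotypes × 3 heat levels (25/32/38 °C) × 10
  blocks × 6 seedling traits, with trait-by-level population means set to
  values realistic for temperate maize seedlings (growth rate peaking at
  the mild level, dry weight collapsing at 38 °C, leaf temperature
  tracking air temperature).  Each genotype's heat response is amplified
  in proportion to a planted susceptibility $s_i \sim U(0.9, 1.9)$ —
  the range observed for diverse inbred panels.  Noise defaults
  (genotype, block and residual SDs of 8%, 5% and 12% of each trait's
  heat-response range) produce repeatabilities around 0.6–0.9, matching
  well-run growth-chamber experiments.  The default interaction strength
  (0.25) is calibrated so the *derived* HSI has about the same spread as
  the planted $s_i$, keeping $\delta$ thresholds meaningful end to end.
* **Counts**: NB draws with mean
  $\text{lib} \cdot q_g \cdot 2^{\gamma_{ig} x_j}$ and common dispersion
  $\phi = \mathrm{BCV}^2$ (default BCV 0.26); log-normal baseline
  abundances so the post-filter gene count is stable; library sizes
  uniform on 0.5–2 × 10⁶ — a deliberate desk-scale stand-in for deep
  libraries that keeps every simulation fast while leaving per-gene
  means high enough for slope recovery; optionally one sample dropped,
  mirroring a 47-of-48 design with a missing pooled replicate.  Planted
  classes: null ($\gamma = 0$), responsive ($\gamma_{ig} = \pm 4$
  everywhere) and tolerance genes ($\gamma_{ig} = h_i \delta_g$,
  $\delta_g = \pm 4$).
* **FASTQ**: planted fractions of reads that exceed the 30%-of-bases at
  Q ≤ 20 exclusion rule and reads carrying an exact adapter substring,
  with the remainder guaranteed clean — exact counting of what the
  filter must remove.

They do **not** emulate: realistic base composition or gene models
(read sequences are uniform random), RNA-level pooling of biological
replicates before sequencing (each sample is a single NB draw; whether
pooling changes the effective dispersion is an open question we resolve
by treating the pooled sample as the replicate unit), per-gene
dispersions, batch or lane effects, or correlated traits beyond what the
susceptibility factor induces.  Passing tests therefore demonstrate the
*statistical machinery* is correct under the assumed model — not that
the model captures every feature of a real experiment.

# Numerical choices

* NB IRLS: tolerance $10^{-8}$ on coefficients, max 50 iterations,
  linear predictor clamped to $\pm 30$ against overflow; non-converged
  genes are flagged and never called.  All-zero genes short-circuit to
  $\beta = 0$, $p = 1$.
* Common dispersion: maximized over $\log\phi \in [\log 10^{-6}, \log 10]$
  with `optimize()` (golden-section/parabolic), tolerance $10^{-6}$.
* Variance components truncated at 0 (the REML boundary); both-zero
  inputs to `repeatability()` return 0 with a warning.
* BH is the standard step-up; ties are handled by the stable ordering of
  `p.adjust()`, and gene identity never affects p-values.
* Degenerate inputs error early with named offenders: missing PCA cells,
  zero-variance traits under standardization, zero effective library
  sizes, HSI without variance, study genes outside the universe.

The test suite runs everything at reduced problem sizes chosen to keep
the whole suite under a minute while leaving each check well-powered:
2,000 genes for dispersion and end-to-end recovery, 1,000–5,000 null
genes for calibration checks, 100 seeds for the HSI ranking study, 500
Monte-Carlo runs for the interaction type-I error.

# Known limitations

* The common-dispersion model ignores genewise dispersion variation;
  strongly variable genes inherit a slightly liberal or conservative
  test.  Empirical-Bayes shrinkage is intentionally out of scope.
* The HSI is only defined up to the scale conventions above; comparisons
  of $\delta$ across studies require the same conventions.
* With eight genotypes the tolerance test has low power, and its
  unadjusted p-values imply a nontrivial expected number of false calls
  among many genes; treat called genes as candidates.
* The quality filter excludes whole reads; adapter *trimming* is not
  implemented, matching a screening-only cleaning strategy.
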