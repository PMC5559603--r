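---
title: "Mapping response eQTLs in stimulated monocytes: models and design choices"
author: "reqtlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping response eQTLs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reqtlkit)
```

## The scientific problem

Innate immune cells such as monocytes mount stereotyped transcriptional
programs when their pattern-recognition receptors meet microbial ligands —
LPS (TLR4), muramyl-dipeptide (NOD2), or triphosphorylated double-stranded
RNA (RIG-I).  Common genetic variants modulate these programs: a *cis*
expression quantitative trait locus (eQTL) associates genotype dosage with
a nearby gene's expression, and a **response eQTL (reQTL)** is an eQTL
whose effect size *changes* when the cells are stimulated — a
gene-by-environment interaction at the level of transcription.  reQTLs are
interesting because a risk variant that only acts during infection is
invisible in resting tissue, yet may drive genetic predisposition to
autoimmune and inflammatory disease.

`reqtlkit` implements the full inference chain for a design with seven
conditions: an untreated baseline plus three treatments (`LPS`, `RNA`,
`MDP`) at two time points (90 min, 6 h).  Every stage is exercised on a
synthetic cohort with planted, known effects, so the statistical machinery
is testable end to end without access to any cohort data.

## Per-condition cis-eQTL mapping

For gene $g$ with probe anchor position $a$ and condition $c$, every SNP
within 1 Mb of $a$ (same chromosome) is tested by simple linear regression
of expression on allelic dosage,
$y_i = \mu + \beta \, d_i + \varepsilon_i$.  No covariates enter the
default model: in the motivating design the donors are homogeneous (single
sex, narrow age range) and batch structure is assumed to be removed
upstream; a pre-corrected expression matrix can be supplied instead.
Missing dosages are mean-imputed per SNP (preserving sample size),
monomorphic SNPs are skipped and counted, and samples with missing
expression are dropped per (gene, condition).

Gene-level significance uses adaptive permutations mirroring a
`100 10000` setting: expression is permuted across samples, each
permutation records the minimum nominal p over the gene's cis SNPs, and
permutation stops once 100 permuted minima beat the observed minimum or at
the ceiling.  A Beta distribution is fitted to the permuted minima by
maximum likelihood (method-of-moments initialization; on failure the
empirical estimator $(r+1)/(N+1)$ is used with a warning) and the reported
`p_perm` is the fitted CDF at the observed minimum.  Within each condition,
Benjamini–Hochberg at FDR 5% over `p_perm` defines the **eGene** set; the
lead eSNP is the SNP with minimum nominal p, ties broken by genomic
position.  Permutation streams are independent across conditions and genes
but fully deterministic given the master seed.

## Calling reQTLs, specificity, and ceQTLs

The core statistic compares the lead SNP's slope between baseline and a
stimulated condition:

$$z = \frac{\beta_{\text{baseline}} - \beta_{\text{stim}}}
      {\sqrt{\sigma^2_{\text{baseline}} + \sigma^2_{\text{stim}}}},$$

with a two-sided normal p-value (`p_beta`).  One test is performed per
(gene, stimulated condition) for every gene that is an eGene *in that
condition or at baseline*.  Including baseline eGenes is a deliberate
design choice: an eQTL that is fully suppressed by stimulation is, by
construction, not an eGene in the stimulated condition, and restricting
the family to stimulated-condition eGenes would make suppressive reQTLs
(temporal codes `1-0-1`, `1-1-0`, `1-0-0`) undiscoverable.  The lead SNP
is taken from the stimulated condition when available, otherwise from
baseline.  The primary analysis corrects the whole family by Bonferroni at
0.05; a BH-corrected variant builds the relaxed set used for enrichment
analyses.

*Treatment specificity*: a significant reQTL of one treatment is compared
against the other two treatments at the same time point in two z-tests;
both must be Bonferroni-significant (family = all cross-treatment tests).
The one-of-two rule is available behind a flag.  *Time-point specificity*
uses the single cross-time z-test within the treatment, with its own
Bonferroni family.  The two comparison types form separate families — the
analysis is per-family, a choice recorded here because a single global
family would also be defensible.

**ceQTLs** (constant eQTLs) are baseline eGenes whose slope never moves:
all six stimulated-vs-baseline comparisons must have *nominal*
`p_beta > 0.05` (relaxed set: `> 0.005`).  Under the null each of six
roughly independent tests passes with probability 0.95, so even a truly
constant eQTL is called with probability near $0.95^6 \approx 0.74$ — the
definition is conservative by construction.  reQTL and ceQTL sets are
provably disjoint at matching thresholds.

## Temporal dynamics and DE congruence

Each reQTL gene is encoded by eGene membership at baseline / 90 min / 6 h
for its treatment (the best-p treatment when shared).  The six categories
are transiently active `0-1-0`, transiently suppressive `1-0-1`, late
active `0-0-1`, late suppressive `1-1-0`, prolonged active `0-1-1`, and
prolonged suppressive `1-0-0`; genes significant at all three time points
(`1-1-1`) are excluded from the six-way classification.  Differential
expression (paired t-test on log2 values; the mean paired difference is
the log2 fold change) between baseline and 90 min ($\Delta_{90}$) and
between 90 min and 6 h ($\Delta_{6h-90}$) yields a two-digit DE code, and
a category's *congruent* code is: transient `1-2` (up then back down),
late `0-1`, prolonged `1-0` or `1-1`.  Per category, a two-sided Fisher's
exact test compares the congruent proportion against the pooled remaining
categories, and a one-sided exact binomial test asks whether active
categories outnumber suppressive ones.  A paired t replaces the moderated
t of array pipelines here; with the generator's Gaussian noise the two are
asymptotically equivalent, and the decision rule (log2FC and FDR
thresholds) is unchanged.

## Selection enrichment and derived-allele direction

Per locus, the strongest selection signal — maximum |iHS| and |SDS| — is
taken over the lead SNP and all SNPs in LD with it ($r^2 > 0.8$, squared
Pearson correlation of unphased dosages; under Hardy–Weinberg this is
essentially haplotype $r^2$).  Loci are binned by MAF (width 0.05) and by
LD proxy count (0–2, 3–5, 6–10, 11–20, 21–50, >50).  The null is built by
resampling, 10,000 times, one pool locus per target locus from the same
(MAF, LD) cell with replacement, so every resample reproduces the
target's bin multiset exactly; the pool is all QC-passing SNPs and target
loci are not removed from it (their mass is negligible at genome scale).
The permutation p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(N+1)$,
never zero.  Note that for the *proportion* statistic the null is
discrete, so exact ties make the estimator mildly conservative; the
median-based statistic is continuous and calibrates exactly.

For the direction analysis, each reQTL's slopes are re-oriented to count
derived-allele copies (slopes flip sign when the ancestral allele is the
dosage-counted allele).  The response effect
$\Delta\beta = \beta_{\text{stim}} - \beta_{\text{baseline}}$ is compared
with the population response direction $d$, the sign of the gene's DE
log2FC in the matching condition: agreement means the derived allele
*increases* response amplitude (amplifying an induction or a
suppression both count as increasing), disagreement means it decreases
it.  By default $d$ is taken from the DE fold change regardless of DE
significance — the gating question is genuinely open — and a flag
restricts to significant DE.  Records with unknown ancestral state or
$d = 0$ are unclassifiable.  An exact one-sided binomial test against 0.5
quantifies excess of increasing-activity reQTLs.

## Replication, GWAS overlap, and Q–Q enrichment

Replication of an eQTL panel in external p-values uses Storey's
$\pi_0$: $\hat\pi_0(\lambda) = \#\{p > \lambda\} / ((1-\lambda)m)$,
clipped to $[0,1]$, with $\pi_1 = 1 - \hat\pi_0$.  The default is the
transparent single-$\lambda$ estimator at $\lambda = 0.5$; the
grid-and-spline smoother (the qvalue package's default behaviour) is
available by flag — it is slightly noisier at desk scale, which is why it
is not the default here.  Small targeted panels use the nominal
replication rate (fraction with p < 0.05) instead.

GWAS-catalog overlap links a lead eSNP to a catalog association when
their genotype $r^2$ exceeds 0.8 (identifier match first, positional
fallback); a `baseline_absent` flag marks loci whose baseline association
is nominally absent (p > 0.01), i.e. only visible under stimulation.
Genome-wide enrichment of an annotated SNP set in GWAS p-values is
summarized by stratified Q–Q curves with expected quantiles
$(i - 0.5)/n$; a hierarchical enrichment model is deliberately out of
scope, the Q–Q table being the in-scope summary.  Duplicate catalog
entries (one SNP, several traits) produce one record per (lead, trait)
pair; aggregation is left to the caller.

## The synthetic cohort generator

`simulate_genotypes()` builds hard-call dosages in independent LD blocks:
each block copies a founder haplotype with a per-SNP error rate solved
(by root-finding on the closed-form correlation) so the expected pairwise
genotype $r^2$ within the block equals the requested value, while the
realized allele frequency equals the block's target MAF.  Haplotypes are
independent per sample, so Hardy–Weinberg holds exactly by construction.
Blocks sit 3 Mb apart, farther than the 1 Mb cis window, making
cross-block independence also hold for cis scans.  The ancestral allele
is the major allele with probability 0.8 (minor otherwise), mimicking
real ancestral-state distributions while exercising both orientations;
dosages are emitted as hard calls 0/1/2 (imputed-dosage pipelines reduce
to this at high imputation quality, and all inference here only needs
hard calls).

`simulate_expression()` plants effects of seven architectures — constant,
or active/suppressive crossed with transient/late/prolonged — as
per-condition slopes on *mean-centered* dosage plus condition-wise mean
shifts and Gaussian noise.  Centering the genetic term is a deliberate
choice: planted slopes then never move condition means, so planted
differential-expression profiles are exactly the configured shifts rather
than being confounded by allele-frequency-dependent offsets (without
centering, a suppressive eQTL's disappearance would masquerade as
differential expression of size $\beta \cdot \bar d$).  Congruent DE
patterns shift the mean by +1.5 log2 units with the effect's own temporal
profile — enough to clear a log2FC > 1 / FDR 0.001 rule at the default
noise SD of 1 — and divergent patterns use a mismatched profile.  One
probe per gene is generated; multi-probe designs are collapsed upstream
by best detection.

What the generator does *not* emulate: coalescent LD decay, allele
frequency spectra, batch and array detection effects, probe
cross-hybridization, heavy-tailed expression noise, or realistic reQTL
effect-size distributions (planted effects are homogeneous by design, for
testability).  Passing tests therefore demonstrate that the *machinery*
is correct and calibrated, not that any particular biological cohort
would yield the same discovery counts.

## Numerical choices and degenerate inputs

* Exact Hardy–Weinberg testing enumerates the conditional distribution of
  the heterozygote count given allele counts in log space; the two-sided
  p sums all outcomes no more probable than the observed one (with a
  $1+10^{-12}$ tie tolerance).
* Perfect regression fits (zero residual variance) are flagged
  `degenerate`; they receive the smallest representable p in scans and
  are excluded from z-tests, where a zero SE would be meaningless.
* Zero-variance paired differences in DE give p = 1 when the mean
  difference is 0 and the smallest representable p otherwise.
* The Beta fit to permuted minima clamps p-values to
  $[10^{-12}, 1-10^{-12}]$ before the likelihood; Nelder–Mead failure
  falls back to the empirical estimator.
* Lead-SNP ties (equal nominal p) break by smallest genomic position, so
  repeated runs are reproducible.
* All seeds are explicit; sub-seeds per (condition, gene) are derived by
  fixed integer arithmetic below $2^{31}$.

## Problem sizes used in the shipped checks

The test-suite property checks run at deliberately desk-scale sizes: null
calibration of the z-test at 2,000 gene/SNP pairs with 134 samples;
architecture recovery at 50 genes per class with 500 samples;
permutation-machinery agreement at 200 genes with the full 10,000
permutations; FDR/FWER control over 50 replicate simulations of 500
genes; and an end-to-end deterministic run at 500 samples, 200 genes and
2,000 SNPs.  The acceptance script (`scripts/acceptance.R`) reruns scaled
versions of the same computations from scratch and writes the resulting
rates and p-values as JSON.

## Known limitations

* The regression model has no covariate adjustment by default; for real
  cohorts with structure, residualize expression first.
* LD is genotype-based $r^2$; haplotype-phase effects are not modeled.
* The ceQTL definition accepts a gene as "constant" by failing to reject
  six nulls; its complement is not a power statement.
* The smoother variant of $\pi_0$ inherits the variance of the
  high-$\lambda$ bins; at small $m$ prefer the single-$\lambda$ default.
* The always-on (`1-1-1`) reQTLs are excluded from dynamics categories,
  mirroring the six-way scheme, although they carry real effect-size
  changes.
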