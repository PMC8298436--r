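---
title: "Empirical-null statistics for allelic and drug-interaction MPRA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical-null statistics for allelic and drug-interaction MPRA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A massively parallel reporter assay couples each candidate regulatory
element to a set of unique barcodes placed downstream of a minimal
promoter and reporter. Activity of barcode $k$ in sample $s$ is estimated
as a depth-normalized log ratio of expressed RNA to delivered plasmid
DNA:

$$
y_{sk} \;=\; \log_2\!\frac{r_{sk} + c}{N^{\mathrm{RNA}}_s}
        \;-\; \log_2\!\frac{d_k + c}{N^{\mathrm{DNA}}},
$$

with raw counts $r_{sk}$ (RNA) and $d_k$ (a single shared input-DNA
library), library sizes $N$ taken as raw column totals, and pseudocount
$c = 1$ (default) to keep dropout barcodes finite without distorting
well-covered ones. One SNP contributes two *elements* — the barcode sets
of its reference and alternate alleles — and the element expression of an
allele in a sample is the mean of its unmasked barcode values.

Filtering happens before any testing: barcodes with input DNA below
`min_dna_count` (default 10) are masked entirely, zero-RNA cells can be
masked per sample, barcodes observed in too few samples can be dropped,
and alleles retaining fewer than `min_barcodes_per_allele` (default 3)
barcodes are removed outright. These thresholds are deliberate package
defaults in conventional MPRA ranges; all are arguments, and the filter
reports the number of cells removed at each step. Filtering is idempotent
and monotone: raising a threshold can only remove more cells.

## Why a basal-barcode empirical null

Barcode sequences themselves perturb reporter expression. If allelic
comparisons were referred to a parametric t distribution, barcode
composition effects shared by all ten barcodes of an allele would
masquerade as allelic signal. The design therefore carries a pool of
*basal* barcodes — identical reporter constructs with no candidate
sequence — and the null distribution of any allelic statistic is
estimated by repeatedly drawing two disjoint random subsets of basal
barcodes (subset size defaulting to the real `barcodes_per_allele`),
treating them as pseudo-alleles, and computing the statistic exactly as
for a real SNP. The empirical p-value uses the add-one convention,

$$
P_{\mathrm{emp}} \;=\; \frac{1 + \#\{|T_{\mathrm{null}}| \ge |T_{\mathrm{obs}}|\}}{1 + n_{\mathrm{sims}}},
$$

so it is never exactly zero and its floor is $1/(n_{\mathrm{sims}}+1)$.
Two properties of this construction matter for interpretation:

- it is *conditional* on the realized basal pool. With 110 basal
  barcodes the realized between-barcode variability fluctuates around its
  expectation, and the null tail need not (and should not) match the
  parametric F or t reference; the tests verify the parametric limit only
  on a much larger synthetic basal pool with iid noise.
- because real alleles and pseudo-alleles share the same barcode-offset
  variance structure, type-I error is calibrated: on all-null synthetic
  data the fraction of SNPs with $P_{\mathrm{emp}} < \alpha$ matches
  $\alpha$ to binomial accuracy, which the acceptance suite checks at
  $\alpha = 0.05$ and $0.1$ with 500 SNPs.

The simulation count defaults to 20,000 for both the t null and the
mixed-model F nulls; the F-statistic count is stated by the study design
this package follows, and the same default is applied to the t null.

## Allelic testing

Per SNP, the *composite log2 fold change* is the mean over samples of
(alt element value − ref element value), paired within sample so shared
sample effects cancel. Significance uses a two-sided two-sample t-test of
the per-sample element values (Welch by default; the pooled variant is an
option and keeps the degrees of freedom constant, which is convenient
when comparing empirical and parametric ranks). Normality is gated by a
Shapiro–Wilk test on per-allele-centered pooled element values; SNPs
failing the gate (p ≤ 0.05) with a significant primary test get a
recorded two-sided Mann–Whitney U verification, which never excludes a
SNP. Single-condition analyses of a drug arm use Benjamini–Hochberg FDR
across SNPs instead of the empirical null, matching the role of those
analyses as support for the mixed model.

The design power analysis simulates the entire pipeline — barcode-level
Normal(0, `barcode_sd`) noise, averaging to element means, t-testing
6 vs 6 replicates — and reports the fraction of simulations significant
at Bonferroni-corrected $\alpha$. At the study's parameters (SD 0.12,
10 barcodes/allele, effect 1.1 log2 units, $\alpha = 0.1/1013$) power is
effectively 100%, comfortably above the 80% design target.

## The allele-by-drug mixed model

Barcode-level measurements of both conditions are modeled per SNP as

$$
y \;\sim\; \text{allele} + \text{drug} + \text{allele}{:}\text{drug} + (1 \mid \text{replicate}),
$$

with allele coded ref = 0 / alt = 1, drug coded vehicle = 0 / treated = 1,
and a random intercept for the replicate pair spanning both conditions
(wells transfected and processed together; the 12-level well coding is
available by changing the sample metadata). Fits use lme4; coefficients
and Wald F statistics ($F = t^2$ per fixed coefficient) are reported from
the REML fit — the choice of reference degrees of freedom is immaterial
because inference runs through the empirical F null, not a parametric F.
SNPs with fewer than 40% of their possible barcode-by-sample measurements
(96 of 240 under the default design) are skipped and reported.

The F null refits the identical model on basal pseudo-alleles with the
true drug and replicate labels. Because every draw shares one balanced
pseudo-design, the model is fitted once and refitted with each draw's
response vector, which keeps 20,000 draws to a few minutes on one CPU.
Only basal barcodes with complete unmasked rows enter the null so the
shared model frame is valid; with the default simulated depths this is
the entire basal pool.

Interactions called by empirical p are validated by a likelihood-ratio
test comparing maximum-likelihood interaction and additive fits against
$\chi^2_1$; on synthetic interaction data at the study's noise level, at
least 95% of SNPs with interaction $P_{\mathrm{emp}} < 0.05$ have LRT
p < 0.051, mirroring the internal-consistency expectation for a
non-overfit interaction model. Effect categories combine the mixed model
with the single-condition analyses: an interaction is present iff
interaction $P_{\mathrm{emp}} < 0.05$; an allele main effect is present
iff allele $P_{\mathrm{emp}}$ is below threshold and — when an
interaction is present too — the vehicle single-condition
$P_{\mathrm{emp}} < 0.1$, the treated-arm FDR q < 0.1, and both
single-condition directions agree. The classifier is a pure function and
is tested exhaustively on a threshold-straddling grid.

## Motif perturbation scoring

Motif analysis asks whether the two alleles differ in their match to a
transcription factor's position weight matrix. Scoring is a standard
log2-odds scan, $\sum_j \log_2(p_{b_j j}/q_{b_j})$ with uniform
background $q$, over both strands, restricted to windows overlapping the
SNP; `N` bases score as background. Scores are rescaled to a relative
score in $[0,1]$ between the matrix's attainable extremes, and the
allelic delta is the difference of best relative scores. A perturbation
is *strong* when the better allele matches at ≥ 0.85 relative score and
|delta| ≥ 0.3, *weak* when |delta| ≥ 0.1. These thresholds are declared
package defaults standing in for motifbreakR's internal p-value-based
"strong" labeling: downstream enrichment consumes the binary label, so
any monotone surrogate preserves the pipeline's semantics, and all three
thresholds are arguments. Scanning is verified against an exhaustive
brute-force enumeration on random fixtures.

## Resampling enrichment and concordance

For each TF, the number of functional SNPs carrying a (by default,
strong) motif perturbation is compared with the counts in 10,000 random
draws of $n = |\mathrm{functional}|$ SNPs taken without replacement from
the analyzed set — a label permutation, so the null respects each TF's
overall hit frequency — with add-one empirical p-values and BH correction
across TFs. Drawing from all analyzed SNPs (rather than only
non-functional ones) is the package's reading of the ambiguous
description of the resampling set; it is the standard permutation choice
and the alternative only shifts nulls conservatively. On small fixtures
the resampling p agrees with the exact hypergeometric tail within
Monte-Carlo error. Because hit counts are discrete, these p-values are
valid but conservative; the calibration tests assert conservative
uniformity (rejection rate not exceeding nominal level) rather than a
continuous-distribution goodness-of-fit, which discreteness would fail
by construction.

The concordance variant counts (SNP, TF) pairs where the allele better
matching the motif is also the allele driving higher expression — the
expected behaviour of a strictly activating TF — with direction ties
excluded and reported. ChIP-peak overlap uses 0-based half-open BED
semantics (`start ≤ pos < end`); SNP positions are supplied 1-based and
converted internally, and interval arithmetic runs on GenomicRanges.

## The synthetic-data generator

The generator emulates the study conditions and is the substrate for
every calibration and recovery test: up to ~1454 SNPs × 2 alleles × 10
barcodes plus 110 basal barcodes; two conditions × 6 replicates; latent
barcode activity
$\mu_0 + b_k + \beta_a[\mathrm{alt}] + \beta_d[\mathrm{drug}] +
\beta_i[\mathrm{alt\cdot drug}] + u_r + \varepsilon$ with barcode offsets
$b_k$ (SD 0.05), replicate offsets $u_r$ (SD 0.05) shared across
conditions, and residual SD 0.12 — the one variance figure the assay
reports (median barcode expression SD ≈ 0.122 in both conditions, checked
by `variance_homogeneity()`). RNA counts are Poisson-lognormal (Poisson
around depth-scaled $d_k 2^{\text{latent}}$), DNA counts lognormal around
depth/barcodes; at the default depths Poisson noise adds little beyond
the latent SD. Basal barcodes share $\mu_0$ and $b_k$ but carry no
allele, drug or interaction terms; a configurable basal offset exists for
robustness checks. Sequencing-level artifacts (PCR duplicates, barcode
errors, GC effects) are deliberately not modeled — the basal null absorbs
barcode-sequence effects empirically, and that is the property under
test — so passing tests demonstrate statistical calibration and
recovery under the stated noise model, not robustness to library-prep
pathologies in real data.

Motif fixtures plant a consensus match overlapping the SNP in one allele
and the worst-scoring base at the SNP in the other. The planted PWMs have
one highly informative position (the one aligned to the SNP) and
moderately informative flanks, the flank consensus avoids the sharp base
and its complement (so no shifted or reverse-strand window re-matches the
informative position through the planted run), and element flanks are
redrawn until the planting satisfies the strong-perturbation contract —
making 100% planted recall a construction invariant rather than a
statistical hope.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-variance t-tests return
t = 0, p = 1 flagged; all-tied Mann–Whitney inputs return p = 1; a
rank-deficient interaction (single condition present) returns LR = 0,
p = 1; singular random-effect fits are kept with the zero variance
component and flagged; mixed-model optimizations restart from three fixed
starting points before being flagged non-converged. Ties in PWM scanning
break toward the leftmost position and forward strand.

The shipped tests run at desk scale by choice: 500 SNPs for null
calibration with 20,000-draw shared nulls, 50 seeds × three effect sizes
for parameter recovery, 100 random fixtures for the scanning oracle, and
2,000 draws where an exact reference is available. Headline counts of a
full screen (e.g. numbers of functional SNPs at a given threshold on real
sequencing data) are properties of the data, not of this implementation,
and are out of scope here.
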