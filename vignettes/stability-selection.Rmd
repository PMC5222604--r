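---
title: "Selecting stable normalisation genes for ageing circadian transcriptomes"
author: "stabnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable normalisation genes for ageing circadian transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabnorm)
```

## The problem

Quantitative statements about gene expression — "this transcript increases
1.5-fold in old animals" — are only as good as the normalisation behind them.
Expression is usually reported relative to reference ("housekeeping") genes
assumed constant. In ageing studies that assumption is fragile twice over:
transcriptional noise grows with age and can affect the reference genes
themselves, and in tissues with a strong circadian clock, such as mouse
liver, a large fraction of the transcriptome oscillates over the day. A
reference gene must therefore be stable against **both** perturbations, and
the stability assessment itself must not presuppose a normalisation.

`stabnorm` implements a screening-and-normalisation workflow for exactly this
situation: candidate reference genes are screened for stability with
compositional (centered log-ratio) statistics that need no prior
normalisation, the survivors are combined into marker sets, samples are
rescaled by the geometric mean of the markers, and age-related changes are
then tested with a repeated-measures mixed model under family-wise error
control.

## Centered log-ratio screening

Let $x_i = (x^{(1)}_i, \dots, x^{(N)}_i)$ be the expression of $N$ genes
under condition $i$. The centered log-ratio is

$$\mathrm{clr}(x_i) = \left( \log\frac{x^{(1)}_i}{g(x_i)}, \dots,
\log\frac{x^{(N)}_i}{g(x_i)} \right), \qquad
g(x_i) = \Big(\prod_k x^{(k)}_i\Big)^{1/N},$$

the log of each gene relative to the geometric mean of its own sample.
Because $g(x_i)$ absorbs any per-sample scale (sequencing depth, input
amount, hybridisation efficiency), clr values are invariant under
multiplying a sample by a positive constant, and each clr vector sums to
zero. The difference of a gene's clr values between two conditions is the
log fold-change the gene would show after aligning the samples to a common
geometric mean — so the **variance of a gene's clr across conditions** is a
normalisation-free generalisation of fold-change analysis to many
conditions, and the **mean clr** measures overall expression level. Stable,
well-expressed genes sit in the high-mean, low-variance corner.

`clr_transform()` computes the transform (natural log; fold-changes are
reported as `exp` of clr differences, so the base cancels).
`clr_gene_stats()` averages clr values within each condition group first and
then takes the mean and the unbiased ($n-1$) variance across condition-level
values. Two grouping conventions are used, matching the two assay designs:

* genome-wide pooled screens: one library per age class, so each column is a
  condition (4 age pools in the reference design);
* targeted panels: every sample is its own condition (8 ages × 12 zeitgeber
  times × 2 replicates = 192 conditions), so circadian variation counts as
  instability.

**Zeros.** Genome-wide count matrices contain zeros and the clr needs
positive values. A pseudocount of 0.5 (half the smallest non-zero count) is
added by default; it is configurable, and with targeted panels — where all
counts are large — it is immaterial.

## The four stability assessments

Candidates are screened by four independent assessments, each producing
pass / fail / not-detectable per gene (`median_criterion()`,
`reference_gene_criterion()`, `meta_criterion()`):

1. **Genome-wide median criterion.** Against all assayed genes (after a
   detectability pre-filter keeping genes with ≥ 20 counts in some library),
   a candidate passes if its mean clr is strictly above the background
   median *and* its clr variance strictly below the background median. Ties
   fail: "above the median" is read literally. The background includes the
   candidates themselves by default — removing a handful of genes from
   thousands cannot move a median — with an `exclude_candidates` switch for
   the literal "all other genes" reading.
2. **Replication on public genome-wide data.** The same criterion applied to
   independent datasets; genes missing from an assay are "not detectable"
   rather than failed.
3. **Panel reference-gene criterion.** On the targeted panel, a candidate
   passes if its clr variance across all 192 individual samples is strictly
   below that of the least variable core-clock gene (*Cry2* in the
   motivating panel): a usable reference must be quieter than any truly
   rhythmic gene.
4. **Meta-analytic fold-change criterion.** Across a large set of public
   studies (130 in the reference design), fold-changes are symmetrised to
   magnitudes $\max(f, 1/f)$ — down-regulation counts against stability just
   as up-regulation does — and a candidate passes if its magnitude is below
   1.2 in strictly more than 90% of studies. An `inclusive` flag accepts
   exactly 90%; the strict reading is the default.

`combine_assessments()` turns the table into marker sets: the **core set**
(no failures) and the **extended set** (at most one failure). Not-detectable
entries count as neither pass nor fail — a gene with one failure and one
missing assay still reaches the extended set; this is the only reading
consistent with the published example shipped in
`inst/extdata/liver_marker_assessments.tsv`, where the core set is
{*Atp5h*, *Gsk3b*, *Sirt2*} and the extended set adds
{*Nono*, *Tprkb*, *Tspo*, *Ttr*}.

## Normalisation

Two multiplicative corrections, in this order:

1. **Positive-control constants** (`positive_control_constants()`): each
   panel hybridisation carries spike-in controls at known input amounts;
   $c_{s,i} = \text{expected}_i / \text{observed}_{s,i}$ converts counts to
   the input-amount scale, and the per-control constants are combined per
   sample by their geometric mean.
2. **Marker-gene factors** (`marker_normalisation_factors()`): for each
   marker the per-sample constant is the gene's cross-sample geometric mean
   over its value in that sample; the sample's factor is the geometric mean
   of the constants over all markers (equal weights). Anchoring each gene to
   its own cross-sample geometric mean makes the factors symmetric in the
   samples and gives them geometric mean 1 by construction.

When the markers are truly constant, these factors invert any per-sample
multiplicative distortion exactly (to machine precision) — this is tested as
an identity, not a tolerance. Using seven markers also bounds the damage an
outlier can do: corrupting one marker $k$-fold in one sample moves that
sample's factor by at most $k^{1/7}$.

## Detecting age effects

Two age groups sampled on the same zeitgeber-time grid are compared with a
linear mixed model (`repeated_measures_anova()`, via `nlme::lme`): age as a
fixed effect and a random intercept per time point, pairing the groups
through the shared times. Choices the data cannot make for us, and what we
chose:

* **Scale.** Models are fitted on log values (flag for raw scale): noise and
  age effects are multiplicative.
* **Random-effects structure.** A random intercept per zeitgeber time is the
  minimal structure that pairs same-time samples across ages while letting
  the circadian profile soak up the time effect. With one observation per
  (age, time) cell the model reduces exactly to a paired t-test over time
  points, which the test suite uses as an independent oracle (agreement to
  1e-6).
* **Replicates.** Kept as individual observations by default;
  `average_replicates = TRUE` collapses each (age, ZT) cell first.
* **Optimizer.** `optim` rather than the default `nlminb`: flat,
  non-rhythmic genes drive the between-time variance component to zero,
  where `nlminb` can abort with a singular-convergence error.
* **Multiplicity.** Bonferroni: with a 36-gene test family at $\alpha =
  0.05$ the per-gene threshold is $0.05/36 \approx 0.00139$. The family size
  defaults to the number of genes tested and is configurable.
* **Fold-change.** `fold_change_estimate()` reports the geometric mean over
  time points of (mean old / mean young) at each time point — consistent
  with the multiplicative model; an arithmetic flag exists. Whether to
  average ratios or ratio grand means is genuinely open; for balanced
  designs with modest rhythms the two differ by far less than the
  Monte-Carlo spread of the estimate.

`two_way_anova()` complements this with the classical two-factor
decomposition (age, time, interaction) plus Bonferroni-corrected per-time
comparisons of the two ages against the pooled residual variance — the usual
follow-up when one asks *when* in the day an age difference appears.

## What the synthetic data emulate

`simulate_panel()`, `simulate_rnaseq_screen()`, `simulate_meta_studies()`
and the composite `simulate_selection_study()` generate every input the
pipeline consumes, with ground truth attached. The count model is
gamma-Poisson (negative binomial): gene $g$ in sample $s$ has mean

$$\mu_{gs} = b_g \, e^{\beta_g a_s} \left(1 + A_g \cos\tfrac{2\pi (t_s -
\phi_g)}{24}\right) f_s,$$

with baseline $b_g$, age ramp $a_s \in [0,1]$ (linear on the log scale from
the youngest to the oldest design age, so $\beta_g$ is the old-vs-young log
fold-change), relative amplitude $A_g$, acrophase $\phi_g$, and log-normal
technical factor $f_s$ (σ = 0.2, a typical library-size spread). Dispersion
grows linearly with age — the "transcriptional noise increases with age"
feature that motivates the whole exercise — and `dispersion = 0` gives the
deterministic noise-free limit used in degenerate-case tests.

**Calibration of the defaults.** No quantitative noise levels are available
to copy, so the defaults are calibrated once to the procedure's documented
working regime and then frozen: panel dispersion 0.002 (≈ 5% CV at typical
panel counts once Poisson noise is included) with inflation 1e-4 per month
(≈ 7% CV in 24-month-old animals). At these levels the seven-marker factors
recover simulated technical factors with log-scale correlation > 0.99, and
1.25–1.52-fold age effects are detectable at N = 24 per group — the regime
the method is designed for. Amplification-free single-molecule counting
panels plausibly sit in this range; deeper-noise settings degrade the factor
recovery first (at a dispersion of 0.01 the seven-marker correlation drops
to ≈ 0.98) and detection power second.

The reference panel mirrors the motivating design: 16 candidate genes, 12
clock genes with amplitudes 0.15–0.6, 4 genes with age effects at the
magnitudes 1.52, 0.74, 1.33 and 1.25, and 20 mildly rhythmic fillers; 8 ages
× 12 times × 2 replicates. The genome-wide screen draws log-normal baselines
spanning ~4 orders of magnitude with per-gene biological variability, one
column per age pool.

**What the simulations do not emulate** — and hence what green tests do not
certify about real data: no batch structure beyond a per-sample scalar, no
probe-specific biases or cross-hybridisation, no correlated gene modules
(every gene's noise is independent given the technical factor), pooling is
represented only by the absence of circadian terms, and the meta-analysis
fold-changes are drawn symmetric log-normal rather than from heterogeneous
real platforms. Passing the recovery suites shows the procedure is correct
and well calibrated under its own assumptions, not that those assumptions
hold for any particular experiment.

## Problem sizes used by the test and acceptance suites

Calibration of the age test uses 2000 simulated null genes (circadian signal
present, no age effect, N = 24 per group); family-wise error is assessed by
grouping them into 55 panels of 36. Power and specificity use 20
independent 52-gene panels; marker-factor recovery and selection recovery
use 20 seeds each. These sizes give Monte-Carlo standard errors comfortably
below the margins being tested while keeping a full run on one CPU in the
order of a minute.

## Known limitations

* The mixed model assumes homoscedastic log-scale residuals; age-inflated
  dispersion makes old groups slightly noisier, which the balanced design
  absorbs well (the null rejection rate stays inside the binomial band), but
  strongly unbalanced designs would not enjoy the same robustness.
* Strict inequalities at the medians mean a candidate exactly at a
  background median fails; with continuous statistics this is a
  measure-zero event, but discretised inputs (heavily rounded tables) could
  make it matter.
* The selection criteria are marginal per gene: a set of candidates that
  are stable individually but co-regulated would pass while violating the
  independence that makes the geometric-mean factor robust. The pairwise
  correlation diagnostics (`pairwise_correlations()`) are provided for
  exactly this check, but no automatic rule is applied.
* Bonferroni is deliberately conservative; for large panels a
  false-discovery-rate procedure would be more powerful, and is out of
  scope here.
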