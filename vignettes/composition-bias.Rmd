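---
title: "Composition bias in co-expression analysis: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition bias in co-expression analysis: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model of the compositional artifact, the simulator that emulates it,
the statistical machinery built around it, and the numerical conventions
and design choices that a maintainer or careful user should know about.

## 1. The compositional artifact

Write $c_{gs}$ for the read count of gene $g$ in sample $s$, $\ell_g$ for
its transcript length and $w_{gs} = c_{gs}/\ell_g$ for its
length-normalized rate. TPM is

$$\mathrm{TPM}_{gs} = \frac{w_{gs}}{\sum_h w_{hs}} \times 10^6 ,$$

a *closed* (zero-sum) quantity: each sample's values sum to $10^6$
exactly. If a block $M$ of genes (here the 13 mtDNA-encoded OXPHOS genes)
carries a fraction $f_s = \sum_{g \in M} w_{gs} / \sum_h w_{hs}$ of the
rate pool, every nuclear gene's TPM carries a factor $(1-f_s)$. When
$f_s$ varies between samples — and the mitochondrial fraction varies
enormously between donors within a tissue — $\log(1-f_s)$ acts as a
shared negative factor on all nuclear genes and $\log f_s$-type terms as
a shared factor on the block, producing:

* negative mt–nuclear correlations,
* positive nuclear–nuclear correlations among unrelated genes,

both growing with the mean and the spread of $f$. A linearization gives
the orders of magnitude: with a log-normal mitochondrial activity factor
of coefficient of variation $v$, the shared nuclear term has standard
deviation $\approx f\,v$ and the block term $\approx (1-f)\,v$, so the
induced mt–nuclear correlation scales like
$-f(1-f)v^2/(\sigma_{mt}\sigma_{nu})$ where $\sigma$ are the total
per-gene log-scale standard deviations. Two consequences the package's
diagnostics make visible:

* the mt–nuclear artifact *saturates* and eventually weakens as
  $f \to 1$ (the block's own variance vanishes), while the
  nuclear–nuclear artifact keeps growing;
* the artifact depends on the *rate* (transcript) share, not directly on
  the read share — the two coincide only when the dominant block's
  length profile matches the transcriptome average.

Median-of-ratios and TMM scaling estimate the sample depth from the
*typical* gene rather than the total, so a dominant minority block moves
into the ignored tail and the induced coupling disappears. This is the
entire rationale for recommending MRN/TMM over TPM/FPKM for correlation
work.

## 2. The simulator

`simulate_dataset()` draws, per cohort:

1. per-gene baseline log-abundances $b_g \sim N(0, 1.2^2)$ shared across
   cohorts plus cohort shifts $N(0, 0.2^2)$ — a heavy-tailed expression
   distribution spanning a few orders of magnitude, as in real tissue;
   the nuclear correlated block can be shifted upward (`nu_log_boost`)
   to reflect that OXPHOS subunits are high-expressed genes;
2. latent standard-normal gene scores with a one-factor-per-block
   construction: block gene $g$ gets
   $z_g = \sqrt{\rho^*}\,F + \sqrt{1-\rho^*}\,\varepsilon_g$ with the two
   block factors correlated as needed for the planted cross-block value.
   Spearman targets are made exact at the latent level through the
   Gaussian-copula correction $\rho^* = 2\sin(\pi\rho_S/6)$; because the
   gene-level transform to rates is monotone, the rank correlations among
   true rates equal the planted values;
3. a per-sample mitochondrial activity multiplier
   $m_s \sim \mathrm{LogNormal}$ with mean 1 and configured coefficient
   of variation, scaling all mt-gene rates. The mt baseline is adjusted
   analytically so the *expected read share* equals `mt_fraction_mean`;
   the share is controlled in expectation, not forced per sample, so the
   realized spread mirrors the wide within-tissue ranges seen in real
   data. Note that the *fraction* CV saturates: for an activity CV $v$
   the share CV is $\approx (1-f)v$;
4. confounder shifts on the log scale: per-gene coefficients
   $N(0, 0.1^2)$ by default for age (bracket midpoints, standardized),
   sex ($\pm 1/2$) and batch;
5. renormalization of read rates $w_g \ell_g$ to a log-normal library
   size (reads are proportional to transcript abundance *times* length);
6. negative-binomial sampling with dispersion 0.02 by default (Poisson at
   0). A dispersion of 0.02 corresponds to a genewise biological
   coefficient of variation of about 14% on top of the planted latent
   variation, typical of deeply sequenced homogeneous bulk cohorts.

Gene lengths are log-uniform on 300–10,000 bp for nuclear genes. The 13
mt genes all receive the mean nuclear length (2,767 bp): mitochondrial
transcript length diversity is not the object of study, and fixing the mt
lengths makes the read-share dial and the transcript-share lever coincide,
so a single parameter controls the artifact strength.

What the generator does *not* emulate: isoform and effective-length
effects, GC/amplification biases, cell-type composition shifts, batch
effects on dispersion, zero inflation, or donor sharing across cohorts.
Passing tests therefore demonstrate correctness of the *machinery* under
a controlled compositional mechanism, not performance on any particular
real dataset.

### Compositional closure inside the simulator

Renormalizing to the library size makes the simulated counts themselves
compositional. Two practical consequences surfaced during design and are
worth recording. First, a correlated block that carries a noticeable
share of the simulated read mass leaks its own factor into the per-sample
total; scaling methods estimate depth from the median gene, so the leak
cancels only when independent background genes dominate the gene panel.
Simulation scenarios therefore use background pools of a few thousand
genes — in real transcriptomes the 139 OXPHOS genes are a small minority
of ~20,000, and a small panel would overstate closure effects the real
analysis does not suffer. Second, even under MRN a very small residual
coupling survives in proportion to the correlated blocks' read share;
with narrow bootstrap intervals at realistic sample sizes this residual
can be statistically detectable while being an order of magnitude smaller
than the TPM artifact. Effect sizes, not significance calls alone, are
the meaningful readout.

## 3. Normalization conventions

* **TPM** is computed directly from counts and lengths; the test suite
  asserts equality (to $10^{-9}$ relative) with the FPKM-rescaling route
  $\mathrm{TPM}_i = \mathrm{FPKM}_i / \sum_j \mathrm{FPKM}_j \times 10^6$.
* **CPM excluding a set**: no length normalization; the excluded genes
  keep the full-total denominator. For correlation analysis, which never
  compares genes within a sample, this is equivalent to a
  length-normalized version.
* **Upper quartile**: the 75th percentile of *non-zero* counts with the
  linear-interpolation quantile (type 7), the common default in
  mainstream statistics software; factors are reported relative to
  library size and rescaled to geometric mean 1 so they are comparable
  across runs.
* **Median-of-ratios**: reference = geometric mean across samples over
  genes positive in *every* sample; factor = median ratio to the
  reference, with the median taken on the log scale (geometric middle of
  the two central ratios when their number is even). This matches the
  DESeq2 size-factor convention bit-for-bit, which the test suite
  asserts.
* **TMM**: reference sample = non-zero upper quartile of depth-normalized
  counts closest to the mean quartile (overridable via `ref`); M/A values
  on genes positive in both sample and reference; 30%/5% two-sided trims
  with *average* rank tie handling; precision weights = inverse
  asymptotic binomial variances; factors rescaled to geometric mean 1.
  The trim constants and weighting follow the original algorithm's
  published defaults. One numerically delicate point: genes with
  mathematically equal count ratios must remain exactly tied in rank, so
  the log-ratio is evaluated as a single expression; with this
  convention the factors agree with edgeR to machine precision (asserted
  in the tests).

## 4. The correlation engine

* **Aggregated ranks.** The combined-cohort statistic draws $k$ samples
  per cohort, ranks each gene *within* the drawn cohort subset (average
  ranks on ties), concatenates ranks across cohorts, and computes Pearson
  correlation on the aggregate — no global re-ranking, since within-cohort
  ranks repeat identically across cohorts and a global re-rank would only
  manufacture ties. The construction makes the statistic invariant to any
  strictly monotone within-cohort transform of the residuals and stops
  high-variance cohorts from dominating. The median over `R` iterations
  is reported.
* **Bootstrap inference.** Within a cohort, samples are resampled with
  replacement `B` times and the median between-set Spearman correlation
  recomputed; the 2.5/97.5 percentiles give the interval. The *raw*
  empirical p is the fraction of bootstrap medians on the opposite side
  of zero from the observed value, with `1/B` substituted (and flagged as
  a bound) when no median crosses zero. Because that raw fraction
  conditions on the observed sign, it is approximately Uniform(0, 0.5)
  under a true null and can never exceed ~0.5; the package therefore also
  reports the sign-doubled two-sided p (`p_two = min(1, 2 p_raw)`), which
  is the quantity that is approximately uniform under the null, and the
  calibration tests assert uniformity on it. Significance calls use
  BH-FDR across cohorts on the raw p, following the directional
  convention of the source methodology.
* **Random-gene null.** The nuclear set is replaced by random panels of
  equal size drawn from expressed nuclear genes (median TPM > 5 across
  all samples by default, threshold configurable); the observed median is
  standardized against the 100 panel medians,
  $Z = (\mathrm{obs} - \bar{T}_{null})/s_{null}$, normality of the panel
  medians is checked by Shapiro–Wilk, and p values come from the normal
  CDF. Whether the test should be one- or two-sided is not dictated by
  the construction, so both are reported with the two-sided value as the
  default. Two design points matter for calibration: the null hypothesis
  embodied by $Z$ is *exchangeability* of the named set with random
  panels — if the named set carries genuine internal co-regulation its
  observed median fluctuates more than panel medians and $Z$ is
  over-dispersed by construction; and the eligible pool must be much
  larger than the panel, otherwise overlapping panels understate the
  null spread.
* **Matched pairs.** Donor-matched 1:1 tumour/normal pairs (one tumour
  kept at random when several match, normals without a tumour dropped and
  counted), per-class MRN normalization and confounder regression within
  each cohort, bootstrap standard errors from 100 draws of 90% of the
  samples, and a Fisher exact test on the cross-cohort 2×2 table of
  significant-positive calls. The Fisher p sums hypergeometric
  probabilities at most the observed table's (with a $1+10^{-7}$
  tolerance ratio, as is standard), and is verified against full
  enumeration on all tables with margins ≤ 12.

## 5. Confounder regression

Per-gene OLS with either per-cohort scope or a combined scope expanding
covariate-by-cohort interactions plus categorical blocks (donor, batch).
The original mixed-effects formulation (donor and batch as random
effects) is approximated by fixed-effect categorical blocks: the
approximation is deterministic and dependency-light, and with many levels
the shrinkage difference is immaterial for the rank-based statistics
computed downstream; an exact mixed-model backend is a natural extension
point. Aliased design columns are dropped deterministically (first
occurrence kept) and reported. Residuals are computed on normalized
values in their natural scale — no log transform is applied before the
linear model; since everything downstream is rank-based, a monotone
rescaling would not change the results, but the choice is recorded here
and in the residual object's provenance.

Age brackets (`"50-59"`) are converted to midpoints and treated as
numeric. The bracket midpoint of `"50-59"` is 54.5 — the bracket is
closed on both integer endpoints.

## 6. The dip statistic

`dip_statistic()` computes Hartigan's dip — the minimal sup-norm distance
from the empirical CDF to any unimodal CDF (convex then concave, a jump
permitted at the mode only) — by iterative modal-interval refinement on
the merged distinct values: fit the greatest convex minorant of the lower
ECDF corners and the least concave majorant of the upper corners within
the current window, locate the largest majorant–minorant gap, shrink the
window to the supporting hull vertices around it, and accumulate the
ECDF-corner deviations from the hulls over the abandoned tails; the dip
is half the largest accumulated deviation.

The implementation was validated against an exact oracle: the band
formulation of the fitting problem (values within
$[U_t-\varepsilon,\,L_t+\varepsilon]$ at each distinct point, convex
prefix, concave suffix, jump at the mode) solved as a linear program,
minimizing $\varepsilon$ over all mode placements. Agreement is within
$3.5\times 10^{-8}$ over 400+ random cases including heavy ties,
near-collinear spacings and clustered data, and the closed forms hold
exactly: $D = 1/(2n)$ for equally spaced samples (the universal lower
bound) and $D = 1/4$ for two equal point masses. A curated set of
oracle values is frozen in the test suite.

`dip_test()` obtains p values by Monte-Carlo simulation from uniform
samples of the same size (the dip is invariant to monotone transforms of
a continuous null), under an explicit seed, rather than from
interpolation tables: exact reproducibility was preferred over speed, and
`dip_null_table()` lets many equally sized panels share one null table.
The p resolution is `1/n_mc` and reported p values never fall below it.

## 7. Scenario design for the validation suite

The test suite runs the full pipeline on simulated study conditions whose
sizes were chosen to keep the suite fast while leaving adequate
statistical power:

* *Artifact demonstration*: 5 cohorts × 150 samples, 13 + 126 + 200
  genes, mt fraction means 0.1–0.6 at activity CV 0.3, no planted
  correlations. With the default noise levels the TPM mt–nuclear median
  is expected near −0.09/−0.22/−0.25 at shares 0.1/0.3/0.6 (the
  saturation regime starts just above 0.6), while MRN and TMM stay
  within ±0.05 of zero.
* *Parameter recovery*: planted cross-block Spearman 0.5 with blocks
  0.8/0.4, 5 cohorts × 200 samples, 2,500 background genes, mt share
  0.05, gene-level log-sd 0.5, dispersion 0.005, library ~10^7. These
  low-noise, large-background conditions keep the attenuation from
  counting noise, confounders and compositional closure to ~10%, so the
  aggregated-rank pipeline recovers the planted value within the ±0.1
  tolerance with margin.
* *Calibration*: 200 single-cohort null datasets (blocks planted,
  cross-correlation zero) of 150 samples with 3,000 background genes for
  the bootstrap uniformity check at B = 200, and 50 datasets with an
  incoherent nuclear set and a 2,000-gene pool for the Z check. The
  percentile bootstrap is known to be slightly anti-conservative at
  moderate n, which is why the scenario uses cohort sizes in the
  hundreds — the same sizes at which the real analyses operate.

## 8. Known limitations

* Fixed-effects approximation of the combined-scope mixed model (above).
* The bootstrap empirical p inherits percentile-bootstrap small-sample
  anti-conservatism; for cohorts below ~100 samples interpret marginal
  calls cautiously.
* Compositional closure is only asymptotically removed by MRN/TMM; tiny
  residual couplings proportional to a correlated block's read share
  remain detectable at large n (Section 2).
* The random-gene-null Z assumes exchangeability of the named set with
  random panels; it is not a test of the correlation's magnitude.
* The dip test's Monte-Carlo null assumes a continuous underlying
  distribution; heavy ties make it conservative.
* `signature_score()` uses `log2(x+1)` on normalized pseudocounts as its
  variance-stabilizing transform. The external proliferation-index
  tooling it stands in for uses a model-based VST with internal gene
  lists; no numeric equivalence is claimed, only a monotone, comparable
  per-sample score.
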