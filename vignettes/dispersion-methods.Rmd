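---
title: "Modelling and testing gene expression variability with dispvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and testing gene expression variability with dispvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispvar)
```

## The model

`dispvar` asks a different question from differential expression: not whether
a gene's *mean* expression differs between two populations (or species), but
whether its *variability across individuals* does. The observed count
$x_{ij}$ of gene $j$ in sample $i$ is modelled hierarchically:

$$x_{ij} \mid x_{i+}, \lambda_{ij} \sim \mathrm{Poisson}(x_{i+}\, l_j\,
\lambda_{ij}), \qquad
\lambda_{ij} \sim \Gamma(\phi_j,\ \phi_j / \mu_j),$$

where $x_{i+}$ is the sample's total read count, $l_j$ the gene's effective
length (the orthologous exonic span over which reads were counted, which may
differ between species), and $\lambda_{ij}$ the true relative expression.
The Gamma is parameterised by (shape, rate), so $E[\lambda] = \mu_j$ and
$\mathrm{Var}[\lambda] = \mu_j^2/\phi_j$ — stated explicitly because a
shape/scale mix-up silently inverts the overdispersion. Marginally the
counts are negative binomial with mean $x_{i+} l_j \mu_j$ and overdispersion
$1/\phi_j$: the Poisson layer absorbs sequencing sampling noise, and
$1/\phi_j$ captures genuine expression variance across individuals.

Both parameters are estimated per gene by direct maximum likelihood with the
offsets $o_i = \log(x_{i+} l_j)$ held fixed: a Newton solve for
$\log\mu$ profiled inside a golden-section search on $\log\phi$
(implemented in C++; one fit costs tens of microseconds, which matters
because the resampling procedures below refit every gene hundreds of
times). $\phi$ is capped at $10^6$: for Poisson-like genes the likelihood in
$\phi$ is monotone and the estimate would otherwise diverge; capped genes
are flagged and report log-overdispersion $\approx -13.8$ — a censored
floor, not an estimate, so no mean-corrected dispersion is assigned to them
(a censored value entering the trend or the residuals would act as an
artificial outlier). An all-zero gene
has no interior optimum and is flagged non-converged. A grid-search
maximiser of the same likelihood is kept in the test suite as an independent
oracle for the optimiser.

## From overdispersion to "dispersion"

Overdispersion is strongly tied to mean expression, for reasons both
technical and biological, so raw $1/\hat\phi_j$ values are not comparable
across expression levels. We fit a degree-1 LOESS of
$\log(1/\hat\phi_j)$ on $\log\hat\mu_j$ across all converged genes and take
the residual as the gene's **dispersion** — a mean-corrected, unitless
(a.u.) summary. Dispersion above 0 means the gene varies more across
individuals than genes of similar expression. Both axes are natural-log;
because the residual is only defined relative to the fitted trend, only
scale-consistent comparisons (between genes in one fit, or between two fits
of the same genes) are meaningful. The span defaults to 0.75 and is
exposed; degree is fixed at 1 — a local-linear trend is flexible enough for
the monotone mean-overdispersion relationship and does not chase the sparse
extremes of the expression range.

## Uncertainty and the differential test

*Standard errors.* `bootstrap_se()` resamples sample columns with
replacement (within the group), refits every gene, **refits the trend**,
and takes the standard deviation of the residual across resamples (default
B = 1000). Refitting the trend per resample is deliberate: the statistic is
trend-relative, so trend uncertainty belongs in the SE. `freeze_trend =
TRUE` reuses the observed trend — faster and documented as an
approximation.

*Differential dispersion.* For two groups the observed statistic per gene
is $|d_A - d_B|$, the absolute difference of mean-corrected dispersions.
The null is built by pooling all columns of both groups and repeatedly
drawing two pseudo-groups of the original sizes with replacement; each
iteration refits genes and trend in both pseudo-groups. The empirical
p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ — the +1
correction keeps p strictly positive, a property the raw fraction lacks and
one required for sane FDR estimation. Pooled columns keep their own
offsets: a sample's library size and its group's effective lengths travel
with the column into whichever pseudo-group it lands in.

A calibration property worth knowing: because both pseudo-groups are drawn
with replacement from the same pool, they share columns, which makes the
two pseudo-group dispersions positively correlated and the null $|\Delta|$
slightly narrower than the sampling distribution of the observed statistic
(computed on disjoint groups). At 39 + 39 samples this shifts the bulk of
null p-values down mildly (median near 0.45 in our calibration runs) while
leaving the lower tail — the part that drives discovery — calibrated to
slightly conservative. A disjoint permutation split would remove the
effect; the resampling-with-replacement construction is retained as the
package's reference procedure, and the shape above is what its user should
expect on null data.

FDR is controlled with Storey q-values: $\hat\pi_0$ is estimated from the
flat right tail of the p-value distribution over a $\lambda$ grid
(0.05–0.95), smoothed with a cubic spline and read off at $\lambda = 0.95$;
with fewer than 100 p-values the spline is unstable and a fixed
$\lambda = 0.5$ estimator is used. `bh_fdr()` is the $\pi_0 = 1$ special
case.

## Companion statistics

*Cell-type specificity.* From a pseudo-bulk matrix (single-cell counts
summed within cell-type labels, then CPM per cell type), the index
$\tau = \sum_k (1 - x_k/\max x)/(K-1)$ ranges from 0 (uniform across cell
types) to 1 (exclusive to one type). $\tau$ is computed on linear CPM, not
log values: the definition requires non-negative linear expression.
`correlate_dispersion_tau()` inner-joins by gene ID — ortholog mapping is
the caller's responsibility.

*Coding constraint.* `pnps()` implements the within-species analogue of
dN/dS: after requiring at least one polymorphism in every group, a
pseudocount of 0.5 on both counts gives
$(P_n + 0.5)/(P_s + 0.5)$, strictly positive and finite by construction.
Group comparisons use Mann-Whitney tests; correlations over the whole range
use quantile-binned Spearman (default 10 bins, with the plain gene-level
Spearman always reported alongside, since binning is a presentation choice,
not a different estimand).

*cis-eQTL scan.* Variants are filtered on MAF > 0.1 and an exact
Hardy-Weinberg test (p > $10^{-7.5}$) — the HWE test is the conditional
exact test on heterozygote counts given allele counts. Pairing uses a
250 kb window around the gene body, 1-based and boundary-inclusive. The
association model is fixed-effect OLS of inverse-normal-transformed
expression on alt-allele dosage plus user-supplied covariates (expression
PCs or similar); covariates are projected out of both sides once
(Frisch-Waugh), so each pair reduces to a simple regression with the
correct residual degrees of freedom. Relatedness correction via a GRM
random effect is out of scope; the covariate interface is the supported
approximation. Gene-level significance uses min-p permutations (joint
permutation of expression + covariates against genotypes), which directly
provides what eigen-decomposition-based corrections approximate. Matched
control SNPs require |ΔMAF| ≤ 0.05, ≤ 100 kb, r² < 0.2, drawn uniformly
among eligible candidates; every emitted match is re-asserted against the
constraints.

## What the generator emulates — and what it does not

`simulate_counts()` draws from exactly the hierarchy above: log-normal
$\mu_j$ (location $\log 10^{-8}$, scale 1.5 — mean counts near 100 at a
$10^7$ library and 1 kb length, spanning the dynamic range of bulk
RNA-seq), a log-linear baseline trend $\log\phi_j = a + b(\log\mu_j -
\text{location})$ with $a = \log 3$, $b = 0.3$ (overdispersion declining
with expression, as observed in bulk data), two groups of 39 samples by
default, and library sizes drawn log-uniformly in $[10^6, 3\times 10^7]$.
Differentially dispersed genes are planted by multiplying $1/\phi$ in group
2 (default fraction 0.1, fold 5), leaving $\mu$ untouched — so planted
genes are *not* differentially expressed, and the test must find them from
variance alone. Offsets use the observed column totals, as an analyst
would.

Genotypes use a block-copy haplotype model (each variant copies its block
founder's allele with probability 0.9) — the simplest mechanism with
tunable r²; it produces no realistic recombination maps or allele-frequency
spectra. Cell-type profiles are noiseless expected counts by default so the
stored true τ is exact to machine precision; Poisson noise is optional. No
batch effects, GC bias, mappability structure, or cell-type composition
drift are simulated — calibration and power results on these data bound
what the method can do when its model is correct, and say nothing about
robustness to misspecification.

## Numerical choices and degenerate inputs

- $\phi$ search bounded in $[10^{-4}, 10^6]$, golden-section tolerance
  $10^{-8}$ on $\log\phi$; inner Newton tolerance $10^{-12}$ with step
  clamping at ±5 on $\log\mu$.
- Trend fitting requires ≥ 50 converged genes; LOESS uses exact
  (`surface = "direct"`) evaluation for reproducibility. A resample whose
  trend fit degenerates contributes NA, not an abort, and p-values divide
  by the per-gene count of valid resamples.
- The rank-based normal transform uses the offset $(r - 0.5)/n$ — symmetric
  and finite; ties get average ranks; constant rows become zeros and are
  flagged.
- Decile and quantile binning break ties by stable input order.
- Every stage seed is derived from the master seed with a stage tag, so
  adding a stage never perturbs another stage's draws; all generators are
  byte-reproducible given the seed.

## Problem sizes used in the shipped checks

The packaged tests run the differential test at 500 genes, 39 + 39 samples
and B = 500 null iterations, parameter recovery at 500 genes × 200 samples,
eQTL recovery at 100 genes × 38 individuals with 99 permutations, and
control matching over 10,000 variants — sizes at which the calibration,
power, and recovery targets are stable across seeds while a full run of the
suite stays in the minutes range on one core. The same computations, at the
same sizes, are what `scripts/acceptance.R` re-runs end to end.

## Known limitations

Shrinkage or empirical-Bayes moderation of $\hat\phi$ is deliberately
absent — the bootstrap and pooled-resampling procedures require plain
per-gene MLEs. The eQTL stage supports no missing genotypes and SNPs only.
The differential-dispersion test compares whole-tissue variability; it
cannot separate cell-type composition changes from per-cell-type
variability (the τ correlation is the diagnostic offered for that
confounding).
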