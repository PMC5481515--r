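---
title: "Models and methods behind strpfr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind strpfr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions used throughout the package, and what its synthetic-data tests
do and do not demonstrate about real experiments.

## The physical system

A scale-down chemostat couples a stirred tank (STR) to a plug-flow loop
(PFR) through a recycle stream. Cells grow under nutrient limitation in the
STR; a fraction continuously passes through the loop, consumes the residual
substrate, starves, and returns. Three quantities characterize the system.

**Residence times.** Each compartment's mean residence time is `V/F`. The
default geometry (1.12 l STR, 0.38 l PFR, 3.04 ml/s recycle flow) gives
τ_STR ≈ 368 s and τ_PFR = 125 s, the latter decomposed into five sample
ports at 30–110 s plus a 15 s outlet loop. Port residence times for the
unreported intermediate ports P2 and P4 are interpolated linearly between
the known P1/P3/P5 values (50 s and 90 s); they only matter for the onset
gating of the synthetic generator.

**Dispersion.** Plug-flow quality is summarized by the Bodenstein number.
`rtd_moments()` computes the RTD moments of a measured tracer curve by
trapezoidal quadrature on the supplied grid — deliberately without
resampling or smoothing, since moment analysis is how Bo is conventionally
reported and is robust at the Bo ≈ 80 regime of interest.
`bodenstein_from_variance()` inverts the closed-vessel variance relation
σ²_θ = 2/Bo − (2/Bo²)(1 − e^(−Bo)) by `uniroot` on (1e−8, 1e6) with a 1e−12
tolerance; σ²_θ is monotone decreasing in Bo on that interval, so the
bracket always holds. Variances below the relation's value at Bo = 1e6 are
reported *at* the cap with a `plug_flow` attribute: "effectively plug flow"
is more honest than an unstable huge number.

For simulation, `simulate_dispersion_rtd()` defaults to a symmetric
Gaussian exit-age density in θ = t/τ centred at 1 whose variance is taken
from the same closed-vessel relation. The well-known skewed open-boundary
solution `E(θ) = sqrt(Bo/(4πθ)) exp(−Bo(1−θ)²/(4θ))` is available as
`form = "open_vessel"`, but it has mean 1 + 2/Bo and a variance that
differs from the closed-vessel relation at order 1/Bo²: estimating Bo from
such a curve under the closed-vessel relation is biased low by ~1% at
Bo ≈ 84 and its mean residence time is off by 10% at Bo = 20. Since the
estimation side of the package assumes closed boundaries, the simulator's
default dialect is made consistent with it; round trips (simulate →
moments → invert) then recover Bo essentially exactly, which is what the
tests verify. Noise is multiplicative log-normal, reflecting proportional
detector error.

**Zoning and effective growth.** Substrate depletion along the loop is
modelled as zero order: residual concentration divided by the volumetric
uptake rate. With the defaults (2.5 mg/l, 0.056 mg l⁻¹ s⁻¹) the growth zone
ends ~45 s into the loop. Because plug flow makes axial volume proportional
to residence time, the growth-zone volume is prorated by t_deplete/τ_PFR,
and the whole-system average growth rate concentrates into it:
`μ_zone = μ_avg (V_STR + V_PFR) / V_growth` ≈ 0.24 h⁻¹ at μ_avg = 0.2 h⁻¹.

## The count model and the DE engine

Counts are modelled as negative binomial with `var = μ + φμ²`. The design
convention follows chemostat practice: a replicate factor plus one combined
experimental factor encoding port × process time; a contrast compares two
levels of that factor, testing by the likelihood ratio between the full
fit and a fit with the two levels merged.

*Filtering.* Genes flagged rRNA/tRNA are removed first (residual structural
RNA survives depletion chemistry), then genes below 2 counts per million in
strictly more than 25% of samples. Both inequalities are strict, so a gene
at exactly 2 cpm, or below threshold in exactly a quarter of the samples,
is kept.

*Normalization.* Library-size factors use the trimmed mean of M-values:
reference = sample whose upper-quartile cpm is closest to the mean upper
quartile; two-sided trims of 30% on log-ratios and 5% on average abundance;
precision-weighted mean of surviving log-ratios; factors rescaled to
geometric mean 1. The implementation is native and agrees with the standard
Bioconductor implementation to ten decimal places on shared inputs (a test
asserts this).

*Dispersion.* Genewise dispersions maximize the Cox–Reid adjusted profile
log-likelihood — the adjustment `−½ log det(XᵀWX)` removes the downward
bias of plain profiling when residual degrees of freedom are few (three, in
a 2-replicate × 4-condition design). Each gene's APL curve, evaluated on a
19-point log-spaced grid from 1e−6 to ~5 with quadratic interpolation
around the maximum, is combined with the moving average of its abundance
neighbours' curves (window = 10% of genes, at least 50), weighted
`prior_df / df_resid` with `prior_df = 10`. The neighbour average plays two
roles: it is the mean–dispersion trend, and because it pools hundreds of
genes its maximum is nearly unbiased, which is what makes the downstream
likelihood-ratio p-values uniform under the null — the property the test
suite checks (KS test on a 2,000-gene null experiment). A plain
method-of-moments genewise estimator was evaluated first and rejected: at
three residual degrees of freedom it under-estimates φ by ~20% and the LRT
becomes detectably liberal.

*Fitting.* One IRLS fit per gene (log link, offsets = log effective library
size, working weights μ/(1+φμ)), converged when the largest coefficient
change drops below 1e−6, capped at 50 iterations with a per-gene
non-convergence flag. Linear predictors are clamped to ±30 to keep
exp() finite on degenerate genes. Deviance differences between nested fits
are referred to χ² with the rank difference as degrees of freedom.

*Calling.* BH adjustment via `stats::p.adjust`; DEGs at `q < 0.01` (strict)
and `|log2FC| ≥ 0.58` (inclusive; 2^0.58 ≈ 1.5-fold). Replicate concordance
is screened by Spearman correlation against same-group partners with a
configurable 0.9 threshold; flagged samples are reported, never silently
dropped.

## Gene-set statistics

The set statistic is the Welch two-sample *t* comparing member vs
non-member log2 fold changes, with Welch–Satterthwaite degrees of freedom
and one-sided p-values per direction, BH-adjusted across sets within each
direction. This is the two-sample core of the GAGE family of methods; the
original's sample-permutation refinements are intentionally out of scope,
and group-mean fold changes (one vector per contrast) are the input
convention. Over-representation uses the exact hypergeometric upper tail
`P(X ≥ k)` with BH across sets and significance at `q < 0.05`. Sets are
intersected with the analysis universe (the post-filter gene list, not the
genome) before the 10–500 size window is applied — unannotated genes simply
drop out of the universe for that category system, as annotation coverage
statistics record. Note that the hypergeometric p-value is discrete and
therefore conservative under the null (its distribution is stochastically
larger than uniform); the tests assert conservative validity rather than
exact uniformity, which only the continuous *t* statistic can achieve.

Overlapping sigma-factor regulons (genes under multiple promoters) are kept
both as per-factor memberships and as their own composite sets, so a
σS/σD-sensitive gene contributes to `sigma_S`, `sigma_D` and
`sigma_S_sigma_D`.

## Cross-nutrient comparison

For a gene measured under two nutrient regimes, δ = |Δ_N| − |Δ_C| compares
response strengths while ignoring direction. Classification: DEG in both
with the same sign → shared; DEG in both with opposite signs and
comparable strength (|δ| ≤ band) → opposite; DEG in exactly one → that
nutrient's specific class; everything else → neither. The comparability
band defaults to 0.58 log2 units — the DEG fold threshold reused, since no
independent value is established — and is configurable. Genes absent from
either study's filtered universe are excluded from pairing rather than
imputed. δ histograms use fixed-width half-open bins ([lo, hi), default
0.25 log2 units).

## The ATP switching-cost model

The estimator prices only polymerization, in the induced direction only:
decay of down-regulated transcripts is free, and repression saves rather
than costs energy. For gene *g* with TPM shift Δtpm = max(0, tpm_PFR −
tpm_STR):

* switched copies per cell per cycle: Δm = Δtpm/10⁶ × mRNA pool (1,380
  molecules per cell by default);
* transcription: Δm × ℓ_nt × 2 ATP;
* translation: Δm × 10 proteins per transcript per cycle × ℓ_aa × 4.3 ATP;
* flux: Σ over genes × cycles/h (3600/cycle_time, cycle = τ_STR + τ_PFR ≈
  497 s) × 10¹² cells/gDW ÷ Avogadro, in mmol ATP gDW⁻¹ h⁻¹;
* reported as a percentage of the non-growth maintenance coefficient
  (3.3 mmol gDW⁻¹ h⁻¹).

Every coefficient is a `cost_model()` field and can be read from YAML. The
model is a declared reconstruction: coefficients are textbook-scale values,
the per-cycle accounting is the package's own convention, and the headline
percentages it produces on any given dataset are data outcomes, not
constants of the method. Its robust qualitative property — checked by
test — is ordering: a broad catabolic-plus-anabolic induction programme
(glucose-type response) costs more than a narrower anabolic-only programme
(ammonia-type response) under an identical cost model, and uniform scaling
of the ATP coefficients never changes the per-gene cost ranking.

## Ordination

TPM values are log2(x+1)-transformed before distance computation (raw-TPM
mode via `log = FALSE`); without the transform the handful of most abundant
transcripts dominates Euclidean distances. The 600 most variable genes by
standard deviation enter the embedding, with lexicographic gene-id
tie-breaking for determinism. Classical (Torgerson) MDS double-centres the
squared distance matrix and takes the top two eigenvectors; goodness of fit
is reported as the squared Pearson correlation between original and
embedded pairwise distances, which is exactly 1 for intrinsically planar
configurations.

Confidence ellipses assume a multivariate *t* with 7 degrees of freedom
(heavier-tailed than normal, hence outlier-resistant, while keeping finite
covariance); location and scatter come from the EM estimator in
`MASS::cov.trob`. The scatter matrix of a *t* is not its covariance, so it
is scaled by ν/(ν−2) before the F(2, n−2) radius is applied — without that
scaling the nominal 95% ellipse covers only ~91% of a large normal sample;
with it, coverage sits within the 95 ± 2% band the tests require. Collinear
point sets have a singular scatter and raise an informative error rather
than returning a degenerate ellipse. Ellipse overlap (used to ask whether
two steady-state clusters are separated) is a geometric check: mutual
center containment plus dense boundary sampling (720 vertices).

## The synthetic generator: what it emulates, and what it does not

`make_genome()` emulates a bacterial analysis universe: log-normal
transcript lengths (median ~1 kb), coding lengths consistent with
`ℓ_nt ≥ 3ℓ_aa`, ~5% residual rRNA/tRNA decoys, COG letters at roughly
*E. coli*-like marginal frequencies with ~14% unannotated, sigma regulons
with ~11% unannotated and a σS/σD composite class, and heavy-tailed
baseline expression (log-normal, σ_log = 1.2) normalized to TPM.
`make_truth()` programs block effects on regulons or explicit gene lists;
the short-term program fires only at loop ports reached after the 70 s
reaction-time onset (P3–P5, not P1–P2), the long-term program ramps
linearly to its steady state at 25 h. `simulate_counts()` draws NB counts
with genewise dispersions log-normal around a median φ (σ_log = 0.3) and
uniform library sizes, defaulting to 0.9–1.1 million reads — a deliberate
10× scale-down of typical study depth for desk-scale runtimes; the range is
a parameter and the test of recovery power runs at full study depth
(7.6–10.4 million).

What passing tests demonstrate: the pipeline is calibrated (≤ nominal false
discoveries, uniform null p-values) and powerful (≥ 80% recovery of 1.5
log2-unit blocks at φ = 0.05) *when the NB model is true*, and every
deterministic computation matches closed forms or independent references.
What they cannot demonstrate: robustness to features real data have and the
generator lacks — correlated genes within operons, sample-level batch and
process-time drift beyond the programmed ramp, count outliers of the kind
replicate screening exists for, and mapping/annotation artefacts. The
generator is a calibration instrument, not an estimate of biological
effect-size distributions.

## Problem sizes and numerical conventions

The test suite and examples use 2,000-gene genomes with 2 replicates ×
3–4 conditions (the calibration checks), 100–500 genes elsewhere, 20-seed
replication for stochastic physics checks, and 3,000-point samples for
coverage simulation; the full suite runs in under two minutes on one core.
Root finding uses `uniroot` at 1e−12 tolerance; IRLS converges at 1e−6 on
coefficients; dispersions are floored at 1e−8; TPM columns sum to 10⁶ to
within 1e−6 relative error. Ties in variance ranking break
lexicographically; all generators are pure functions of their parameters
and a seed, and restore the caller's RNG state.

## Known limitations

* The DE engine targets calibration-level agreement with the NB/LRT
  framework, not coefficient-level replication of any specific external
  package's shrinkage defaults (quasi-likelihood F-tests and robustified
  outlier weighting are out of scope).
* The dispersion model of the reactor is one-dimensional; no CFD or
  compartment-network hydrodynamics, oxygen transfer or Monod kinetics.
* The ATP model ignores degradation/turnover costs by default and treats
  the translation burst per transcript as a single configurable constant.
* Reported maintenance percentages, DEG counts and MDS R² on synthetic
  data depend on the programmed truth; they are illustrations of the
  machinery, not reproductions of any particular experimental dataset.
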