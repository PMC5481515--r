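# strpfr

Analytics for **STR-PFR scale-down bioreactor studies**: continuously run
two-compartment systems in which a stirred tank reactor (STR, nutrient-limited
but well mixed) feeds a plug-flow loop (PFR) where cells transiently starve
before returning — a laboratory mimic of the substrate gradients of
large-scale fermenters. The package is aimed at bioprocess and microbial
systems-biology groups who run such experiments (e.g. *E. coli* under
fluctuating ammonia or glucose supply) and need the complete downstream
analysis from reactor physics to transcriptome statistics.

## What it computes

**Reactor characterization.** Compartment residence times `τ = V/F`;
residence-time-distribution (RTD) moments of tracer curves by trapezoidal
quadrature (`τ = ∫tE(t)dt`, `σ²_θ = σ²/τ²`); the Bodenstein number from the
closed-vessel axial-dispersion relation

```
σ²_θ = 2/Bo − (2/Bo²)(1 − e^(−Bo))
```

inverted by bracketed root finding; substrate depletion times `c/q` under
zero-order uptake; and the effective growth rate when growth is confined to
the substrate-containing zone, `μ_zone = μ_avg (V_STR + V_PFR)/V_growth`.

**Differential expression.** A native negative-binomial engine for gene-level
count matrices: rRNA/tRNA and low-coverage filtering (`< 2` counts per
million in `> 25%` of samples), TMM normalization, TPM, genewise dispersions
by Cox–Reid adjusted profile likelihood with empirical-Bayes shrinkage
toward an abundance trend, per-gene NB log-linear IRLS fits
(`var = μ + φμ²`, log link, library-size offsets), likelihood-ratio
contrasts, Benjamini–Hochberg FDR, DEG calling at `q < 0.01` and
`|log2FC| ≥ 0.58` (1.5-fold), and Spearman replicate-concordance screening.

**Gene-set analytics.** Welch two-sample *t* set statistics (set members vs
the rest of the analysis universe, per-direction BH) and hypergeometric
over-representation `P(X ≥ k)`, with the 10–500 member size window and
COG/sigma-regulon collections in GMT format.

**Cross-nutrient comparison.** The response-strength statistic
`δ = |log2 Δ_N| − |log2 Δ_C|`, Venn-style classification of genes into
shared / opposite / nutrient-specific groups, and δ histograms.

**ATP switching cost.** Converts STR→PFR TPM shifts into newly synthesized
transcript copies per cell per circulation cycle, prices them at ~2 ATP per
transcribed nucleotide and ~4.3 ATP per polymerized amino acid, and expresses
the resulting flux as a percentage of non-growth maintenance
(`m_ATP` = 3.3 mmol gDW⁻¹ h⁻¹ by default).

**Ordination.** Top-600 variable genes, classical (Torgerson) MDS on
Euclidean distances with distance-correlation `R²`, and robust 95%
confidence ellipses under a multivariate-*t* scatter model.

**Synthetic data.** `make_genome()`, `make_truth()` and `simulate_counts()`
generate complete synthetic STR-PFR experiments (annotation, regulon
blocks, programmed fold-change truth with a 70 s onset along the loop,
NB counts) so the entire pipeline is testable without downloads.

## Worked example

```r
library(strpfr)

reactor_summary(reactor_config())
#> STR-PFR system summary
#>   tau_STR               368.4 s
#>   tau_PFR (total)       125.0 s
#>   cycle time            493.4 s
#>   STR volume share       74.7 %
#>   depletion time         44.6 s
#>   mu (growth zone)      0.239 1/h
```

The loop spends 125 s per pass; residual ammonia (2.5 mg/l at an uptake of
0.056 mg l⁻¹ s⁻¹) is gone after ~45 s, so two thirds of the loop is a
starvation zone and growth in the remaining volume runs at 0.24 h⁻¹ rather
than the average 0.2 h⁻¹.

```r
cv <- simulate_dispersion_rtd(Bo = 84, tau_mean = 125, noise_sd = 0.01, seed = 42)
m  <- rtd_moments(cv)
m$bodenstein <- bodenstein_from_variance(m$sigma2_theta)
m
#> RTD: tau = 125.00 s, sigma2 = 367.44 s^2, sigma2_theta = 0.02352, Bo = 84.0
```

A synthetic experiment with a nitrogen-stress program (σN regulon up 1.5
log2 units after the 70 s onset, ribosomal COG J down 1.0):

```r
genes  <- make_genome(2000, seed = 1)
truth  <- make_truth(genes, short_effects = list(sigma_N = c(+1, 1.5),
                                                 J = c(-1, 1.0)), seed = 2)
design <- make_design(str_times = c(0, 28), pfr_times = 28, ports = c("P3", "P5"))
exp1   <- simulate_counts(genes, design, truth, phi = 0.05, seed = 3)
nexp   <- normalize_experiment(filter_genes(exp1))
res    <- de_contrast(nexp, "P5_28h", "S_28h")
res
#> contrast P5_28h_vs_S_28h: 1896 genes tested, 78 DEGs (56 up / 22 down)

col <- size_filter(gene_set_collection(gene_sets_from_annotation(genes),
                                       res$gene_id))
gt  <- gage_t(col, setNames(res$log2FC, res$gene_id))
head(gt[order(gt$p_up), c("set", "size", "t", "q_up")], 1)
#>     set size        t         q_up
#> sigma_N   83 14.67668 8.867151e-24
```

The programmed σN induction dominates the set statistics, as a stringent /
Ntr-type response would in real data. Ordination and the switching-cost
estimate from the same experiment:

```r
mds_expression(nexp$tpm, top = 600)
#> classical MDS: 8 samples, R2 = 0.928

atp_switching_cost(nexp$tpm,
  str_samples = nexp$samples$sample_id[nexp$samples$group == "S_28h"],
  pfr_samples = nexp$samples$sample_id[nexp$samples$group == "P5_28h"],
  genes = nexp$genes)
#> switching cost: 2.94e+06 ATP/cell/cycle = 0.0354 mmol/gDW/h = 1.07% of maintenance
```

i.e. switching this particular induced program on every 8-minute cycle
would add about 1% to the cell's non-growth ATP maintenance demand.

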