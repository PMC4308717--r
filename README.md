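# xconstraint

Detection of evolutionarily constrained gene expression and splicing from
two-species comparative RNA-seq panels.

## The problem

When the same gene is quantified across many cell types in two species
(e.g. human and mouse), most genes vary widely — but a large class of
orthologues keeps its expression within a narrow band across *every*
sample of *both* species. These genes are under evolutionary constraint on
their expression level, and an analogous class of splice junctions is
constrained in its inclusion level. `xconstraint` provides the estimators
to find both classes, the replicate-reproducibility filter that precedes
them, and the genome-signal analyses that characterise them, for anyone
analysing matched cross-species expression panels.

## The statistics at its core

* **DNR (dynamic range)** of an orthologous gene pair: pooling the
  non-zero, reproducibility-filtered RPKM over all samples of both
  species,
  `DNR = log10(max RPKM) − log10(min RPKM)`,
  defined only for genes detected in ≥ 2 samples per species. The DNR
  distribution over a panel is bimodal; a two-Gaussian EM fit places the
  constrained/unconstrained threshold at the intersection of the weighted
  component densities (`fit_dnr_mixture()`, an S3 model object with
  `print`/`coef`/`predict`/`plot` methods).
* **npIDR**: a non-parametric irreproducible discovery rate — the
  signal-binned fraction of elements detected in exactly one of two
  replicates, made monotone in signal; elements with npIDR ≤ 0.1 keep the
  replicate mean, others are zeroed.
* **ψ / θ (intron-centric splicing metrics)**: percent-spliced-in from
  donor-side, acceptor-side and pooled split-read counts, and the
  completeness-of-splicing index against exon–intron boundary reads;
  junctions with intermediate mean inclusion and variance ≤ 20% of the
  Bernoulli maximum `m(1−m)` are constrained in splicing.
* **Vls/Vt**: per gene, the fraction of transcript-abundance variance
  explained by a constant-splicing model (a ray in transcript space, on
  square-root-rescaled abundances), bootstrap-stabilised; 1 = purely
  expression-driven, 0 = purely splicing-driven.
* **Bin and metagene conservation**: cross-species correlation of log10
  read density in orthologous 100-nt bins, stratified by region class /
  distance to gene / conservation score, and max-normalised metagene
  profiles around TSS/TTS with per-gene cross-species divergence
  `|Δ log10 signal|`.

A seeded synthetic-data module (`sim_config()`, `simulate_*()`) generates
every input with known truth, so the whole pipeline is testable offline.

## Worked example

```r
library(xconstraint)
cfg <- sim_config(n_genes = 1000, n_samples = 10)
sim <- simulate_expression(cfg, seed = 1)
dnr <- compute_dnr(sim$m1, sim$m2, sim$orth)
fit <- fit_dnr_mixture(dnr$dnr[!is.na(dnr$dnr)], seed = 1)
fit
#> Two-component Gaussian mixture of DNR values
#>   n = 996, log-likelihood = -902.28 (21 EM iterations)
#>   component 1 (constrained-like):   w = 0.456, mu = 1.108, sigma = 0.101
#>   component 2 (unconstrained-like): w = 0.544, mu = 3.303, sigma = 0.774
#>   density-intersection threshold: DNR = 1.4219
calls <- classify_constraint(dnr, fit$threshold)
table(calls$call)
#>   constrained unconstrained     undefined
#>           460           536             4
```

The fitted mixture finds the low-DNR component (genes varying ~1.1 orders
of magnitude across 40 samples and two species) against the wide-range
component (~3.3 orders), and the intersection threshold classifies genes
at 99.7% agreement with the generator's truth on this panel. Four genes
are `undefined` — detected in fewer than two samples in one species — and
belong to neither class. `run_pipeline(seed = 1, outdir = "out")` runs
every stage (replicate filtering, matching, ANOVA, junction ψ/θ, Vls/Vt,
bin and metagene conservation) and writes TSV/JSON outputs.

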