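---
title: "Methods: activity-informed keystone-taxon analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-informed keystone-taxon analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models and
procedures, the assumptions behind them, the parameters that matter, and
the places where the design was genuinely open and a choice had to be made.
Numerical claims about behaviour (recovery rates, calibration, determinism)
are exactly those computed by the test suite and `scripts/acceptance.R`;
nothing stated here goes beyond what that code measures.

## The data model

The workflow operates on two sample × taxon count matrices over the same
taxa — genome abundances (the DNA layer) and transcript counts mapped to
the same genomes (the RNA layer) — plus per-sample metadata: depth (m),
month, oxygen regime (oxic / anoxic / oxycline) and a continuous
environmental profile from a sonde cast (water temperature °C, dissolved
oxygen mg/L and % saturation, specific conductivity µS/cm, pH, chlorophyll,
phycocyanin and fDOM fluorescence in RFU, turbidity FNU, sampling time).
Counts are compositional: sequencing depth is arbitrary, so only relative
information is meaningful. Every transform in the package exists to deal
with that constraint.

## Normalisations

* **TSS** divides each sample by its total; rows sum to 1. Used for
  correlation screening and the per-condition top-10 prevalence report.
* **Hellinger** takes the square root of the relative abundance, tempering
  the dominance of abundant taxa before Bray–Curtis. It depends only on
  within-sample proportions, so it gives identical output on raw or
  TSS-scaled input (a property the tests assert).
* **CLR** maps each composition to unconstrained coordinates,
  `ln(x + c) − mean ln(x + c)`. The pseudocount `c` defaults to 1 on raw
  counts — the usual convention when zeros are present — and `c = 0` makes
  the transform exactly scale-invariant, which the tests use as an
  invariant. A zero-total sample is a hard error everywhere: silently
  dropping a sample would corrupt the PERMANOVA design downstream.
* **Min–max** scales each environmental predictor to [0, 1] so that
  heterogeneous units cannot dominate the penalised regressions. A constant
  predictor maps to zero with a warning rather than dividing by zero.

## Community analysis

Bray–Curtis dissimilarities are computed on Hellinger-transformed counts
and ordinated by classical scaling (PCoA): the squared distance matrix is
Gower-centred and eigendecomposed; coordinates are eigenvectors scaled by
the square roots of the positive eigenvalues. Negative eigenvalues —
expected for semi-metric dissimilarities — are reported but excluded from
the percentage of variance explained. On genuinely Euclidean input the
coordinates reproduce the distances to 1e-9, which the tests assert as the
classical-scaling identity.

PERMANOVA uses sequential (Type-I) partitioning in the order the terms are
given, mirroring the conventional implementation; term order is the user's
responsibility. Significance uses raw-label permutations with the +1
convention, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, with 999 permutations by
default. When the permutation group is small enough the backend enumerates
the complete set, so the toy 6-sample case in the tests is compared against
an independent exhaustive-enumeration oracle. One consequence worth knowing:
with balanced two-group designs every relabelling that reproduces the same
partition has the same pseudo-F, so the attainable p floor is set by the
partition multiplicity, not by `1/(n_perm+1)`.

Pairwise PERMANOVA reports raw p-values (the convention for these tables);
a Benjamini–Hochberg column is emitted alongside for reference but is not
used for decisions. Levels with fewer than two samples are skipped with a
warning.

The top-10 prevalence report ranks taxa per condition by mean relative
abundance, descending, with ties broken deterministically by taxon id (a
tie at the cut is logged). `Presence_Count` is the number of conditions (of
11 in the reference design) in which a taxon makes the top 10, and
`Bar_Percent = Presence_Count / n_conditions × 100` exactly.

## Co-occurrence network: glasso + StARS

The network stage CLR-transforms the counts, takes the **correlation**
matrix of the CLR coordinates, and estimates a sparse precision matrix by
graphical lasso (block coordinate descent over columns of the working
covariance, implemented in C++ with warm starts along the penalty path).
Correlation rather than covariance puts all taxon pairs on one scale so a
single penalty treats them comparably — the convention of the established
sparse-network packages. The penalty path is 30 log-spaced points from the
largest absolute off-diagonal down to 1% of it.

StARS selects the penalty: 50 random subsamples (fraction 0.8 for n ≤ 144,
`10√n/n` above), edge-selection instability `mean 2ξ(1−ξ)` per penalty,
monotonised from the sparse end, and the smallest penalty whose monotonised
instability stays within β = 0.05 — the densest graph that is still
reproducible under subsampling. Edge weights are signed partial
correlations from the selected precision matrix; degree centrality (edge
count) ranks the taxa and the top 15 proceed to the chain graph. Ties in
degree are broken by taxon id so reports are deterministic.

At the simulated study scale (n = 200, p = 60) the acceptance tests measure
roughly 75–80% recovery of planted edges at a classical false-positive rate
around 2%; the false-discovery share of the selected graph sits near
30–40%, with the best single penalty on the path (the knee of the operating
curve) reaching ~70% recovery at 17–27% false discoveries. StARS with
β = 0.05 selects one step denser than that knee here — a known property of
stability selection, which privileges reproducibility over parsimony.

## The chain graph

The covariate-aware stage is a penalised-likelihood Gaussian chain graph:
responses are `ln(count+1)` of the selected taxa (the log option for skewed
abundances; pseudocount fixed at 1), predictors the min–max-scaled sonde
variables (nine by default: depth, wtemp, do_raw, sp_cond, pH, chlor_rfu,
phyco_rfu, fdom_rfu, turb_fnu). Each response is lasso-regressed on the
predictors (coefficient matrix **B**), and the residual precision **Ω** is
estimated by graphical lasso. Edges follow the chain-graph semantics:
directed predictor→taxon links weighted by the coefficient, undirected
taxon–taxon links weighted by the residual partial correlation; no
predictor–predictor edges. Both penalties default to BIC selection over a
small grid; fixed values are accepted for reproducible refits (the
robustness ensembles refit with a fixed configuration).

This is a deliberate frequentist surrogate for the Bayesian adaptive-
shrinkage chain graph used in this literature: deterministic, desk-scale,
and carrying the same graph semantics. The posterior sampler is out of
scope and is an extension point; all validation is by parameter recovery —
a single planted environmental effect of one latent log-unit per predictor
SD is recovered with the correct sign in 50/50 seeded runs at n = 200, and
under a null with no effects fewer than 10% of predictor–taxon
coefficients exceed 0.1 in magnitude.

## The connectivity robustness index

For a focal taxon, the ensemble draws 14 companions uniformly without
replacement (100 runs by default; companion draws are independent across
runs and layers, each run seeded from the master seed by a counter-based
derivation), refits the chain graph, and thresholds that run at the 90th
percentile (linear-interpolation quantile) of the absolute weights over all
of the run's edges. A run is flagged when the focal taxon holds at least
one edge *strictly* above the threshold — strict, so a degenerate
all-equal-weights graph flags nothing; and "at least one", because the
source procedure does not define a multiplicity rule (the per-run flagged
count is retained for diagnostics). The index is the flagged percentage,
0–100%. Comparing the DNA and RNA indices against a 30% reporting cutoff
classifies the taxon: the cutoff is a convention chosen to separate the
contrast this analysis is designed around (indices in the 40s versus
around 10), is exposed in configuration, and raw indices are always
reported alongside.

Two properties anchor the index's correctness in the tests: under a fully
null community (diagonal precision, no environmental effects) the index
matches a brute-force exchangeability oracle computed on the same fitted
graphs, and raising the threshold quantile never increases any run's
flagged count.

One small-sample caveat the 16-sample demo exposes: with few samples and
collinear predictors, BIC-selected regression coefficients can be large
and unstable, and since predictor→taxon weights (log-units per predictor
range) and taxon–taxon weights (partial correlations, bounded by 1) share
the threshold pool, the environmental edges can dominate the top decile
and drive indices toward zero for taxa without strong environmental links.
`threshold_pool = "taxon-taxon"` restricts the pool to biotic edges when
that is a concern; at n = 200 the pooled default behaves as intended.

## The synthetic generator

The generator exists so every stage has a planted ground truth. It
emulates a seasonally sampled stratified lake:

* **Design.** Fixture mode reproduces the reference 16-sample grid exactly
  — depths 5/10/15/23.5 m with group sizes 2/2/6/6, July–October with
  3/6/2/5, oxygen regimes 4/9/3, eleven condition groups in total. General
  mode draws any number of samples from the same grid with depth-consistent
  oxygen regimes.
* **Network.** A sparse support of hub-and-spoke (default 3 hubs of degree
  8) plus a capped random background (mean degree 2) receives signed edge
  magnitudes drawn from [0.2, 0.5]. Positive definiteness is enforced by a
  uniform diagonal shift past the most negative eigenvalue of the edge
  matrix. The shift, rather than row-wise diagonal dominance, is what keeps
  every edge at a comparable realised partial correlation (~0.17–0.42): a
  degree-8 hub cannot carry eight partial correlations of 0.2–0.5 (the row
  mass would exceed 1), and a row-wise dominant diagonal dilutes precisely
  the hub edges the recovery tests need to see.
* **Counts.** Logistic-normal-multinomial: the latent per-sample
  log-abundance field is multivariate normal with covariance Θ⁻¹, shifted
  by the planted environmental effects, pushed through a softmax and
  sampled multinomially with log-normal library sizes (median 10⁴). The
  planted precision matrix is therefore the literal ground truth of the
  latent layer, which makes glasso recovery a well-posed oracle test.
* **Environmental effects** act on the hub taxa (two predictors each by
  default, strength 1) and are parameterised per standard deviation of the
  scaled predictor, so "strength 1" always means one latent log-unit per
  predictor SD regardless of how the sampling design spreads that
  predictor. The sonde profiles carry roughly half variable-specific
  variance on top of the shared depth/season/oxygen structure so that
  planted effects are statistically identifiable.
* **RNA layer.** A fraction (default 0.3) of the DNA support is re-wired by
  degree-preserving double-edge swaps and given fresh magnitudes — the same
  taxa with a partly different network, so a taxon can be abundant yet
  transcriptionally quiet. Re-wiring rather than independent regeneration
  isolates exactly that contrast.
* **Taxonomy.** GTDB-like records whose resolution declines toward finer
  ranks (defaults mimic a catalogue where nearly all records resolve to
  order but only ~10% to species); a single uniform variate per record
  against non-decreasing unknown rates makes unknown-ness automatically
  monotone down the hierarchy.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: phylogenetic signal in the counts, taxon-specific
overdispersion beyond the logistic-normal level (the real data's
overdispersion is uncharacterised; library-size parameters are exposed in
the config), genuinely collinear environmental profiles (real lake sonde
variables co-vary far more strongly than the generator's, so
predictor-level attributions on real data deserve more caution than the
sign-recovery rates here suggest), and any sequence-level process.

## Seeding and determinism

All randomness flows from one integer master seed. Stages derive
independent streams with a small polynomial hash of a text tag
(`derive_seed(seed, "counts_dna")`, `derive_seed(seed, "run_17")`), kept
below 2³¹; RNG state is restored after every seeded block. Identical
configuration and seed reproduce every output file byte for byte, which
the acceptance suite asserts over the full pipeline.

## Problem sizes used by the tests

The test suite validates at sizes chosen to pin each property with
comfortable margins: normalisation and geometry oracles on toy matrices;
PERMANOVA against exhaustive enumeration at n = 6 and calibration over 500
null simulations of 18 samples; network recovery at n = 200, p = 60 with
StARS at 50 subsamples; chain-graph recovery over 50 seeds at n = 200;
keystone discrimination over 50 replicates of 20-run ensembles; and the
full 16-sample pipeline twice for determinism. The acceptance script runs
the same computations once at the same scales and writes the headline
numbers as JSON.

## Known limitations

* The chain graph is a point-estimate surrogate; it reports all nonzero
  penalised estimates and provides no credible intervals or posterior
  edge probabilities.
* Degree is the only centrality implemented — by design, as it is the
  selection criterion this workflow defines — so betweenness- or
  eigenvector-based robustness variants are out of scope.
* The index has no analytical null; calibration is by simulation and the
  exchangeability oracle only.
* Bray–Curtis and PCoA are the only ordination route; no NMDS, db-RDA or
  dispersion tests.
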