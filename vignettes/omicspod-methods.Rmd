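---
title: "Benchmark-dose modeling and mechanistic points of departure with omicspod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose modeling and mechanistic points of departure with omicspod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

omicspod turns a pre-normalized feature-by-sample omics matrix measured at
multiple doses into gene-level benchmark doses (BMD), transcriptome-wide
points of departure (twPOD), co-dose-dependency networks, and adverse
outcome pathway (AOP) enrichments. This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic validation does and does not show
about real data.

## Input model and assumptions

The unit of analysis is one omics layer: a numeric matrix (features x
samples) with per-sample dose, condition and time point. Analysis always runs
within one (condition, timepoint) stratum; strata are processed independently
and never share information. The core assumptions are:

* **Pre-normalized, approximately homoscedastic responses.** Fitting is
  ordinary (unweighted) least squares with i.i.d. Gaussian errors. Inputs
  should be on a variance-stabilized scale (log-intensity, VST counts,
  M-values); raw counts violate the error model and are out of scope.
* **A dose-0 control and at least three distinct dose levels per stratum** —
  the minimum for fitting curvature. Validation rejects designs below this.
* **Complete per-feature dose series.** Features with missing values are
  dropped at load (default policy) or the load aborts.

## Prefiltering

Features unlikely to respond to dose are removed before curve fitting.
Three methods are provided:

* `anova_filter()` — one-way fixed-effects F test across dose groups
  (default, nominal p < 0.05, unadjusted). A pre-filter should be permissive:
  its job is to cut the fitting workload, not to control the final error
  rate, which is governed downstream by fit quality (R²) and enrichment FDR.
  Benjamini–Hochberg adjustment is available as an option.
* `trend_filter()` — the Jonckheere–Terpstra test against an ordered
  alternative, two-sided (the smaller one-sided tail doubled, capped at 1).
  For strata with at most 12 samples the exact null distribution is used:
  via the Mann–Whitney convolution (Gaussian-binomial) algorithm when the
  feature has no tied values, or by enumerating group-label assignments when
  ties are present and the assignment count is small; otherwise the normal
  approximation with tie correction.
* `moderated_trend_filter()` — a linear trend test with empirical-Bayes
  variance moderation: the ensemble of per-feature residual variances
  determines a prior (d0, s0²) by moment matching on the scaled-F
  distribution, each feature's variance is shrunk to
  (d0·s0² + d·s²)/(d0 + d), and the slope t statistic uses d0 + d degrees
  of freedom. With d0 = 0 this is the ordinary t-test; with d0 = Inf all
  features share the pooled variance.

## The dose-response model family

Eight mean functions cover the shapes routinely used in toxicogenomic
benchmark-dose analysis:

| name   | f(d; θ)                       | parameters |
|--------|-------------------------------|------------|
| linear | a + b·d                       | a, b |
| power  | a + b·d^g                     | a, b, g ∈ [0.5, 18] |
| hill   | a + b·d^g / (k^g + d^g)       | a, b, k > 0, g ∈ [0.5, 18] |
| exp2   | a·e^{b·d}                     | a, b |
| exp3   | a·e^{s·(d/b)^g}               | a, b > 0, g; s = ±1 fixed from the data trend |
| exp4   | a·(c − (c−1)·e^{−d/b})        | a, b > 0, c > 0 |
| exp5   | a·(c − (c−1)·e^{−(d/b)^g})    | a, b, c, g |
| poly2  | a + b₁·d + b₂·d²              | a, b₁, b₂ |

The exponent lower bound of 0.5 for power and Hill avoids infinite slope at
dose 0, which otherwise produces degenerate BMD estimates; the bound is
part of the registry defaults and can be relaxed by supplying a custom
family.

**Fitting.** Linear and quadratic models are solved in closed form. The
nonlinear models use bounded L-BFGS-B from 5 deterministic data-driven
starts plus 5 seeded random starts; the best solution is then polished at a
much tighter tolerance (`factr = 10`, finite-difference step 1e-7), which is
necessary for the optimizer to reach the least-squares optimum to the
precision the BMD inversion requires. Parameter bounds scale with the dose
range and response amplitude, making fits equivariant to rescaling the dose
axis. Fit quality is summarized by R² = 1 − RSS/TSS (defined as 0 for flat
features with TSS = 0) and the Gaussian AIC n·ln(RSS/n) + 2(p+1), with the
error variance counted as a parameter and the additive constant omitted —
only AIC differences matter.

## BMR, BMD, and bounds

The benchmark response (BMR) defines "how much change counts". Three kinds
are supported, all measured from the fitted baseline f(0):

* **relative** (default, r = 0.1): target = baseline·(1 ± r);
* **absolute** (A in response units): target = baseline ± A;
* **sd** (k control standard deviations): target = baseline ± k·SD(controls).

The sign follows the response direction; under the default `auto` policy the
direction is the sign of f(d_max) − f(0). The BMD is the smallest dose in
(0, d_max] at which the fitted shift reaches the target, found by scanning
1024 uniformly spaced grid points and bisecting the bracketing interval to a
relative tolerance of 1e-8. A curve that never reaches the shift within the
tested range yields status `no_crossing`, not an extrapolated dose: BMDs are
never reported beyond the highest tested dose.

**BMDL/BMDU** come from a residual bootstrap: residuals are centered,
inflated by sqrt(n/(n−p)) to undo the variance deflation of least-squares
residuals, resampled with replacement (default B = 250), the model refit,
and the BMD re-solved; the 2.5th/97.5th percentiles of the bootstrap BMDs
are the bounds, reported only when at least half the replicates succeed.
Without the inflation the intervals are systematically narrow at small n;
with it, empirical coverage over 200 simulated Hill genes at the default
6-level x 3-replicate design with noise SD 0.1 was 90–92% for a nominal
95% interval — adequate for screening, and the residual shortfall (the
estimator's own bias on saturating curves) is documented rather than hidden.

**Selection vs averaging.** Fits with R² < 0.6 are excluded. `AIC` mode
takes the minimum-AIC survivor. `average` mode combines survivors with
Akaike weights w_i ∝ exp(−ΔAIC_i/2); BMD, BMDL and BMDU are the weighted
arithmetic means. A gene is dose-dependent (DDG) iff at least one survivor
remains. Optional precision filters (BMDU/BMDL ratio, BMD/BMDL ratio) are
off by default.

## Transcriptome-wide points of departure

`bmd_distribution()` summarizes the DDG BMDs: an ECDF, plus a Gaussian KDE
on log10(BMD) (doses span decades, so density estimation belongs on the log
scale) with Silverman's rule-of-thumb bandwidth on a 512-point grid. Modes
are local maxima; antimodes are the minima between consecutive modes.

`twpod()` offers five summaries:

* `percentile` (default q = 5, linear interpolation between closest ranks) —
  the conservative, robust choice for tier-1 prioritization;
* `mean_lowest_n` (default n = 20);
* `first_mode` — the dose at the first KDE mode;
* `accumulation_curvature` — restrict BMDs below the first antimode, build
  the accumulation curve (sorted BMD vs cumulative count, both min-max
  normalized so the construction is unit-invariant), and return the BMD at
  the point of maximum discrete curvature |x′y″ − y′x″|/(x′² + y′²)^{3/2}
  with central differences. When the BMD distribution is unimodal there is
  no antimode to split sensitive from insensitive genes; the method then
  falls back to the full BMD set and flags the result, because the antimode
  is the critical parameter of this method and its absence makes the twPOD
  unreliable (typically an underestimate);
* `lowest_geneset` — the minimum over enriched gene sets of the median
  member BMD.

Whether to summarize BMD or BMDL values is a user choice; BMD is the
default and BMDL can be supplied instead.

## Co-dose-dependency networks

`predict_grid()` evaluates each DDG's selected model (or Akaike-weighted
mixture) on 1000 uniformly spaced doses from 0 to the maximum tested dose.
`correlate_pairs()` computes the Pearson correlation between predicted
curves with a two-tailed t p-value at N − 2 degrees of freedom, N being the
grid size. **Caveat:** grid points are model predictions, not independent
observations, so these p-values are a reporting convention for ranking pair
strength, not calibrated hypothesis tests; interpret them relatively.

`cluster_genes()` uses hierarchical agglomerative clustering with distance
1 − r and average linkage; k is chosen by maximum mean silhouette over
k ∈ 2..10 unless fixed. `overlay_ppi()` marks known PPI pairs (never
inferring new ones), flags transcription factors, and computes degree,
harmonic closeness (sum of reciprocal shortest-path distances, normalized
by n − 1, so disconnected nodes contribute 0) and eigenvector centrality
(power iteration to 1e-10 per connected component on the shifted adjacency
A + I, max-normalized globally) on the PPI subgraph induced by the analyzed
genes. `cross_layer_correlation()` correlates the expression and
methylation curves of each shared gene and classes them inverse (r ≤ −0.5)
or concordant (r ≥ 0.5).

## AOP enrichment, networks, and hazard rollup

`fisher_enrich()` is the one-tailed over-representation test: P(X ≥
overlap) with X hypergeometric, BH-adjusted, enriched at FDR < 0.05. The
default universe is every analyzed feature carrying at least one KE
annotation — enrichment should ask "among genes that could have mapped,
which events concentrate the dose-dependent ones", and an all-features
universe would inflate every KE. KE and AOP tests each get a single global
BH pass rather than per-AOP correction, the simpler and more conservative
reading.

`build_ke_network()` assembles the mechanism map: enriched KEs plus
*connectors* — KEs on at least one shortest directed KER path from any MIE
to an enriched KE, or from an enriched KE to any AO, within the KER graph
restricted to the AOPs containing that enriched KE. Shortest paths (rather
than all simple paths) keep the connector set interpretable and the
computation polynomial; the intent is to show how enriched events plug into
initiating events and outcomes, not to enumerate every causal route. Each
node carries the mean BMD of its mapped DDGs (DDGs only — the network
describes the dose-dependent mechanism, and non-responsive mapped genes
would dilute the dose anchoring).

`aop_detail()` renders one AOP: per-KER PPI bundle weights (count of
interacting protein pairs between consecutive KEs' DDGs), TF-to-target
edges across consecutive KEs, per-KE mean BMD, and the top genes per KE.
`prioritize_genes()` ranks mapped genes by six criteria — TF status, PPI
degree, harmonic closeness, eigenvector centrality, mean |r| to the other
mapped genes, and BMD (lower better) — as unweighted mean of dense ranks
(no criterion weighting is defensible a priori; the mean of ranks is
scale-free and transparent), ties broken by lower BMD then gene id, top 5
returned by default.

`hazard_rollup()` counts enriched AOPs per hazard class (nine CLP/GHS-style
classes by default, overridable; unannotated AOPs accumulate under
"unclassified") and reports per-AOP tPODs as the median BMD of DDGs mapped
to the AOP's enriched KEs (median rather than mean for robustness to the
right-skew of BMD distributions; mean available as an option).

## The synthetic study generator

`generate_fixture()` emits every input the pipeline reads, with known
ground truth. Defaults describe a typical in vitro design: 6 dose levels
{0, 1, 2.5, 5, 10, 20} x 3 replicates; 100 genes of which 20 are
dose-responsive (Hill-shaped by default) and 80 flat; homoscedastic
Gaussian noise with SD 0.1 on log-scale responses (roughly the residual
spread of well-normalized expression data); an AOP scaffold of three
four-event chains in which one planted KE concentrates 75% of the
responsive genes; a PPI network densified among the planted genes; a small
TF table; and an optional methylation layer whose curves mirror (inverse)
or copy (concordant) the expression curves. True BMDs come from closed-form
inversion of the generating model (numeric bisection to 1e-12 where no
closed form exists) — an oracle independent of the fitting code.

What the generator deliberately does **not** emulate: count noise and
mean-variance dependence (inputs are post-normalization by contract), probe
or mapping noise, correlated errors between genes, batch structure, and
partially overlapping mechanisms. Passing the planted-mechanism tests
therefore demonstrates that the machinery is correct under its stated
assumptions, not that any particular real exposure will be recovered.

## Validation problem sizes

The shipped checks use: noiseless closed-loop recovery at the default 6x3
design (tolerance 1e-6 relative); 200 simulated noisy Hill genes with
B = 250 bootstrap replicates for calibration; an exhaustive sweep of every
hypergeometric table with universe up to 60 against explicit
binomial-coefficient summation; 500 random DAGs of up to 12 nodes against
brute-force path enumeration for the connector logic; and 20 seeded
end-to-end runs of the planted-mechanism study. These sizes were chosen so
the full suite exercises every contract in a few minutes on one core.

## Known limitations

* Heteroscedastic errors are not modeled; results on strongly
  mean-variance-coupled data will be less precise (use VST upstream).
* Bootstrap BMD intervals undercover mildly (~90–92% for nominal 95%) on
  saturating curves at small n; treat BMDL as a screening bound, not an
  exact confidence limit.
* The curve-correlation p-values inherit the fixed-N grid convention and
  are not calibrated tests (see above).
* AOP knowledge tables are a static user-supplied snapshot; no live
  retrieval or curation is attempted.
* Cross-layer joining is by exact feature id; promoter regions must be
  pre-mapped to gene ids upstream.
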