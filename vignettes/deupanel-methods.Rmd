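---
title: "Methods: duplicate-panel QC, symbolic trajectories and tied-covariance modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplicate-panel QC, symbolic trajectories and tied-covariance modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deupanel)
```

## The measurement model

The pipeline targets panels in which each gene is measured as a
*technical duplicate* (x₁, x₂) of copy-number counts at four deuterium
concentrations — 40, 80, 150 and 300 ppm — with 150 ppm as the
physiological control. With only two replicates, a classical sd/mean
coefficient of variation is unstable; dispersion is instead summarized
by the dimensionless statistic

> CV = |x₁ − x₂| / (x₁ + x₂) ∈ [0, 1].

We take the absolute value: a dispersion measure must be nonnegative,
and no downstream quantity uses the sign of the replicate difference.

A gene's response is its **ratio profile** (r₄₀, r₈₀, r₃₀₀), the mean
duplicate count at each non-control concentration divided by the mean
control count. Ratios of means (rather than means of per-replicate
ratios) match the copy-number-averaging convention of the QC thresholds
below.

## QC filtering

Each ratio is a quotient of two noisy measurements, so its relative
error combines the two CVs. The package defaults to quadrature,

> err(r_c) = √(CV_c² + CV_ctrl²),

the standard first-order propagation for a quotient of independent
measurements; a linear sum (`error_method = "linear"`) is available as a
conservative alternative, since with only duplicate counts the
independence assumption cannot be verified from the data. The three
per-ratio errors are *summed* into a per-gene total, and genes are
excluded when

* total error > 0.55 (`max_total_error`), or
* mean control count < 20 copies (`min_copies`), or
* (optionally) the gene is absent from a user-supplied consensus list.

Thresholds are strict inequalities: a gene exactly at a threshold is
retained. When a gene fails several criteria the reported reason is
prioritized `lowcount > error > nonconsensus` — a low-abundance gene is
unreliable regardless of its error, so that is the more informative
verdict. Symbols measured more than once are resolved before filtering:
the record with the lower total error wins, ties go to file order, and
every dropped record is logged.

## Symbolic trajectory encoding

Ratios are discretized over a five-symbol alphabet with fixed
cut-points 0.70, 0.82, 1.17 and 1.37 (↓ ↙ → ↗ ↑, or `D d S u U` in the
machine-readable rendering). The band edges are asymmetric around 1
because a ratio and its reciprocal are not equidistant from 1; the
stable band [0.82, 1.17] spans roughly ±17–18 %, of the order of the
propagated measurement error, so boundary values default to "no
change": the stable band is **closed** on both ends, its neighbours
half-open, the extreme bands open. This closure convention is a package
decision — the cut-points themselves leave the endpoint assignment
open, and no worked example sits exactly on a boundary.

A profile becomes a three-symbol code in concentration order; 5³ = 125
codes are possible. The census groups genes by code, orders patterns by
their members' mean ratio at the top concentration (descending, ties
broken lexicographically on the code), and reports **singletons** —
genes whose code no other gene shares — as one of the three outlier
detectors.

## Outlier consensus

Three detectors with different geometry:

* **Centroid distance** — Euclidean distance from the Global Center
  (the mean profile over all retained genes; identically the
  gene-count-weighted mean of pathway centroids, an identity the test
  suite checks to 1e−12 and that lets published centroid tables stand
  in for per-gene data). "A clear inflection point in the distance
  distribution" is operationalized as the largest consecutive drop
  within the top half of the sorted distances; a fixed top-k (default
  6) is the alternative, and the degenerate all-equal curve falls back
  to top-k with a warning.
* **DBSCAN** — density clustering on the raw (unstandardized) ratio
  coordinates, since the radius ε = 0.13 and the centroid tables are
  stated in ratio units. A point is *core* when at least `min_samples`
  = 5 points (itself included) lie within ε; ε can be taken from the
  5-distance curve at its point of maximum discrete curvature (largest
  second difference — the knee just below the jump into sparse
  territory), with a configured value always winning and a knee-less
  curve yielding the default with a warning. Border points join the
  first core cluster that reaches them when points are processed in
  gene-symbol order; this tie-break makes the complete labelling (not
  just the core/noise split) reproducible and input-order invariant.
* **Singletons** from the symbolic census.

The Venn consensus reports all seven regions; the pipeline removes the
full DBSCAN noise set before clustering, the most sensitive of the
three detectors.

## Tied-covariance Gaussian mixture

The outlier-free core is modelled as a k-component Gaussian mixture in
which all components share one covariance matrix Σ ("tied" — equal
ellipsoids). On a desk-scale data set (~90 genes in 3-D) per-component
covariances overfit: they raise the in-sample log-likelihood but pay
more than they earn in BIC, which is why tied covariance is the
default and the full-covariance mode exists mainly for the model scan's
comparison row.

Numerics, fixed once:

* EM with log-sum-exp responsibilities; the M-step pools the
  responsibility-weighted scatter about all component means for Σ.
* Initialization by k-means++-style seeding; `n_restarts` (default 10)
  independent runs, best final log-likelihood wins.
* Convergence at relative log-likelihood change ≤ 1e−6, cap 500
  iterations (non-convergence warns and returns the best iterate);
  monotonicity of the log-likelihood is asserted in the tests with
  1e−8 slack.
* Σ is ridge-regularized by adding 1e−6 to the diagonal after every
  update; a component whose responsibility mass collapses is re-seeded
  at the point with the weakest current assignment.
* Parameter count p = (k−1) + kd + d(d+1)/2 (tied) or
  (k−1) + kd + k·d(d+1)/2 (full); BIC = −2L + p·ln(n), lower better.
* One master seed expands deterministically into per-restart,
  per-stage and per-leave-one-out sub-seeds, so every report is exactly
  reproducible from `(data, config, seed)`.

Model choice is deliberately left to the user: the scan flags the
BIC-optimal and silhouette-optimal rows, but the pipeline fits the two
configured component counts (default 4 and 6), since on a continuous
expression gradient the numerically best silhouette (often the trivial
k = 2 split along the enrichment axis) is not the biologically useful
resolution.

Diagnostics:

* **Mahalanobis boundary drivers** — d_M = √((x − μ)ᵀ Σ⁻¹ (x − μ)) to
  the assigned component mean; genes with d_M > 2.42 (the default
  cut-off) are statistically peripheral to their module.
* **Leave-one-out ARI stability** — for each gene and each of the two
  model orders, refit without the gene and compare to the baseline
  labelling on the shared genes. The per-gene difference is defined as
  ARI(k=4 model) − ARI(k=6 model), so a *negative* mean says the
  6-component model is the more stable of the two; the sign convention
  is stated here because it is easy to invert silently.
* **Transition tables** — the k=4 × k=6 contingency table with
  marginals, exported in Sankey node/link form, showing which coarse
  modules fragment at the finer resolution.

Silhouettes use `cluster::silhouette` (singleton clusters score 0);
the ARI uses `mclust::adjustedRandIndex`, with the degenerate case of
two trivial partitions (chance-correction denominator zero) defined as
1. k-means uses `stats::kmeans` Lloyd iterations behind the package's
own k-means++ seeding and restart policy.

## The synthetic-data generator

`generate_panel()` emulates the study conditions with known truth:

* **Modules**: six centroids in ratio space (the bundled reference
  module table), membership weights proportional to the reference
  module sizes (17, 18, 13, 17, 9, 17), isotropic Gaussian spread
  `ratio_noise_sd` = 0.10 around the centroid — chosen to match the
  stated 10–15 % propagated-error scale of such panels.
* **Sentinel outliers**: eight profiles reconstructed from published
  per-gene percent changes of archetypal responders (drug-efflux
  V-shape, receptor suppression under depletion, cytokine surge under
  enrichment, progressive up-trends), planted *exactly* (no cluster
  noise) so density-based detection has a crisp oracle.
* **Counts**: log-normal control baselines (meanlog = log 500,
  sdlog = 1, floored at 30 copies so honest genes cannot trip the
  low-count filter by chance); expected count at concentration c is
  baseline × ratio. Replicates are expected × (1 ± CV) with a random
  sign and *fixed* magnitude, so each pair's CV statistic equals the
  gene's drawn CV exactly (up to integer rounding). The count-noise
  family of the original platform is not identifiable from summary
  statistics; this two-point family was chosen because only the CV
  statistic feeds the pipeline, and it makes the planted-verdict oracle
  exact. Counts are rounded to whole copies by default
  (`integer_counts = FALSE` recovers exact zero-noise identities).
* **Planted QC failures**: 6 genes with CV 0.20 (total error
  3√2 × 0.20 ≈ 0.85, decisively past 0.55 — honest genes draw CVs in
  [0.005, 0.09], bounded by 3√2 × 0.09 ≈ 0.54) and 2 genes with
  control baselines in [5, 15] copies. With the default 110-gene
  panel, 102 genes survive QC, mirroring the study scale.

The truth sidecar (module label, outlier flag, failure reason, true
profile) is written as a separate file and never read by the pipeline.

What the generator does **not** emulate: platform-level artifacts
(lane effects, background counts, control probes — upstream of this
pipeline's inputs), gene–gene correlation within modules beyond the
shared centroid, heavy-tailed count noise, and any association between
expression level and CV. Passing recovery tests therefore demonstrate
algorithmic correctness under the stated geometry, not robustness to
real-platform noise.

## Problem sizes and test design

The suite runs study-sized problems: 110-gene panels for end-to-end
checks, 300 genes for six-module parameter recovery (noise sd 0.03,
requiring ARI > 0.9 and mean centroid error < 0.05), 200 random
40-gene instances for the DBSCAN/naive-reference equivalence, and all
203 × 203 pairs of set partitions of six items for the ARI pair-counting
sweep. Quantities that require the original per-gene measurements — the
identity of the 11 outlier genes, the 14 realized codes, the printed
silhouettes — are covered by these property-based stand-ins instead of
value reproduction; the printed summary tables (pathway centroids with
gene counts, module centroids with memberships) are bundled as data and
fed back through the package's own arithmetic.

## Known limitations

* The quadrature-vs-linear choice for error propagation changes which
  genes sit near the 0.55 boundary; both are implemented, quadrature is
  the documented default, and the threshold is interpreted against the
  chosen formula.
* Symbolic boundary closure is a convention; genes within measurement
  error of a cut-point can legitimately carry either neighbouring
  symbol, which is one motivation for the probabilistic mixture stage.
* Leave-one-out refits use fresh seeded initializations rather than
  warm starts from the full fit; on multi-modal likelihoods a refit can
  land in a different optimum, which the ARI then (correctly) reports
  as instability of that model order.
* Exhaustive component matching for label alignment is O(k!) and
  restricted to k ≤ 9, ample for this setting.
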