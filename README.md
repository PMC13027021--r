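# deupanel

Analysis pipeline for small gene-expression panels measured in
**technical duplicate** across graded deuterium concentrations
(40, 80, 150 and 300 ppm, with 150 ppm — the natural isotopic abundance
of body water — as control). The setting is NanoString-style copy-number
counting of a cancer gene panel in A549 lung adenocarcinoma cells, where
the question is which genes respond to deuterium depletion (40/80 ppm)
or enrichment (300 ppm), individually and as coordinated modules.

## What it computes

Each gene *g* carries two replicate counts *x₁, x₂* per concentration.
The pipeline:

1. **Duplicate QC.** Dispersion per concentration is
   CV = |x₁ − x₂| / (x₁ + x₂). Expression ratios
   *r_c* = mean(x₁, x₂ at *c*) / mean(x₁, x₂ at control) carry a
   propagated relative error √(CV_c² + CV_ctrl²); the three per-ratio
   errors are summed and genes with total error > 0.55 or control mean
   < 20 copies are excluded, optionally followed by consensus-gene
   curation.
2. **Symbolic trajectories.** Each ratio is discretized over the
   five-symbol alphabet ↓ (< 0.70), ↙ [0.70, 0.82), → [0.82, 1.17],
   ↗ (1.17, 1.37], ↑ (> 1.37), turning the profile (r₄₀, r₈₀, r₃₀₀)
   into a three-symbol code (5³ = 125 possible); the census of realized
   codes exposes dominant programs and singleton genes.
3. **Outlier consensus.** Three detectors — Euclidean distance from the
   Global Center (the mean profile; equivalently the gene-count-weighted
   mean of pathway centroids), DBSCAN noise points in ratio space
   (ε = 0.13, min_samples = 5, ε selectable from the 5-distance knee),
   and singleton symbolic codes — combined in a Venn consensus.
4. **Mixture modules.** The outlier-free core is clustered by a
   tied-covariance Gaussian mixture (one shared Σ across components,
   fitted by EM with k-means++ seeding and restarts), scanned over
   k = 2–9 against a k-means baseline with silhouette and
   BIC = −2L + p·ln(n) (p = (k−1) + kd + d(d+1)/2 for tied Σ), and
   diagnosed by Mahalanobis boundary drivers (d_M > 2.42), leave-one-out
   ARI stability (k = 4 vs k = 6) and cluster-transition tables.

A synthetic-panel generator (`generate_panel()`) emulates the study
conditions with known ground truth — planted modules, planted sentinel
outliers, planted QC failures — so every stage is testable without the
original measurements.

## Worked example

```r
library(deupanel)

panel <- generate_panel(generator_config(seed = 42))   # 110-gene panel
res <- run_pipeline(panel$counts,
                    config = pipeline_config(seed = 42, n_restarts = 8))
table(res$qc$verdict)
#>              retained        excluded_error     excluded_lowcount
#>                   102                     6                     2
#> excluded_nonconsensus
#>                     0
```

110 genes enter, the 6 planted high-error and 2 planted low-count genes
are excluded, 102 survive. The report summarizes the rest of the run:

```r
print(res)
#> == duplicate-panel analysis report ==
#> input genes: 110
#> retained after QC: 102 (error-excluded 6, low-count 2, non-consensus 0)
#> outliers removed: 17 | clustered: 85
#> ...
#> -- trajectory patterns --
#> 17 of 125 theoretical codes realized
#> singletons: G0005, G0018, G0025, G0059, G0092, G0097
#> ...
#> -- mixture modules --
#> k = 6 tied: logLik 208.29, BIC -287.74
#> silhouette: mixture 0.258 vs k-means 0.262
#> boundary drivers (d_M > 2.42): 8
```

Only 17 of 125 symbolic codes are realized, six genes carry a code of
their own, and DBSCAN removes 17 density outliers before the
six-component tied mixture partitions the 85-gene core.

Single-gene arithmetic is exposed directly; the drug-efflux archetype
(+12 % at 40 ppm, −42 % at 80 ppm, +27 % at 300 ppm) encodes as
stable / strong-down / moderate-up:

```r
pattern_arrows(encode_triplet(data.frame(
  gene_id = "ABCB1", r40 = 1.122, r80 = 0.585, r300 = 1.268))$pattern)
#> [1] "→ ↓ ↗"
```

The bundled pathway-centroid reference table reproduces the Global
Center through the weighted-mean identity:

```r
round(global_center_from_centroids(a549_pathway_centroids()), 3)
#>   r40   r80  r300
#> 0.884 0.940 1.436
```

i.e. broad suppression under depletion and a mean +44 % response at
300 ppm.

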