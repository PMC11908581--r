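# chromaqc

Quality-centric evaluation of chromatographic data: quantify per-compound
signal quality, cluster compounds into quality tiers with unsupervised
learning, and validate the tiers by how well a retention-time model predicts
within each cluster.

## The problem

Ion-pair liquid chromatography (IPLC) runs of therapeutic oligonucleotides
produce one detector trace per injection. Machine-learning models that
predict retention time (tR) from sequence properties are only as good as
the signals they are trained on — but "good signal" is rarely quantified.
`chromaqc` operationalises it with four peak-quality measurements computed
from the raw trace `Y(t) = B(t) + P(t) + N(t)` (baseline + peak + noise):

- **SNR** — apex height above the fitted idle-region baseline, divided by
  the standard deviation of the detrended idle-region noise;
- **ΔtR** — signed difference `tR,1 − tR,2` between two replicate
  injections of the same sample;
- **peak skewness** — `Qs,0(x) = WR(x) / WL(x)`, the ratio of right to left
  half-widths at fraction `x = 0.5` of the apex height (1 = symmetric,
  < 1 fronting, > 1 tailing);
- **peak area** — trapezoidal area under the baseline-subtracted peak.

Together with sequence length and sulfur-modification count these form a
per-compound feature table. The table is standardized (z-score), normalized
(min-max), reduced with PCA, and partitioned by k-means, with k selected by
the elbow criterion (maximum second difference of the WCSS curve) and
validated by the mean silhouette score. Finally, a grid-searched regressor
(gradient-boosted trees or RBF support-vector regression) is fitted per
cluster; clusters whose models predict tR poorly contain low-quality data,
and the report tells the lab which quality measurements most separate the
best cluster from the worst.

A synthetic chromatogram simulator (exponentially modified Gaussian peaks,
linear baseline, Gaussian noise, latent quality tiers with known ground
truth) makes the entire pipeline testable without instrument data.

## Worked example

```r
library(chromaqc)

cfg <- pipeline_config(simulate = list(n_compounds = 150), seed = 4,
                       n_estimators = 100, cv_folds = 3)
report <- run_quality_pipeline(cfg, out_dir = "qc_run")
report
#> Quality-evaluation run
#>   rows: 150   k: 3   mean silhouette: 0.866
#> # A tibble: 3 x 5
#>   cluster  rank verdict rmse_test r2_test
#>     <int> <int> <chr>       <dbl>   <dbl>
#> 1       1     1 high       0.0257   0.995
#> 2       2     2 medium     0.0363   0.994
#> 3       3     3 low        0.139    0.962
#>   Features separating the best from the worst cluster most strongly: peak_area, sulfur_count.
```

The 150 simulated compounds fall into three clusters (k chosen by the
elbow, supported by a mean silhouette of 0.87). Cluster 1 — the high-SNR,
symmetric-peak group (clusters are re-indexed by descending mean SNR) —
supports the most accurate retention-time model (test RMSE 0.026 min);
the noisy, tailing, irreproducible cluster 3 is five times worse. That
performance gap is the evidence that the clusters capture real
data-quality differences, and the closing line of the report tells the
data producers *which* measurements most distinguish the best cluster
from the worst.

Individual stages are ordinary functions over tibbles and compose with the
pipe: `measure_peak()`, `assemble_quality_table()`, `fit_preprocess()`,
`pca_reduce()`, `wcss_curve()`, `select_k_elbow()`, `kmeans_fit()`,
`silhouette_validate()`, `evaluate_clusters()`, `rank_clusters()`.
`tidy()`/`glance()` methods expose every fitted object as a tibble and
`autoplot()`/`plot_*()` draw the standard figures. A command-line front
end ships at `inst/scripts/chromaqc` (subcommands `simulate`, `measure`,
`cluster`, `evaluate`, `run`, `report`).

Real datasets are supported as CSV inputs (`quality_table` mode, or
`chromatograms` mode for raw time/intensity traces); nothing in the
package requires the synthetic simulator.

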