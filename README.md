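# morphosignal

Phylogenetic signal in landmark-based shape data.

`morphosignal` is an R package for researchers who characterize small
anatomical structures — it was built around the ventral and dorsal haptoral
anchors of monogenean gill parasites (*Ligophorus* spp.), digitized as 8
two-dimensional landmarks per anchor — and want to know how much of the
variation in their shape and size is explained by shared evolutionary
history rather than convergence. It implements the complete workflow:

* **Input**: TPS (tpsDig dialect), CSV and XLSX landmark files; Newick
  phylogenies (via `ape`), with exact species-to-tip matching and alias
  tables.
* **Outlier screen**: squared Mahalanobis distance $D^2$ against
  $\chi^2_m$ quantiles in a full-rank PCA subspace, per species or pooled;
  flags, never deletes.
* **Superimposition**: Generalized Procrustes Analysis (partial
  Procrustes, proper rotations only, deterministic canonical orientation),
  centroid size $CS = \sqrt{\sum_i \lVert x_i - \bar{x}\rVert^2}$, and
  orthogonal tangent-space projection.
* **Shape PCA** of the covariance matrix of tangent coordinates, at
  specimen or species-mean level, with variance tables.
* **Allometry**: multivariate regression of shape on $\log CS$
  (mean-centered, through the origin) with a permutation test; residuals as
  size-corrected shapes; evolutionary allometry on Felsenstein's
  independent contrasts.
* **Phylogenetic signal**, two ways:
  squared-change-parsimony mapping of the tree into morphospace, whose
  minimized **tree length** $L = \sum_{\text{branches}}
  \lVert \Delta x \rVert^2 / \ell$ is compared with tip-data permutations
  (signal = observed tree shorter than permuted trees); and the
  **multivariate K** statistic
  $$K = \frac{\mathrm{tr}\,(\mathbf{Y}-\mathbf{1}\hat a)^\top(\mathbf{Y}-\mathbf{1}\hat a)}
             {\mathrm{tr}\,(\mathbf{Y}-\mathbf{1}\hat a)^\top \mathbf{C}^{-1}(\mathbf{Y}-\mathbf{1}\hat a)}
        \Big/ \frac{\mathrm{tr}\,\mathbf{C} - N/(\mathbf{1}^\top\mathbf{C}^{-1}\mathbf{1})}{N-1},$$
  the multivariate generalization of Blomberg's K ($K = 1$ under Brownian
  motion on the tree, $<1$ less signal, $>1$ more), with a randomization
  test.
* **Synthetic data**: a generator producing landmark datasets with known
  ground truth (Brownian species shapes on a tree, within-species noise,
  allometric coupling, random rigid motions and digitizer scales), plus
  matched null scenarios, so every stage is verifiable end to end.

## Worked example

Simulate a 14-species anchor dataset with moderate Brownian signal and mild
allometry, then run the full pipeline (ingest → screen → GPA → PCA →
allometry → size correction → signal tests):

```r
library(morphosignal)

cfg <- synthetic_config(n_tips = 14, n_specimens = 20, bm_rate = 5e-4,
                        noise_sd = 0.01, allometry_beta = 0.03, seed = 42)
sim <- generate_dataset(cfg)
report <- run_pipeline(run_config(sim$dataset, sim$tree,
                                  sides = "ventral", seed = 1))
report
#> == ventral anchors ==
#>   species-mean PCA: PC1 31.9%, PC2 21.9% (cumulative 53.7%)
#>   allometry: 11.4% of shape variation, p = 9.999e-05
#>   shape: tree length 0.06326 (p = 9.999e-05), K = 0.848 (p = 0.015)
#>   size: tree length 0.3696 (p = 0.05279), K = 0.503 (p = 0.442)
#>   shape_size_corrected: tree length 0.0545 (p = 9.999e-05), K = 0.926 (p = 0.003)
```

Reading the output: the first two PCs of the species-mean shapes carry
53.7% of shape variance; size predicts 11.4% of shape variation and the
allometry is highly significant (10,000 permutations); anchor shape carries
clear phylogenetic signal by both tests (short tree length, p ≈ 1e-4;
K = 0.85 with p = 0.015), and the signal survives size correction, while
logCS itself shows no significant signal in this simulated dataset. The
`report` object holds every intermediate (GPA fit, PCAs, allometry fit,
null distributions, phylomorphospace node coordinates); passing
`out_dir =` to `run_config()` additionally writes CSV tables and a JSON
index at full precision.

To analyse real data, replace the simulated objects with
`read_tps()`/`read_landmark_table()` and `read_phylogeny()` inputs.

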