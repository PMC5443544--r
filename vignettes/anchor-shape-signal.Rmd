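---
title: "Detecting phylogenetic signal in anchor shape and size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phylogenetic signal in anchor shape and size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosignal)
library(ape)
```

## The question and the data

Monogenean flatworms attach to fish gills with a haptor whose paired hooked
sclerites — the ventral and dorsal anchors — are shaped by some mixture of
shared evolutionary history and adaptation to the host. morphosignal
implements the landmark-based workflow used to weigh those two forces: each
anchor is reduced to a set of 2-D landmarks (8 by default), shape is
separated from position, scale and orientation by Generalized Procrustes
Analysis (GPA), and two complementary statistics then ask whether species
that are close on a molecular phylogeny also sit close in shape (and size)
space.

A dataset is a collection of landmark configurations labelled by specimen,
species and anchor side. Ventral and dorsal anchors are analysed as fully
independent streams that share only the phylogeny, because the two anchor
pairs are distinct structures with potentially different evolutionary
dynamics; a species sampled for only one side simply drops out of the other
side's stream.

## Superimposition and shape variables

GPA centers each configuration, scales it to unit centroid size
(CS, the square root of the summed squared landmark distances to the
centroid), and iteratively rotates all configurations to their mean until
the consensus stabilises (RMS change below `tol = 1e-10`, at most 100
sweeps, consensus initialised from the first configuration). We use partial
Procrustes superimposition — configurations stay at unit CS, with no cosine
rescaling — because it keeps CS interpretable as the size variable logCS
used downstream. Only proper rotations are fitted: anchors are chiral
objects, and a left/right pair must never be silently mirrored
(`allow_reflection = TRUE` exists for the rare deliberate use).

Two numerical choices deserve a note:

* **Canonical orientation.** The orientation of a Procrustes consensus is
  mathematically arbitrary. We rotate the final consensus onto its
  principal axes with a deterministic sign rule (largest-magnitude
  coordinate positive, determinant +1), so tangent coordinates are
  reproducible and invariant to the orientation in which specimens were
  digitized. Without this, re-digitizing the same specimens at a different
  angle would change every downstream score.
* **Tangent projection.** Aligned shapes are projected orthogonally to the
  consensus direction. The resulting tangent coordinates are the linear
  shape variables used by PCA, regression and the signal tests; their rank
  is at most 2k − 4 for k 2-D landmarks, which every consumer of the
  coordinates must (and does) tolerate.

Shape PCA is an eigen-decomposition of the sample covariance matrix
(divisor n − 1) of the tangent coordinates, at specimen level or after
averaging within species. The species-mean level is the one comparable to
published variance tables; the specimen level shows how individuals
scatter. A deterministic sign convention (largest loading element positive)
makes scores platform-stable.

## Outlier screening

Before analysis, configurations can be screened by comparing squared
Mahalanobis distances with chi-squared quantiles. Superimposed shape data
are rank-deficient, so distances are computed on PCA scores retaining
eigenvalues above 1e-12 times the largest (or a user-fixed dimension).
Screening defaults to within species and side — an outlier is an aberrant
individual relative to its own species — with a pooled option, and a
conventional default cutoff of 0.975. The screen only flags; exclusion is
a separate, explicit step, so no datum disappears silently. Note that the
sample Mahalanobis distance is bounded by (n − 1)²/n, so very small groups
cannot exceed high-dimensional chi-squared cutoffs: small species samples
are reported as skipped rather than screened against an unstable
covariance.

## Allometry

Evolutionary allometry is quantified by regressing tangent coordinates on
logCS. Shape and logCS are mean-centered first, after which the regression
passes through the origin; this is the standard morphometric reading of a
"through the origin" multivariate regression, since a strict no-centering
fit would conflate the mean shape itself with allometry (the strict variant
remains available via `center = FALSE`). The effect size is the percentage
of total shape variation predicted by size, and its significance is a
permutation test (default 10,000 shuffles of logCS). Size-corrected shapes
are the residuals re-centered on the grand mean, so every downstream
analysis runs on them unchanged; correcting twice is a no-op.

Because species are phylogenetically dependent, allometry across species is
re-assessed on Felsenstein's independent contrasts of the species means
(computed via `ape::pic`, with polytomies resolved to zero-length
bifurcations and a warning). Contrasts have expectation zero, so that
regression really does pass through the origin with no centering, and the
permutation scheme randomizes both the pairing and the signs of the size
contrasts, both exchangeable under the no-allometry null.

## Phylogenetic signal

Two statistics are computed, deliberately different in spirit:

* **Tree length.** The phylogeny is mapped into morphospace by
  squared-change parsimony: internal-node values minimise the sum over
  branches of squared change divided by branch length (the maximum-
  likelihood ancestral states under Brownian motion). The minimised
  objective — the "tree length", in units of squared Procrustes distance
  for shape and squared logCS for size — is short when close relatives are
  morphologically close. Significance comes from permuting the tip data
  across the tips (default 10,000 permutations), counting permutations with
  tree length ≤ observed, with the +1 Monte-Carlo correction so p is never
  exactly zero. The optimum is found exactly by solving the tree's
  inverse-branch-length-weighted Laplacian system; the permutation
  distribution reuses the resulting tip-space quadratic form, which makes
  10,000 permutations essentially free.
* **Multivariate K.** The ratio of observed to Brownian-expected trait
  similarity given the tree's covariance structure, scaled so K = 1 under
  Brownian motion, K < 1 for less signal and K > 1 for more. With one trait
  it reduces exactly to Blomberg's K (the test suite verifies agreement
  with an independent univariate implementation to 1e-8). Significance uses
  999 randomizations by default, counting draws ≥ observed.

Signal tests run at the species-mean level. By default they use the full
tangent-space data; the historical practice of mapping only the first two
PC scores is one setting away (`pcs = 2`), and the two versions are
reported separately because they answer slightly different questions (the
full space weights every dimension, the PC restriction reproduces what a
2-D morphospace plot shows). When the supplied tree is a bare topology the
machinery uses unit branch lengths — mapping "a topology" — and honours
lengths when they exist (`use_lengths = FALSE` forces the unit-length
mode). Tree length for logCS uses the same squared-change objective as
shape, keeping one objective throughout rather than mixing squared and
absolute units.

Degenerate inputs are defined to behave sensibly: a dataset with no
variation yields tree length 0, every permutation draw equal to it, and
p = 1 for both statistics (variation below 1e-20 of the data's magnitude is
treated as numerical zero); a constant logCS skips the allometry stage with
a note rather than failing the run.

## The synthetic generator

`generate_dataset()` produces datasets in which every downstream quantity
has a known truth. Species mean shapes evolve by multivariate Brownian
motion (rate `bm_rate` per tangent dimension per unit branch length) in the
tangent space of a fixed anchor-like 8-landmark template; within species,
each specimen adds an allometric component `beta * (logCS − mean logCS)`
and isotropic landmark noise (`noise_sd`); logCS itself has a Brownian
species component (`size_bm_rate`) plus within-species variation
(`size_sd`). Configurations are emitted at physical size under a random
rotation, translation and digitizer scale per specimen (rotation uniform on
[0, 2π), scale log-uniform on [−0.5, 0.5], never reflected), so a pipeline
cannot pass the tests without genuinely superimposing; the digitizer scale
is recorded so `apply_scale()` recovers physical units exactly.

Defaults mirror the motivating study's design: 14 species, 8 landmarks, 20
specimens per species. Where the study dictates no value we fixed, once,
magnitudes a morphometric dataset of small sclerites plausibly shows:
`bm_rate = 5e-4` (species means a few percent of shape space apart),
`noise_sd = 0.01` (within-species Procrustes scatter about an order of
magnitude below between-species spread), logCS around log(50) with
`size_sd = 0.08` and `size_bm_rate = 0.02`. The generator emulates the
statistical structure the comparative methods assume — Brownian means,
isotropic noise, linear allometry. It does not emulate landmark-specific
error anisotropy, digitization drift, modularity between anchor parts, or
non-Brownian evolution (OU attraction, early bursts); passing tests on
synthetic data therefore validate the machinery, not those biological
assumptions.

`null_scenario()` supplies the matching no-signal references: label
shuffling (exactly the permutation null) and species means drawn
independently of the tree (Brownian motion on a star phylogeny of equal
average depth).

## Interfaces and the pipeline

The package's interface is its functions: `run_pipeline(run_config(...))`
executes ingest → screen → GPA → PCA → allometry → size correction →
signal tests per anchor side and returns (optionally writes) a report
bundle with every number at full precision, the archived configuration and
the seeds, so a rerun is bit-identical. We deliberately expose the workflow
as R functions plus this vignette rather than a shell executable: that is
how comparative-morphometrics work is actually driven, interactively and
in scripts.

Species labels must match tree tips exactly (after whitespace trimming);
an alias table handles abbreviated labels. A species with landmarks but no
tip is a hard error listing the orphans — silently dropping data is the one
thing the pipeline refuses to do.

## Verification scale and limitations

The test suite verifies each stage against independent oracles at desk
scale: Procrustes distances against a rotation-grid scan, squared-change
parsimony against a general-purpose numerical minimiser on 6-tip trees,
K against its univariate special case, and the calibration of both
permutation tests against nominal type-I error (500 null replicates, 199
permutations each) with power checked under strong Brownian signal on a
14-tip tree — sizes chosen so the full battery runs in well under a minute
while keeping binomial error bands tight enough to be meaningful.

Known limitations: 2-D landmarks only (no 3-D, no semilandmarks, no
missing-landmark estimation); TPS curve records are not parsed; the
published anchor study's raw coordinate spreadsheet must be supplied by the
user to reproduce its printed table (it is not redistributable here), and
reproducing its printed tree lengths additionally requires the original
phylogeny's branch lengths, which were never published — those numbers are
for eyeball comparison only.
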