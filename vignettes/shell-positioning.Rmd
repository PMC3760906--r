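---
title: "Radial positioning of centromeric FISH signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial positioning of centromeric FISH signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshell)
```

## The question the pipeline answers

When a proliferating myoblast fuses into a myotube, its nucleus shrinks and
flattens, and interphase chromosomes can relocate. A standard way to
quantify relocation is 3D FISH against chromosome-specific centromeric
alpha-satellite probes: nuclei are imaged as two-channel confocal z-stacks
(DNA counterstain + probe), each nucleus is divided into K = 5 co-centric
shells of equal volume, every centromere signal is assigned to a shell, and
the shell distributions of the two cell states are compared with a
chi-square test of homogeneity. Morphometry (nuclear volume and flattening)
is compared with the Mann-Whitney U test, after a Shapiro-Wilk check shows
the samples are non-normal. `nucshell` implements that pipeline end to end,
plus the downstream gene-expression layer (2-fold change with
Benjamini-Hochberg-adjusted t-tests, mapped per chromosome).

## Nucleus segmentation and morphometry

Segmentation is deliberately plain: Gaussian pre-smoothing (default
0.2 µm), a global Otsu threshold, per-slice hole filling, 3-D 26-connected
components, and a minimum-volume filter (default 50 µm³, well below any
real nucleus but above debris). All physical quantities are computed in µm
from the voxel spacing, axis order always (z, y, x). Analyses of this kind have often delegated
reconstruction to interactive microscopy software whose parameters are
unpublished; a threshold-plus-components scheme with every parameter
exposed is the reproducible alternative.

Morphometry comes from an inertia-equivalent ellipsoid fit: the covariance
matrix of the mask voxel coordinates (plus the second moment of a single
voxel, since the mask is a union of cubes, not a point cloud) is
eigen-decomposed and the semi-axis along eigenvector *i* is
$a_i = \sqrt{5\lambda_i}$, the radius a uniform solid ellipsoid needs to
have the same second moment. **Flattening is defined as a/c**, longest over
shortest semi-axis (dimensionless, ≥ 1). No standard definition exists for
"flattening" of a nucleus, so comparisons are only meaningful within this
definition. Volume is the plain voxel count times voxel volume, not the
fitted ellipsoid volume. Components whose voxel volume differs from their
fitted-ellipsoid volume by more than 30 % are flagged as suspected touching
or ragged objects and excluded from morphometry (no watershed splitting is
attempted; sparse myoblast cultures rarely produce merged nuclei in
z-stacks).

## The radial coordinate: two metrics, one equal-volume contract

Two radial coordinates are provided, both increasing from centre to
periphery:

* **edt** (default): $1 - d(v)/\max d$, where $d$ is the anisotropic
  Euclidean distance to the nearest background voxel. Defined for any mask
  shape whatsoever.
* **ellipsoid**: the scale $s$ at which the voxel sits on the $s$-scaled
  fitted ellipsoid (a Mahalanobis-type radius in the principal frame);
  $s = 1$ on the fitted surface.

Shell boundaries are *empirical volume quantiles* of the chosen coordinate
over the mask voxels: voxels are ranked (ties broken deterministically in
raster order) and split into K consecutive blocks whose sizes differ by at
most one voxel. This guarantees the equal-volume contract — each shell
volume within one voxel of total/K — for arbitrary masks and either
metric, which a fixed analytic cut such as $r_k = (k/K)^{1/3}R$ would only
achieve for ideal spheres.

The two metrics are *not* interchangeable on realistic nuclei. On a digital
sphere they agree for ≈ 96 % of voxels (disagreements confined to adjacent
shells at the boundaries), but the agreement degrades with flattening: at
semi-axes (8, 7, 6) µm it is ≈ 91 %, and at a myoblast-like (8, 6, 3) µm
only ≈ 72 %. This is a geometric fact — iso-distance surfaces of a
flattened ellipsoid are not scaled copies of it — not a numerical artifact.
Consequently the choice of metric is part of the method and is recorded in
every partition and run manifest. The edt metric is the default because it
makes no shape assumption; the ellipsoid metric is the right choice when
results must be compared against a generator or model whose ground truth is
expressed in ellipsoid coordinates, and it is what the recovery analyses in
this package use.

## Spot detection and shell assignment

Probe-channel spots are detected by Laplacian-of-Gaussian filtering matched
to a single physical spot radius (default 0.4 µm, converted to per-axis
voxel scales), 3-D local maxima above mean + 5 SD of the filtered in-mask
values, and sub-voxel centroids from the intensity-weighted mean of the
positive response in a 3×3×3 neighbourhood. Spots whose centroid lies
outside every mask are discarded and counted in the log. Per-nucleus spot
counts different from the expected ploidy are visible in the audit table;
whether overlapping homolog signals should count as one or two signals is
an acquisition-level ambiguity the detector cannot resolve — it reports
what is resolvable.

Assignment: in edt mode a spot receives the shell of the voxel containing
its centroid (centroids up to one voxel outside the mask are snapped to the
nearest mask voxel; farther ones are discarded and logged). In ellipsoid
mode the radial coordinate has a closed form at any point, so it is
evaluated at the sub-voxel centroid and cut at the partition boundaries.
The distinction matters on coarse axial grids: with 0.4 µm z-steps and a
~2 µm short semi-axis, the containing-voxel rule blurs the radial
coordinate by up to ±0.1, and because neighbouring shells can hold very
different signal mass (e.g. 8 % vs 41 %), symmetric blur produces a *net*
drift into the sparse shell. Evaluating the closed form at the centroid
removes that bias; we measured it at roughly +4 percentage points on the
innermost shell of flattened nuclei before the change and about +2 after.

## Statistics

* **Chi-square homogeneity** on the 2×K table of shell counts, expected
  counts from the margins, no continuity correction, df = K − 1 (reduced
  if a zero-total shell is dropped, with a warning). Expected counts below
  5 trigger a warning, not a failure — outermost-shell counts make them
  unavoidable at realistic totals. Per-chromosome p-values are reported
  unadjusted by default, matching per-chromosome reporting practice; a BH
  column is available.
* **Mann-Whitney U**, two-sided: exact enumeration when n1 + n2 ≤ 12
  without ties, otherwise the normal approximation with mid-rank ties.
* **Shapiro-Wilk** (3 ≤ n ≤ 5000) documents the non-normality gate that
  justifies the rank test for volume and flattening.
* **Count reconstruction.** Published shell tables print percentages to
  two decimals but not counts. `reconstruct_counts()` searches exhaustively
  for the smallest total n ≤ 1000 whose rounded counts reproduce every
  percentage exactly at two decimals (half-away-from-zero, the printing
  convention). All fourteen packaged rows reconstruct exactly with totals
  between 68 and 128 — consistent with populations of a few dozen nuclei
  carrying ~2 signals each — and the reconstructed counts reproduce the
  published significance pattern for all seven chromosomes.
* **Differential expression**: per-gene two-sample t on log2 values, BH
  across all genes, classified up/down only if |log2 FC| ≥ 1 *and*
  adjusted p < 0.01. The default t statistic uses the **pooled variance**
  (df = n1 + n2 − 2). With triplicates — the design this layer exists
  for — Welch's df can fall to 2 and no gene reaches a BH-adjusted 0.01
  regardless of effect size (we measured ~16 % power at 8-fold effects
  versus ~95 % for the pooled test), so Welch is available but not the
  default. Quantile normalisation (`limma::normalizeQuantiles`, mean of
  tied targets) is applied at the matrix level; note that with few samples
  and many strong spikes it slightly compresses true fold changes, so
  power benchmarks run on the generator's already-commensurable scales.

## The synthetic-data generator

Every stage is validated against simulated data with known truth, because
the original raw images and arrays are external. The generator emulates:

* **Nuclei**: ellipsoids with Haar-uniform random orientation, semi-axes
  jittered per nucleus (CV 8 %). Defaults: myoblast-like (8, 6, 3) µm and
  a condition multiplier (7/8, 1, 2/3) giving myotube-like (7, 6, 2) µm —
  smaller and more flattened, the direction reported for differentiating
  muscle nuclei; the literature gives no exact dimensions, so only the
  ordering is meaningful.
* **Spots**: a shell index drawn from a per-probe (optionally
  per-condition) probability vector — printed shell-percentage rows can be
  used directly after normalising away their rounding — then a position
  uniform over that volume-quantile band of the true ellipsoid. Two spots
  per nucleus by default (one diploid autosome pair); configurable because
  X-probe counts differ by sex and merged homolog signals occur.
* **Imaging**: anisotropic Gaussian PSF (default σ = 0.4/0.13/0.13 µm
  z/y/x), Poisson photon noise on signal plus background (10 counts), and
  Gaussian read noise (SD 2), at 0.4/0.2/0.2 µm voxel spacing. These are
  generic confocal values; the study's acquisition statistics are unknown.
* **Expression**: log2-scale matrices, i.i.d. Gaussian noise (SD 0.25)
  around per-gene baselines, a configurable fraction of genes shifted by
  ±effect in group 2, triplicates per group by default.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: chromatin texture and intra-nuclear
intensity structure, multi-nucleus syncytium geometry (fields hold one
nucleus each), optical aberrations and depth-dependent attenuation,
segmentation of touching nuclei, and probe-specific hybridisation
efficiency. Recovery results on synthetic stacks bound the *algorithmic*
error of the pipeline, not the *biological* measurement error.

All randomness flows from one master seed through per-stage substreams
keyed by stage name and nucleus id, so identical configurations give
bit-identical outputs and adding a stage does not perturb earlier draws.

## Numerical choices and degenerate inputs

* Quantile ties at shell boundaries are broken in raster order —
  reproducible, and the equal-volume contract stays within one voxel.
* Voxel centres sit at integer indices; physical coordinate =
  (index − 1) × spacing.
* Otsu runs on a 256-bin histogram of the smoothed channel; segmentation
  is therefore invariant to positive intensity rescaling.
* Planar or linear voxel sets are rejected as degenerate before the
  ellipsoid fit; constant samples are rejected by the Shapiro-Wilk
  wrapper; zero-variance genes fall back to a mean-comparison verdict
  (p = 0 or 1) with a message.
* An ellipsoid that cannot fit in a user-fixed grid aborts naming the
  offending axis.

## Problem sizes used by the test-suite and acceptance analyses

Chosen as the package's own desk-scale study conditions: 50 nuclei per
condition (a typical scored population size for such experiments) for the full
imaging-to-assignment recovery run; a 10 µm digital sphere at 0.2 µm
isotropic sampling (~523 000 voxels) for shell-geometry checks; 1000
replicates of 500 uniform spots for the chi-square null calibration;
10 000 replicate tables for the homogeneity type-I check; 2000-gene
matrices with 10 % spiked genes, in triplicate, for expression power and
null simulations. Unit tests use smaller instances of the same generators.

## Known limitations

* Which radial measure the original interactive software used is not
  recoverable; both metrics are provided and recorded, but cross-study
  comparability of shell distributions is limited by that choice.
* No deconvolution, drift or chromatic correction; no watershed for
  touching nuclei; flagged components are simply excluded.
* The expression layer starts from a gene-level log2 matrix; probe-level
  summarisation of vendor files is out of scope.
* BH at a stringent 0.01 threshold is rank-limited when true effects are
  sparse: with ~1 % spiked genes, power drops steeply however large the
  effect. Power claims here are tied to the stated 10 % benchmark density.
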