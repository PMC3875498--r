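---
title: "Clustering large tractography datasets with representatives, LOFs and an atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering large tractography datasets with representatives, LOFs and an atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-brain diffusion-MRI tractography produces hundreds of thousands of
streamlines ("tracts"), each an ordered polyline in mm world coordinates,
while the number of anatomically meaningful fiber bundles hidden in such a
dataset is only in the hundreds. The datasets are therefore massively
redundant, and pairwise-distance clustering of all tracts at once is
computationally out of reach. `tractclust` implements CATSER, a
representative-based agglomerative clustering strategy in the CURE family
that exploits this redundancy: it clusters only a random sample of tracts,
describes each evolving cluster by a small, well-spread set of
*representative* streamlines, uses Local Outlier Factors (LOFs) to make the
merging order outlier-aware, discards slow-growing mini-clusters as noise,
and finally assigns every remaining streamline to its nearest prototype
cluster. A probabilistic white-matter atlas can optionally steer the merging
toward anatomically coherent bundles.

## Streamline model and similarity measures

A tract is at least two distinct 3D points; consecutive duplicate points are
collapsed at the I/O boundary, and TRK's voxel-scaled coordinate convention
is converted to mm world space on load so every internal distance is in mm.
Four measures are provided, all symmetric, nonnegative and zero on
identical tracts:

* **TCD** — Euclidean distance between the length-weighted centroids
  (the centre of gravity of the polyline, robust to uneven vertex spacing).
* **TOS** — angle in degrees between the endpoint-orientation unit vectors,
  in [0, 180].
* **HD** — two-sided point-set Hausdorff distance over the stored vertices
  (no segment interpolation).
* **CD** — a combined measure for possibly incomplete tracts: both tracts
  are resampled to 20 arc-length-uniform points, the closest point pair
  anchors a partial match, and equal-arc-length sub-tracts are sliced out
  around the anchors. The one-sided value is the mean of four components
  mapped into [0, 1]: TCD via the bounded map $d/(d+c)$ with $c$ = 20 mm,
  TOS via angle/180, the sub-tract centroid distance via $d/(d+c)$ with
  $c$ = 10 mm, and a shape term. To handle reversed streamlines the value is
  the minimum over `b` and reversed `b`, so a tract and its reversal are at
  distance 0.

The shape term compares the turning-angle sequences of the two fragments
(mean absolute difference, scaled by 180), which is translation- and
rotation-invariant, cheap, and zero for congruent fragments. The elastic
contour-matching descriptors used elsewhere in the literature would fit
behind the same interface; the normalization constants and weights are
config-exposed because only the *bounded, monotone* property matters to the
clustering. With weights (1, 0, 0, 0) the CD reduces to the normalized TCD,
which the test suite asserts.

Pairwise distances for the sample are precomputed once into a dense
symmetric matrix; the lower triangle is computed in contiguous row blocks
(one worker per block, row-balanced by element count). Every entry is a pure
function of two tracts, so the matrix — and everything downstream — is
bit-identical for any worker count. The Hausdorff kernel is compiled (Rcpp);
everything else is plain R.

## Local Outlier Factors

LOFs (Breunig-style) are computed from the precomputed matrix: k-distance,
reachability distances, local reachability density (LRD), and
LOF = mean(LRD of the k neighbours)/LRD(self). Interior points of a dense
cluster score about 1; isolated points score well above 1. Numerical
conventions: the neighbourhood is truncated to exactly *k* tracts with ties
broken toward the lower index (deterministic), and when a tract and all its
neighbours have infinite LRD (exact duplicates) the LOF is defined as 1.
The neighbour count defaults to `k = 15`; values much below ~10 fluctuate,
and values above the size of the smallest expected cluster artificially
inflate the LOFs of small bundles, so `k` stays configurable.

## The clustering pipeline

1. **Sampling.** A Fisher–Yates shuffle draws the reduced random sample
   (default 20 000 tracts, clamped to the dataset).
   `estimate_sample_size()` offers the Chernoff-bound alternative: the
   smallest sample that, with probability $1-\delta$, keeps a fraction $f$
   of every cluster of at least $u$ tracts,
   $s = fN + \frac{N}{u}\log\frac1\delta +
   \frac{N}{u}\sqrt{\log^2\frac1\delta + 2fu\log\frac1\delta}$.
2. **Matrix + LOFs** for the sample.
3. **Partitioning.** The sample is shuffled and split into `n_partitions`
   (default 3) parts differing in size by at most one.
4. **Preclustering** per partition down to about a third of the partition
   size (the CURE-style $n/(pq)$ rule with $q=3$), with the first outlier
   elimination.
5. **Join** — clusters are carried over unchanged; representatives are
   recomputed whenever a cluster next merges.
6. **Final clustering** to `target_k` prototype clusters (default 250),
   with the second elimination.
7. **Reassignment** of eliminated tracts to the nearest prototype cluster
   if they pass the acceptance test below.
8. **Labeling** of the unsampled remainder against the representatives
   only, with the tract's LOF taken as 1 (computing LOFs for the full
   dataset would require the full matrix).

**Cluster formation.** The medoid is the member minimizing the mean raw
distance to all members. Representatives are chosen greedily: the first
maximizes the LOF-adjusted distance to the medoid, each next one the minimum
adjusted distance to the medoid and all previously chosen; the count follows
a monotone piecewise function of cluster size — `round(n/3)` below the
transition size 120, constant 40 beyond it — so small clusters are described
proportionally and large ones at bounded cost. The distance between two
clusters is the minimum over representative pairs of the raw distance times
the LOF correction factor.

**LOF adjustments.** The correction factor for a tract pair is
$\alpha(\ell_i, \ell_j) = \max(1, \ell_i)\cdot\max(1, \ell_j)$: exactly 1
while both LOFs are at most 1, strictly increasing and symmetric above.
This specific product form is this package's choice; any factor with those
properties yields the same qualitative behaviour, and the tests pin the
properties, not the formula. Intra-cluster distances are *divided* by
$\alpha$ (outlying members are pulled inward and stop becoming
representatives); inter-cluster distances are *multiplied* by it (clusters
fronted by outlying representatives are pushed apart and merge late or
never).

**Outlier elimination** fires once per stage, after `ceil(t%)` of the merges
planned for that stage, removing live clusters with at most `s` members.
The presets are low (95 %, 1; 85 %, 4), moderate (80 %, 2; 85 %, 6) and high
(80 %, 4; 85 %, 8); the pipeline default is the study configuration
(80 %, <3; 60 %, <4). Merge order is deterministic: ties break toward the
lexicographically smallest cluster-slot pair.

**Acceptance test for (re)assignment.** A tract joins its nearest cluster
only if the distance to that cluster's closest representative is at most
$\gamma$ times the spread of the cluster's internal representative
distances, measured as their standard deviation. Degenerate clusters fall
back: with fewer than two representative pairs the mean internal member
distance is used, and singletons use the global median pairwise distance of
the sample. $\gamma$ defaults to 2 for both reassignment and labeling.
The test uses raw distances: an eliminated tract's own elevated LOF would
otherwise inflate every distance and make step 7 pointless.

## Atlas guidance

The probabilistic atlas is a set of named classes on a common voxel grid
(1 mm isotropic by default), each class a set of voxels with probabilities
in (0, 1]. Construction from labeled bundles: per dataset and voxel, the
class probability is (tracts of the bundle through the voxel)/(all labeled
tracts through the voxel); per class, probabilities are averaged over the
datasets whose bundle reaches the voxel, max-normalized to 1 per class, and
voxels below the 0.3 cutoff are dropped as unreliable. Classes may overlap.
Rasterization samples each segment at a quarter-voxel step with 0-based,
half-open `[i, i+1)` voxels.

A tract's membership in a class is the fraction of its voxels intersecting
the class's (binarized) voxel set; a cluster's membership is the mean over
members, maintained incrementally through merges. During guided runs every
cluster distance is multiplied by a four-case factor derived from the two
clusters' best classes: 1 when neither cluster touches the atlas,
$1 + s$ when exactly one does (repulsion growing with that membership $s$),
$1/(1 + s_a s_b)$ when both favour the same class (attraction), and
$1 + s_a + s_b$ for different classes (strongest repulsion). As with the
LOF factor, these functional forms are the package's choice; the ordering
and monotonicity of the four cases is the contract.

After a guided run, clusters are greedily merged whenever the *union-voxel*
spatial agreement of the merged cluster with its best class strictly exceeds
both parents' agreements, repeated to a fixed point. The union-voxel variant
(fraction of the voxelized cluster inside the class) is used deliberately:
the per-tract-mean membership of a merged cluster always lies between its
parents' values and can never strictly improve, whereas split halves of one
bundle share their off-atlas fringe, so re-joining them genuinely raises the
union fraction. Spatial matching of final clusters to classes is greedy
one-to-one on a matching score combining the mean absolute
probability–density difference over intersecting voxels and the mean
leftover mass on both sides,
$(1 - \bar e) - (\bar n_{class} + \bar n_{cluster})/2 \in [-1, 1]$, with
disjoint pairs pinned to the minimum so they never win ties.

## Synthetic data

The generator emulates what the pipeline actually consumes: bundles of
smoothly curving polylines. Each bundle is a cubic spline through 4–6
control points; each tract samples the centerline at a random vertex count
(10–20), receives a constant Gaussian radial offset (bundle thickness,
default SD 1 mm) plus per-point jitter at a quarter of that, and is
truncated by up to 30 % of its arc length from a random end. The truncation
is not cosmetic: real deterministic-tractography streamlines end wherever
anisotropy drops and differ substantially in length within one bundle, and
the sd-based acceptance test above is only meaningful when within-bundle
distances have non-degenerate spread. Isolated outliers are jagged random
polylines placed uniformly in the data bounding box; fractions 0/0.33/0.66/
0.99 reproduce the graded noise scenarios of the centroid experiment, in
which every tract is replaced by a degenerate micro-segment at its centroid
so that the TCD measure turns the full pipeline into plain 3D point
clustering.

What the generator does **not** emulate: crossing/kissing bundle
geometries, registration error between subjects, scanner noise statistics,
and tract density gradients within a bundle. Passing tests on these
synthetics therefore demonstrate the correctness and calibration of the
algorithmic machinery, not clinical performance on real brains.

## Problem sizes and numerical choices

The default evaluation scenarios, chosen to exercise every stage at desk
scale: parameter recovery uses 8 bundles × 250 tracts + 5 % outliers
(2 100 tracts) with the Hausdorff measure over 5 seeds; the centroid-noise
experiment uses 16 bundles × 60 tracts with noise up to 99 %. The noise
sweep is evaluated under the *low* elimination strategy, where noise has the
strongest effect — under aggressive elimination the acceptance spread grows
with the injected noise and masks the degradation. LOF calibration uses
1 000 isotropic Gaussian points, k = 15, and the median LOF over points
within one standard deviation of the sample mean.

Other numerics: `round()` (banker's) in the representative-count function;
argmin/argmax ties always resolve to the lowest index; the partial-match
anchor is the first minimum in row-major order; empty elimination stages
(target equal to the initial cluster count) perform no merges and no
elimination; a guided run against an atlas the data never touches is
bit-identical to the unguided run, which the acceptance suite asserts.

## Limitations

* The dense similarity matrix is O(n²) memory; the intended regime is a
  sample of up to a few tens of thousands of tracts, not the full dataset.
* CD component normalization constants are stand-ins for constants buried
  in prior elastic-matching work; they are config-exposed and only their
  bounded monotone form is relied upon.
* The atlas weighting uses binarized class support; the stored voxel
  probabilities only gate which voxels survive construction. Probabilistic
  weighting and orientation-aware atlases are natural extensions.
* The minimum-length load filter is off by default; there is no single
  defensible threshold across acquisitions.
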