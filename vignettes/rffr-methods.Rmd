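---
title: "Reducing a fully flexible receptor model by binding-cavity clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing a fully flexible receptor model by binding-cavity clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rffr)
library(dplyr)
```

## The problem

Ensemble ("fully flexible receptor", FFR) docking treats every snapshot of a
molecular-dynamics trajectory as an alternative rigid target. A 20 ns
trajectory sampled every 1 ps yields 20,000 receptor conformations; docking a
ligand library against all of them is rarely affordable. The question this
package answers is: which small subset of snapshots preserves the
conformational diversity of the binding site, so that docking against the
subset (the *reduced* FFR model, RFFR) stands in for docking against the
whole trajectory?

The approach clusters snapshots not by global RMSD — which averages away the
motions that matter for binding — but by four descriptors of the
substrate-binding cavity itself:

* accessible surface area of the cavity (Å²),
* cavity volume (Å³),
* number of heavy (non-hydrogen) atoms in the cavity,
* backbone RMSD (N, CA, C, O of the cavity residues) versus the first frame (Å).

Area and volume come from pocket-geometry software and are ingested as
columns of the feature CSV; the RMSD and heavy-atom columns can optionally be
computed in-package from a multi-model PDB trajectory plus a cavity residue
list (`compute_cavity_rmsd()`, `count_cavity_heavy_atoms()`). RMSD uses
least-squares rigid superposition by default (`superpose = TRUE`); a no-fit
mode exists because upstream trajectory tools differ in their fitting
conventions and some trajectories arrive pre-aligned.

## The procedure

1. **Normalise.** The four features carry incommensurate units, so each
   column is min–max mapped onto [0, 1] — the unique affine map onto the unit
   interval (`minmax_normalize()`). A constant column (e.g. a fixed
   heavy-atom count taken from the crystal-structure cavity) normalises to
   all zeros with a warning rather than being dropped, keeping the feature
   count at four. The column minima/maxima are retained, so `denormalize()`
   inverts the map to within 1e-9 relative error.

2. **Cluster.** Lloyd's k-means with k-means++ seeding, 10 restarts per k,
   swept over k = 2..15 (`kmeans_sweep()`). k-means++ rather than uniform
   seeding stabilises the sweep so the index curves are reproducible;
   nearest-centroid ties break to the lowest cluster index and any cluster
   that empties mid-iteration is repaired with the point farthest from its
   centroid, so runs are bit-reproducible and every cluster stays non-empty
   (the validity indices require it). Convergence is zero label changes,
   capped at 300 iterations. Per-k seeds derive deterministically from one
   master seed.

3. **Score each partition** with three validity criteria (`validity_sweep()`):

   * Davies–Bouldin: \(DB = \frac{1}{k}\sum_i \max_{j\ne i}
     \frac{\bar d_i + \bar d_j}{d_{i,j}}\), with \(\bar d_i\) the mean
     distance of cluster-\(i\) points to their centroid (the q = 1, p = 2
     member of the DB family, the most common instantiation) — lower is
     better.
   * Dunn: minimum single-linkage inter-cluster distance over maximum
     intra-cluster diameter (the classical definition of the two set
     distances) — higher is better.
   * Gap statistic: \(Gap(k) = E^*[\log W_k] - \log W_k\), with
     \(W_k = \sum_r D_r / (2 n_r)\) the pooled within-cluster dispersion
     (\(D_r\) the sum of squared distances over ordered pairs — chosen so
     that \(W_k\) reduces exactly to the within-cluster sum of squares,
     an identity the test suite asserts against the k-means inertia). The
     reference expectation is estimated from `b_refs = 50` Monte-Carlo
     datasets drawn uniformly over the per-feature observed range — the
     simpler of the two reference distributions in the gap-statistic
     literature, and the natural null here since the features are already
     min–max normalised to the unit box. Reference datasets are clustered
     with the same k-means settings; the simulation standard error is
     \(s_k = sd_b[\log W_k^{(b)}]\sqrt{1 + 1/B}\).

4. **Select k** (`select_partition()`). Each index nominates its optimum;
   if they disagree, the gap statistic is the decisive criterion (highest
   gap among the candidates), with residual ties broken by higher Dunn,
   lower DB, then smaller k. Because the "tolerance range" within which a
   gap optimum may be accepted is not quantified in the gap-statistic
   convention this rule follows, the default is a plain argmax of the gap;
   the standard one-standard-error rule is available as `gap_rule = "se"`
   for noisy gap curves. Every comparison is recorded in the `rationale`
   field.

5. **Validate against docking** (`cluster_feb_summary()`). Free energies of
   binding (FEB, kcal/mol) from exhaustive docking of each ligand against
   each snapshot are collapsed per (snapshot, ligand) — default: minimum
   over the independent docking runs, the usual "best pose" convention;
   a mean mode exists since the collapse rule is a genuine free choice —
   then the median FEB of each cluster is computed independently per
   ligand. If every ligand attains its best (lowest) median in the same
   cluster, the partition has captured a binding-relevant structure:
   `concordance` (fraction of ligands agreeing with the modal best cluster)
   is 1. `rank_consistency()` adds pairwise Spearman correlations of the
   cluster orderings — near 1 when cavity geometry rather than ligand
   identity drives the ranking.

6. **Reduce** (`build_rffr()`). At least two snapshots per cluster (the
   coverage rule that keeps downstream docking queues balanced), chosen as
   the snapshots nearest each centroid (medoids) or, when docking data are
   in hand, the snapshots with the lowest mean FEB. Undersized clusters
   contribute all their members and are flagged.

`run_pipeline()` chains the stages from a `pipeline_config()` (or YAML
file), writes per-stage CSV/JSON artifacts plus a manifest carrying the
config fingerprint and seed, and is byte-reproducible for a fixed config
and seed.

## The synthetic-data generator

Real inputs of this analysis (an MD trajectory, pocket-geometry output,
docking results) are expensive and not redistributable, so the package
ships a generator that emulates their statistical structure
(`synthetic_spec()`, `generate_feature_table()`,
`generate_docking_table()`):

* snapshot cluster memberships drawn from mixing weights; features from
  per-cluster Gaussians. A Gaussian mixture is the minimal structure under
  which k-means plus these validity indices behave as intended;
* area/volume/RMSD truncated at zero by **resampling** (clipping would pile
  probability mass at 0 and distort the indices); heavy-atom counts rounded
  to the nearest non-negative integer. A constant heavy-atom column is
  supported via zero within-cluster spread, since pocket software is
  sometimes run once on the crystal structure rather than per snapshot;
* the time column is `i * interval_ps` with the first frame at one interval,
  so 20 ns at 1 ps gives exactly 20,000 rows;
* FEB values are `Normal(base[ligand] + offset[cluster], noise_sd)` with
  exactly one cluster carrying the lowest offset — the planted analogue of
  one conformational cluster binding everything best.

Default scales mirror the motivating system: 10 clusters, 20 ns at 1 ps,
20 ligands, 25 docking runs per pair. Cluster centres spread over realistic
cavity scales (area 550–1150 Å², volume 750–1550 Å³, 300–372 heavy atoms,
RMSD 0.6–2.85 Å) with within-cluster standard deviations (12 Å², 16 Å³,
2 atoms, 0.045 Å) giving a minimum pairwise separation above 10 pooled
standard deviations (`min_cluster_separation()`); the heavy-atom and RMSD
centres are deterministically permuted across clusters so the centres are
not collinear. The default FEB offsets put the planted best cluster
2 kcal/mol below the runner-up with 0.5 kcal/mol run noise — comfortably
detectable by cluster medians yet noisy at the level of individual runs.

What the generator does **not** emulate: temporal autocorrelation between
consecutive snapshots (real trajectories are not i.i.d. draws), non-Gaussian
or overlapping conformational basins, ligand-specific induced-fit effects
(offsets are additive across ligands), or correlated docking errors. Tests
passing on this generator therefore certify the statistical machinery —
recovery of well-separated planted structure, the index definitions, the
selection rule, the median/concordance logic — not the claim that any real
trajectory has such structure.

## Numerical choices and degenerate inputs

* Distances are Euclidean throughout, on the normalised features.
* Davies–Bouldin errors on coincident centroids; Dunn errors when every
  cluster is a singleton (zero diameter) and returns 0 when duplicate
  points straddle clusters; the gap statistic errors when W = 0. Each is a
  typed condition, not a silent NA.
* k = 1 and k = n are valid k-means inputs (closed forms checked in tests);
  k > n errors.
* Validity indices are invariant under cluster relabeling and row
  permutation; Dunn is scale-invariant. All are asserted as properties.
* Brute-force oracles (double loops, exhaustive assignment enumeration at
  n ≤ 10) back the index and optimiser implementations in the test suite,
  and `stats::kmeans` serves as an independent cross-check on planted
  blobs — it is never the implementation.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen so
the statistical properties they assert are comfortably identifiable:
model-selection recovery uses 2,000 snapshots with 10 planted clusters
(separation ≥ 10 pooled SDs, full k = 2..15 sweep, 50 gap references);
recovery sweeps for 3/5/10 clusters use 120–400 snapshots with 8
references; concordance replicates use 100 snapshots × 20 ligands. At
these sizes the planted structure is unambiguous, so a correct
implementation recovers it essentially always — failures indicate defects,
not noise.

## A worked run

```{r example}
spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.2,
                       ligand_ids = sprintf("L%d", 1:5), seed = 42)
traj <- generate_feature_table(spec)
dock <- generate_docking_table(spec, traj$.cluster_true)

nf <- minmax_normalize(traj)
sw <- kmeans_sweep(nf, k_min = 2, k_max = 6, seed = 42, n_restarts = 5)
v <- validity_sweep(nf, sw, b_refs = 10, seed = 42)
sel <- select_partition(v)
sel

part <- sw[[sprintf("k=%d", sel$chosen_k)]]
summ <- cluster_feb_summary(snapshot_feb(dock), part)
glance(summ)

build_rffr(part, x = nf)$counts
```

```{r plots, fig.width = 7, fig.height = 3}
autoplot(v)
```

## Limitations

* The feature set is fixed at the four cavity descriptors; pocket area and
  volume must be computed externally per snapshot.
* k-means assumes roughly isotropic clusters in the normalised space;
  elongated or nested conformational basins may be split or merged, which
  is why three complementary validity criteria are consulted rather than
  one.
* Concordance is a deliberately coarse statistic (modal agreement across
  ligands); it validates that *a* cluster dominates, not that cluster
  medians differ significantly — no hypothesis test is attached.
* The optional PDB path reads multi-model PDB only (no DCD/XTC/NetCDF);
  trajectories in other formats should be converted or summarised to the
  feature CSV upstream.
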