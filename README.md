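# rffr

Reduce a fully flexible receptor (FFR) model — the full ensemble of
molecular-dynamics snapshots of a receptor — to a small representative
ensemble (RFFR) for ensemble docking.

Docking a ligand library against every snapshot of even a modest MD
trajectory (20 ns sampled at 1 ps = 20,000 conformations) is rarely
affordable. `rffr` clusters the snapshots by four descriptors of the
substrate-binding cavity — accessible surface area (Å²), cavity volume (Å³),
heavy-atom count, and cavity backbone RMSD versus the first frame (Å) —
rather than by global RMSD, then selects the number of conformational
clusters with three validity criteria and keeps a handful of
representatives per cluster.

## Method at a glance

Features are min–max normalised onto [0, 1] and clustered with seeded
k-means (k-means++ initialisation, Lloyd iterations, restarts) for
k = 2..15. Each partition is scored by:

- **Davies–Bouldin** (lower better):
  `DB = (1/k) Σᵢ maxⱼ≠ᵢ (d̄ᵢ + d̄ⱼ)/d(cᵢ,cⱼ)`, with `d̄ᵢ` the mean distance of
  cluster *i*'s points to their centroid;
- **Dunn** (higher better): minimum single-linkage inter-cluster distance
  over maximum intra-cluster diameter;
- **gap statistic** (higher better): `Gap(k) = E*[log Wₖ] − log Wₖ`, with
  `Wₖ = Σᵣ Dᵣ/(2nᵣ)` the pooled within-cluster dispersion and the reference
  expectation estimated from uniform draws over the observed feature box,
  clustered with the same k-means settings.

If the three candidates disagree, **the gap statistic is the decisive
criterion**. The chosen partition is then validated against docking
results: free energies of binding (FEB, kcal/mol) are collapsed per
(snapshot, ligand), and the median FEB of each cluster is computed per
ligand — if every ligand binds best in the same cluster (concordance = 1),
the partition captured binding-relevant structure. Finally `build_rffr()`
keeps at least two snapshots per cluster (medoids, or lowest-FEB members).

A synthetic-data generator with planted Gaussian cluster structure and
cluster-dependent FEB shifts makes the whole pipeline testable without a
trajectory or docking runs.

## Worked example

```r
library(rffr)

spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.2,
                       ligand_ids = sprintf("L%d", 1:5), seed = 42)
traj <- generate_feature_table(spec)           # 200 snapshots, planted labels
dock <- generate_docking_table(spec, traj$.cluster_true)

nf  <- minmax_normalize(traj)
sw  <- kmeans_sweep(nf, k_min = 2, k_max = 6, seed = 42, n_restarts = 5)
v   <- validity_sweep(nf, sw, b_refs = 10, seed = 42)
select_partition(v)
#> <rffr_k_choice> chosen k = 3 (candidates: DB 3, Dunn 3, gap 3)
#>   Davies-Bouldin minimised at k = 3 (DB = 0.0664).
#>   Dunn maximised at k = 3 (Dunn = 7.5477).
#>   Gap candidate (rule 'max') at k = 3 (gap = 4.7970).
#>   All three criteria agree: k = 3 chosen unanimously.
```

All three criteria recover the three planted conformational clusters: DB is
near zero (tight clusters far apart), Dunn is large, and the gap curve
peaks at k = 3. Docking validation and reduction:

```r
part <- sw[["k=3"]]
summ <- cluster_feb_summary(snapshot_feb(dock), part)
glance(summ)
#> # A tibble: 1 × 3
#>   n_ligands modal_cluster concordance
#>       <int>         <int>       <dbl>
#> 1         5             3           1

build_rffr(part, x = nf)$counts
#> # A tibble: 3 × 3
#>   cluster n_selected n_total
#>     <int>      <int>   <int>
#> 1       1          2      69
#> 2       2          2      70
#> 3       3          2      61
```

Every ligand attains its best median FEB in cluster 3 (the planted best
binder), and the reduced ensemble keeps 2 of ~65 snapshots per cluster — a
~97% reduction with all conformational states still represented.
`autoplot(v)` draws the three index curves; `autoplot(summ)` draws the
per-cluster median-FEB lines across ligands; `run_pipeline()` chains all
stages from a YAML config and writes CSV/JSON artifacts plus a manifest.

## Package layout

- `synthetic_spec()`, `generate_feature_table()`, `generate_docking_table()` — planted-structure data generator
- `read_feature_table()`, `minmax_normalize()`, `compute_cavity_rmsd()`, `count_cavity_heavy_atoms()` — feature I/O and optional PDB extraction
- `kmeans_partition()`, `kmeans_sweep()` — seeded k-means core
- `davies_bouldin()`, `dunn_index()`, `gap_statistic()`, `validity_sweep()`, `select_partition()` — model selection
- `snapshot_feb()`, `cluster_feb_summary()`, `rank_consistency()`, `build_rffr()` — docking validation and reduction
- `pipeline_config()`, `run_pipeline()` — end-to-end orchestration (CLI wrapper in `inst/scripts/`)

See `vignettes/rffr-methods.Rmd` for the model, its assumptions, and the
design decisions.
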