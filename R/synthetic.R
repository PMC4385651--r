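#' Specify a synthetic MD feature / docking dataset
#'
#' Builds the specification for a synthetic trajectory-feature table and its
#' companion docking table. The generator plants a Gaussian-mixture cluster
#' structure in the four cavity descriptors (accessible surface area, cavity
#' volume, heavy-atom count, backbone RMSD) and a cluster-dependent shift in
#' the free energy of binding (FEB), with exactly one "best" cluster carrying
#' the most negative FEB offset. This is the statistical structure the
#' downstream clustering and validation stages assume, so every stage can be
#' exercised without an MD trajectory or docking runs.
#'
#' Defaults mirror the scales of a 20 ns InhA-NADH trajectory sampled every
#' 1 ps (20,000 snapshots), partitioned into 10 conformational clusters and
#' docked against 20 ligands with 25 runs per (snapshot, ligand) pair.
#'
#' @param n_clusters Number of planted conformational clusters.
#' @param duration_ns Trajectory length in nanoseconds.
#' @param interval_ps Sampling interval in picoseconds. The number of
#'   snapshots is `floor(duration_ns * 1000 / interval_ps)`.
#' @param cluster_means `n_clusters` x 4 matrix of per-cluster feature means
#'   (columns: area \eqn{\mbox{\AA}^2}, volume \eqn{\mbox{\AA}^3}, heavy-atom
#'   count, RMSD \eqn{\mbox{\AA}}). Defaults to a well-separated spread over
#'   realistic cavity scales; see [default_cluster_means()].
#' @param cluster_sds `n_clusters` x 4 matrix of per-cluster feature standard
#'   deviations, same units.
#' @param mixing_weights Per-cluster membership probabilities; must be
#'   positive and sum to 1. Default: equal weights.
#' @param ligand_ids Character vector of ligand identifiers.
#' @param feb_base Named per-ligand baseline FEB (kcal/mol).
#' @param feb_cluster_offset Per-cluster FEB shift (kcal/mol). Exactly one
#'   cluster must attain the minimum (the planted best-binding cluster).
#' @param feb_noise_sd Standard deviation of the per-run FEB noise (kcal/mol).
#' @param runs_per_pair Docking runs per (snapshot, ligand) pair.
#' @param seed Integer seed; identical specs generate identical tables.
#'
#' @return An object of class `rffr_synthetic_spec`.
#' @seealso [generate_feature_table()], [generate_docking_table()]
#' @export
#' @examples
#' spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.3, ligand_ids = c("A", "B"))
#' traj <- generate_feature_table(spec)
synthetic_spec <- function(n_clusters = 10,
                           duration_ns = 20,
                           interval_ps = 1,
                           cluster_means = default_cluster_means(n_clusters),
                           cluster_sds = default_cluster_sds(n_clusters),
                           mixing_weights = rep(1 / n_clusters, n_clusters),
                           ligand_ids = sprintf("LIG%02d", seq_len(20)),
                           feb_base = NULL,
                           feb_cluster_offset = default_feb_offsets(n_clusters),
                           feb_noise_sd = 0.5,
                           runs_per_pair = 25,
                           seed = 1L) {
  if (!is.numeric(n_clusters) || length(n_clusters) != 1 || n_clusters < 1 ||
      n_clusters != round(n_clusters)) {
    stop_rffr("`n_clusters` must be a positive integer.", "rffr_invalid_spec")
  }
  n_clusters <- as.integer(n_clusters)
  if (!is.numeric(duration_ns) || duration_ns <= 0) {
    stop_rffr("`duration_ns` must be positive.", "rffr_invalid_spec")
  }
  if (!is.numeric(interval_ps) || interval_ps <= 0) {
    stop_rffr("`interval_ps` must be positive.", "rffr_invalid_spec")
  }
  cluster_means <- as.matrix(cluster_means)
  cluster_sds <- as.matrix(cluster_sds)
  if (!identical(dim(cluster_means), c(n_clusters, 4L)) ||
      !identical(dim(cluster_sds), c(n_clusters, 4L))) {
    stop_rffr("`cluster_means` and `cluster_sds` must be n_clusters x 4 matrices.",
              "rffr_invalid_spec")
  }
  if (any(cluster_sds < 0)) {
    stop_rffr("`cluster_sds` must be non-negative.", "rffr_invalid_spec")
  }
  colnames(cluster_means) <- colnames(cluster_sds) <- rffr_feature_columns()
  if (length(mixing_weights) != n_clusters || any(mixing_weights <= 0) ||
      abs(sum(mixing_weights) - 1) > 1e-9) {
    stop_rffr("`mixing_weights` must be positive and sum to 1 (within 1e-9).",
              "rffr_invalid_spec")
  }
  ligand_ids <- as.character(ligand_ids)
  if (anyDuplicated(ligand_ids)) {
    stop_rffr("`ligand_ids` must be unique.", "rffr_invalid_spec")
  }
  if (is.null(feb_base)) {
    feb_base <- setNames(seq(-9.5, -6, length.out = length(ligand_ids)), ligand_ids)
  }
  if (is.null(names(feb_base))) names(feb_base) <- ligand_ids
  if (!setequal(names(feb_base), ligand_ids)) {
    stop_rffr("`feb_base` must be named by `ligand_ids`.", "rffr_invalid_spec")
  }
  feb_base <- feb_base[ligand_ids]
  if (length(feb_cluster_offset) != n_clusters) {
    stop_rffr("`feb_cluster_offset` must have one entry per cluster.", "rffr_invalid_spec")
  }
  if (sum(feb_cluster_offset == min(feb_cluster_offset)) != 1) {
    stop_rffr("exactly one cluster must attain the minimum `feb_cluster_offset`.",
              "rffr_invalid_spec")
  }
  if (feb_noise_sd < 0) {
    stop_rffr("`feb_noise_sd` must be non-negative.", "rffr_invalid_spec")
  }
  if (runs_per_pair < 1 || runs_per_pair != round(runs_per_pair)) {
    stop_rffr("`runs_per_pair` must be a positive integer.", "rffr_invalid_spec")
  }
  n_rows <- floor(duration_ns * 1000 / interval_ps)
  if (n_rows < 1) {
    stop_rffr("spec implies zero snapshots; increase `duration_ns` or decrease `interval_ps`.",
              "rffr_invalid_spec")
  }
  structure(
    list(
      n_clusters = n_clusters,
      duration_ns = duration_ns,
      interval_ps = interval_ps,
      n_snapshots = as.integer(n_rows),
      cluster_means = cluster_means,
      cluster_sds = cluster_sds,
      mixing_weights = mixing_weights,
      ligand_ids = ligand_ids,
      feb_base = feb_base,
      feb_cluster_offset = feb_cluster_offset,
      best_cluster = which.min(feb_cluster_offset),
      feb_noise_sd = feb_noise_sd,
      runs_per_pair = as.integer(runs_per_pair),
      seed = as.integer(seed)
    ),
    class = "rffr_synthetic_spec"
  )
}

#' @export
print.rffr_synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<rffr_synthetic_spec> %d clusters, %g ns @ %g ps (%d snapshots), %d ligands x %d runs, seed %d\n",
    x$n_clusters, x$duration_ns, x$interval_ps, x$n_snapshots,
    length(x$ligand_ids), x$runs_per_pair, x$seed
  ))
  cat(sprintf("  planted best-binding cluster: %d (offset %.2f kcal/mol)\n",
              x$best_cluster, min(x$feb_cluster_offset)))
  invisible(x)
}

#' Default planted cluster centres for the four cavity features
#'
#' Cluster means are spread across realistic InhA-cavity scales (area roughly
#' 550--1150 \eqn{\mbox{\AA}^2}, volume 750--1550 \eqn{\mbox{\AA}^3},
#' 300--372 heavy atoms, backbone RMSD 0.6--2.85 \eqn{\mbox{\AA}}). The
#' heavy-atom and RMSD columns are deterministically permuted across clusters
#' so that the centres are not collinear in feature space. Together with
#' [default_cluster_sds()] the minimum pairwise separation is at least 10
#' pooled standard deviations, i.e. well-separated planted structure.
#'
#' @param n_clusters Number of clusters.
#' @return `n_clusters` x 4 numeric matrix.
#' @export
default_cluster_means <- function(n_clusters) {
  n <- as.integer(n_clusters)
  # golden-ratio sequence gives a fixed, n-agnostic permutation
  perm1 <- order((seq_len(n) * (sqrt(5) - 1) / 2) %% 1)
  perm2 <- rev(perm1)
  m <- cbind(
    area_A2     = seq(550, 1150, length.out = n),
    volume_A3   = rev(seq(750, 1550, length.out = n)),
    heavy_atoms = seq(300, 372, length.out = n)[perm1],
    rmsd_A      = seq(0.6, 2.85, length.out = n)[perm2]
  )
  if (n == 1) m[, "rmsd_A"] <- 1.5
  m
}

#' @rdname default_cluster_means
#' @export
default_cluster_sds <- function(n_clusters) {
  matrix(rep(c(12, 16, 2, 0.045), each = n_clusters), nrow = n_clusters,
         dimnames = list(NULL, rffr_feature_columns()))
}

# One planted best-binding cluster (index 3 when possible) 2 kcal/mol below
# the rest; remaining offsets spread mildly so cluster FEB rankings are
# non-trivial but stable.
default_feb_offsets <- function(n_clusters) {
  n <- as.integer(n_clusters)
  if (n == 1) return(-2)
  off <- seq(-0.4, 0.8, length.out = n - 1)
  best <- min(3L, n)
  append(off, -2, after = best - 1L)
}

#' Minimum pairwise cluster separation of a synthetic spec
#'
#' Separation between two cluster centres is the Euclidean norm of the
#' difference of their mean vectors after dividing each feature by its pooled
#' (root-mean-square across clusters) standard deviation. A minimum of 10 or
#' more corresponds to well-separated planted clusters that k-means plus the
#' validity indices should recover essentially perfectly.
#'
#' @param spec An [synthetic_spec()] object.
#' @return Minimum over cluster pairs of the pooled-sd separation.
#' @export
min_cluster_separation <- function(spec) {
  stopifnot(inherits(spec, "rffr_synthetic_spec"))
  if (spec$n_clusters < 2) return(Inf)
  pooled <- sqrt(colMeans(spec$cluster_sds^2))
  z <- sweep(spec$cluster_means, 2, pooled, "/")
  d <- sqrt(cross_sqdist(z, z))
  min(d[upper.tri(d)])
}

#' Generate a synthetic trajectory feature table
#'
#' Draws one snapshot per sampling interval: cluster membership from the
#' mixing weights, then the four cavity features from the per-cluster
#' Gaussians. Area, volume and RMSD are truncated at zero by resampling
#' (keeping within-cluster distributions unimodal rather than piling mass at
#' zero); the heavy-atom count is rounded to the nearest non-negative
#' integer. The time column is `i * interval_ps` for the i-th snapshot
#' (first frame at `interval_ps`), so a 20 ns trajectory at 1 ps yields
#' exactly 20,000 rows.
#'
#' @param spec An [synthetic_spec()] object.
#' @return A tibble with the feature-table schema (`snapshot_id`, `time_ps`,
#'   `area_A2`, `volume_A3`, `heavy_atoms`, `rmsd_A`) plus a `.cluster_true`
#'   column holding the planted labels for recovery tests.
#'   [write_feature_table()] drops the extra column on export.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "rffr_synthetic_spec"))
  n <- spec$n_snapshots
  seeds <- derive_seeds(spec$seed, 2L)
  withr::with_seed(seeds[1], {
    labels <- sample.int(spec$n_clusters, n, replace = TRUE,
                         prob = spec$mixing_weights)
    draw <- function(j, truncate) {
      v <- rnorm(n, spec$cluster_means[labels, j], spec$cluster_sds[labels, j])
      if (truncate) {
        bad <- which(v < 0)
        while (length(bad)) {
          v[bad] <- rnorm(length(bad), spec$cluster_means[labels[bad], j],
                          spec$cluster_sds[labels[bad], j])
          bad <- bad[v[bad] < 0]
        }
      }
      v
    }
    area <- draw(1L, TRUE)
    volume <- draw(2L, TRUE)
    heavy <- pmax(0L, as.integer(round(draw(3L, FALSE))))
    rmsd <- draw(4L, TRUE)
  })
  tibble::tibble(
    snapshot_id = sprintf("snap_%06d", seq_len(n)),
    time_ps = seq_len(n) * spec$interval_ps,
    area_A2 = area,
    volume_A3 = volume,
    heavy_atoms = heavy,
    rmsd_A = rmsd,
    .cluster_true = as.integer(labels)
  )
}

#' Generate a synthetic docking (FEB) table
#'
#' For every (snapshot, ligand) pair, draws `runs_per_pair` free-energy-of-
#' binding values from `Normal(feb_base[ligand] + feb_cluster_offset[label],
#' feb_noise_sd)`. The planted best cluster therefore attains the lowest
#' median FEB for every ligand (up to noise), the behaviour the per-cluster
#' median validation stage is designed to detect.
#'
#' @param spec An [synthetic_spec()] object.
#' @param labels Integer cluster labels in `1..n_clusters`, one per snapshot
#'   (e.g. the `.cluster_true` column of [generate_feature_table()], or the
#'   labels of a fitted partition).
#' @param snapshot_ids Snapshot identifiers aligned with `labels`; defaults
#'   to the ids the feature generator assigns.
#' @return A tibble `(snapshot_id, ligand_id, run, feb_kcal_mol)`.
#' @export
generate_docking_table <- function(spec, labels, snapshot_ids = NULL) {
  stopifnot(inherits(spec, "rffr_synthetic_spec"))
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > spec$n_clusters)) {
    stop_rffr(
      sprintf("cluster labels must lie in 1..%d.", spec$n_clusters),
      "rffr_invalid_label"
    )
  }
  n <- length(labels)
  snapshot_ids <- snapshot_ids %||% sprintf("snap_%06d", seq_len(n))
  if (length(snapshot_ids) != n) {
    stop_rffr("`snapshot_ids` must align with `labels`.", "rffr_invalid_label")
  }
  n_lig <- length(spec$ligand_ids)
  r <- spec$runs_per_pair
  # row order: snapshot (slow) x ligand x run (fast)
  mu <- rep(spec$feb_base, each = 1)
  grid <- tidyr::expand_grid(
    snapshot_id = snapshot_ids,
    ligand_id = spec$ligand_ids,
    run = seq_len(r)
  )
  mean_feb <- rep(spec$feb_base[grid$ligand_id], 1) +
    spec$feb_cluster_offset[rep(labels, each = n_lig * r)]
  seeds <- derive_seeds(spec$seed, 2L)
  feb <- withr::with_seed(seeds[2], rnorm(nrow(grid), mean_feb, spec$feb_noise_sd))
  dplyr::mutate(grid, feb_kcal_mol = unname(feb))
}
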