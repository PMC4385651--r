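# broom-style methods for the fitted objects.

#' Tidy a fitted partition
#'
#' One row per cluster: size, within-cluster sum of squares, and the
#' centroid coordinates in normalised feature space.
#'
#' @param x An `rffr_partition`.
#' @param ... Unused.
#' @return A tibble with one row per cluster.
#' @export
tidy.rffr_partition <- function(x, ...) {
  C <- x$centroids
  colnames(C) <- colnames(C) %||% paste0("x", seq_len(ncol(C)))
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k), size = x$sizes),
    tibble::as_tibble(C)
  )
}

#' @rdname tidy.rffr_partition
#' @export
glance.rffr_partition <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, iterations = x$iterations,
                 converged = x$converged, n = length(x$labels),
                 seed = x$seed, n_restarts = x$n_restarts)
}

#' Augment a feature table with fitted cluster labels
#'
#' @param x An `rffr_partition`.
#' @param data Feature table (or any tibble with `snapshot_id`) to augment.
#' @param ... Unused.
#' @return `data` with a `.cluster` column joined by snapshot id.
#' @export
augment.rffr_partition <- function(x, data, ...) {
  dplyr::left_join(tibble::as_tibble(data),
                   dplyr::rename(partition_labels(x), .cluster = "cluster"),
                   by = "snapshot_id")
}

#' Tidy validity-sweep results
#'
#' @param x An `rffr_validity` tibble.
#' @param ... Unused.
#' @return A long tibble `(k, index, value)` over the three indices.
#' @export
tidy.rffr_validity <- function(x, ...) {
  tibble::as_tibble(x)[, c("k", "db", "dunn", "gap")] |>
    tidyr::pivot_longer(-"k", names_to = "index", values_to = "value")
}

#' Summarise a model-selection result
#'
#' @param x An `rffr_k_choice`.
#' @param ... Unused.
#' @return A one-row tibble with the chosen k and the three candidates.
#' @export
glance.rffr_k_choice <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, candidate_db = x$candidate_db,
                 candidate_dunn = x$candidate_dunn,
                 candidate_gap = x$candidate_gap, gap_rule = x$gap_rule)
}

#' Tidy per-cluster median FEB values
#'
#' @param x An `rffr_feb_summary`.
#' @param ... Unused.
#' @return The `(ligand_id, cluster, median_feb, n_snapshots)` tibble.
#' @export
tidy.rffr_feb_summary <- function(x, ...) x$medians

#' @rdname tidy.rffr_feb_summary
#' @export
glance.rffr_feb_summary <- function(x, ...) {
  tibble::tibble(n_ligands = x$n_ligands, modal_cluster = x$modal_cluster,
                 concordance = x$concordance)
}

#' Tidy an RFFR ensemble selection
#'
#' @param x An `rffr_ensemble`.
#' @param ... Unused.
#' @return The selected-snapshot tibble.
#' @export
tidy.rffr_ensemble <- function(x, ...) x$selected

#' @rdname tidy.rffr_ensemble
#' @export
glance.rffr_ensemble <- function(x, ...) {
  tibble::tibble(n_selected = nrow(x$selected), n_clusters = nrow(x$counts),
                 mode = x$policy$mode, min_per_cluster = x$policy$min_per_cluster,
                 n_undersized = length(x$undersized))
}
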