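#' Build the reduced (RFFR) snapshot ensemble
#'
#' Selects a small representative subset of snapshots from a fitted
#' partition so that every conformational cluster stays represented in
#' downstream docking: at least `min_per_cluster` snapshots per cluster
#' (default 2, the minimum coverage rule), with clusters smaller than that
#' contributing all their members (recorded and warned).
#'
#' Two selection policies:
#' \describe{
#'   \item{`"medoids"`}{per cluster, the `min_per_cluster` snapshots nearest
#'     the centroid in normalised feature space (requires `x`). The single
#'     medoid of a singleton cluster is the member itself.}
#'   \item{`"best_feb"`}{per cluster, the snapshots with the lowest
#'     per-snapshot FEB averaged over ligands (requires `feb`, the
#'     [snapshot_feb()] table).}
#' }
#'
#' @param partition An `rffr_partition`.
#' @param x Normalised features the partition was fitted on (`"medoids"`
#'   mode).
#' @param feb Per-snapshot FEB tibble `(snapshot_id, ligand_id, feb)`
#'   (`"best_feb"` mode).
#' @param min_per_cluster Minimum snapshots per cluster (default 2).
#' @param mode Selection policy, `"medoids"` (default) or `"best_feb"`.
#' @return An object of class `rffr_ensemble`: `selected` tibble
#'   `(snapshot_id, cluster, rank, score)` (score = centroid distance or
#'   mean FEB, by mode), `counts` tibble `(cluster, n_selected, n_total)`,
#'   `undersized` cluster indices, and the `policy` record.
#' @export
#' @examples
#' spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.2)
#' nf <- minmax_normalize(generate_feature_table(spec))
#' part <- kmeans_partition(nf, 3, seed = 2)
#' build_rffr(part, x = nf)$counts
build_rffr <- function(partition, x = NULL, feb = NULL, min_per_cluster = 2L,
                       mode = c("medoids", "best_feb")) {
  mode <- match.arg(mode)
  stopifnot(inherits(partition, "rffr_partition"))
  if (min_per_cluster < 1 || min_per_cluster != round(min_per_cluster)) {
    stop_rffr("`min_per_cluster` must be a positive integer.", "rffr_invalid_spec")
  }
  min_per_cluster <- as.integer(min_per_cluster)
  labs <- partition_labels(partition)
  if (mode == "medoids") {
    if (is.null(x)) {
      stop_rffr("medoids mode requires the feature matrix `x`.", "rffr_missing_input")
    }
    X <- feature_values(x)
    if (nrow(X) != nrow(labs)) {
      stop_rffr("`x` does not align with the partition.", "rffr_join_error")
    }
    d <- sqrt(cross_sqdist(X, partition$centroids)[cbind(seq_len(nrow(X)),
                                                         partition$labels)])
    scored <- dplyr::mutate(labs, score = d)
  } else {
    if (is.null(feb)) {
      stop_rffr("best_feb mode requires the per-snapshot FEB table `feb`.",
                "rffr_missing_input")
    }
    mean_feb <- tibble::as_tibble(feb) |>
      dplyr::summarise(score = mean(.data$feb), .by = "snapshot_id")
    scored <- dplyr::inner_join(labs, mean_feb, by = "snapshot_id")
    if (nrow(scored) == 0) {
      stop_rffr("no docked snapshot overlaps the partition.", "rffr_join_error")
    }
  }
  selected <- scored |>
    dplyr::arrange(.data$cluster, .data$score, .data$snapshot_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .by = "cluster") |>
    dplyr::filter(.data$rank <= min_per_cluster) |>
    dplyr::select("snapshot_id", "cluster", "rank", "score")
  counts <- tibble::tibble(cluster = seq_len(partition$k),
                           n_total = partition$sizes) |>
    dplyr::left_join(dplyr::count(selected, .data$cluster, name = "n_selected"),
                     by = "cluster") |>
    dplyr::mutate(n_selected = dplyr::coalesce(.data$n_selected, 0L)) |>
    dplyr::select("cluster", "n_selected", "n_total")
  undersized <- counts$cluster[counts$n_selected < min_per_cluster &
                                 counts$n_total > 0]
  if (length(undersized)) {
    warn(sprintf("cluster(s) smaller than min_per_cluster contribute all members: %s",
                 paste(undersized, collapse = ", ")),
         class = "rffr_undersized_cluster")
  }
  structure(
    list(selected = selected, counts = counts, undersized = as.integer(undersized),
         policy = list(mode = mode, min_per_cluster = min_per_cluster)),
    class = "rffr_ensemble"
  )
}

#' @export
print.rffr_ensemble <- function(x, ...) {
  cat(sprintf("<rffr_ensemble> %d snapshots from %d clusters (mode '%s', >= %d per cluster)\n",
              nrow(x$selected), nrow(x$counts), x$policy$mode,
              x$policy$min_per_cluster))
  if (length(x$undersized)) {
    cat("  undersized cluster(s):", paste(x$undersized, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the RFFR snapshot id list
#'
#' One snapshot id per line, the input format of downstream docking queues.
#'
#' @param ensemble An `rffr_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rffr_ids <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "rffr_ensemble"))
  writeLines(ensemble$selected$snapshot_id, path)
  invisible(path)
}
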