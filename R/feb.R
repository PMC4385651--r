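#' Read a docking-results table from CSV
#'
#' Expects the header `snapshot_id,ligand_id,run,feb_kcal_mol` — one row per
#' docking run, e.g. 25 independent Lamarckian-GA runs per (snapshot,
#' ligand) pair. Validates that (snapshot, ligand, run) triples are unique
#' and FEB values are finite.
#'
#' @param path Path to the CSV file.
#' @return A tibble `(snapshot_id, ligand_id, run, feb_kcal_mol)`.
#' @export
read_docking_table <- function(path) {
  if (!file.exists(path)) {
    stop_rffr(sprintf("docking table not found: %s", path), "rffr_io_error")
  }
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      snapshot_id = readr::col_character(),
      ligand_id = readr::col_character(),
      run = readr::col_integer(),
      feb_kcal_mol = readr::col_double()
    ),
    show_col_types = FALSE
  )
  validate_docking_table(tbl)
}

validate_docking_table <- function(tbl) {
  need <- c("snapshot_id", "ligand_id", "run", "feb_kcal_mol")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop_rffr(
      sprintf("docking table is missing column(s): %s", paste(missing, collapse = ", ")),
      "rffr_schema_error", missing_columns = missing
    )
  }
  if (anyDuplicated(tbl[, c("snapshot_id", "ligand_id", "run")])) {
    stop_rffr("duplicate (snapshot_id, ligand_id, run) rows in docking table.",
              "rffr_integrity_error")
  }
  if (any(!is.finite(tbl$feb_kcal_mol))) {
    stop_rffr("non-finite FEB values in docking table.", "rffr_integrity_error")
  }
  tibble::as_tibble(tbl[, need])
}

#' Collapse docking runs to one FEB per (snapshot, ligand)
#'
#' The default policy keeps the minimum (most favourable) FEB over the runs
#' of each pair — the usual docking convention of scoring a receptor
#' conformation by its best pose energy. A `"mean"` policy is provided for
#' sensitivity analyses. The policy used is recorded in the result's
#' `collapse` attribute.
#'
#' @param table Docking tibble `(snapshot_id, ligand_id, run, feb_kcal_mol)`.
#' @param collapse `"min"` (default) or `"mean"`.
#' @return A tibble `(snapshot_id, ligand_id, feb)` with attribute
#'   `collapse`.
#' @export
snapshot_feb <- function(table, collapse = c("min", "mean")) {
  collapse <- match.arg(collapse)
  table <- validate_docking_table(table)
  if (nrow(table) == 0) {
    stop_rffr("docking table is empty.", "rffr_empty_input")
  }
  f <- if (collapse == "min") min else mean
  out <- table |>
    dplyr::summarise(feb = f(.data$feb_kcal_mol),
                     .by = c("snapshot_id", "ligand_id"))
  attr(out, "collapse") <- collapse
  out
}

partition_label_table <- function(partition) {
  if (inherits(partition, "rffr_partition")) return(partition_labels(partition))
  tbl <- tibble::as_tibble(partition)
  if (!all(c("snapshot_id", "cluster") %in% names(tbl))) {
    stop_rffr("`partition` must be an `rffr_partition` or a (snapshot_id, cluster) table.",
              "rffr_type_error")
  }
  tbl[, c("snapshot_id", "cluster")]
}

#' Per-cluster median FEB and best-cluster concordance
#'
#' Joins the collapsed per-snapshot FEB values with the cluster labels and
#' computes, independently for each ligand, the median FEB of every cluster.
#' Each ligand's best cluster is the one attaining the minimum median
#' (argmin ties break to the lower cluster index and are recorded).
#' Concordance is the fraction of ligands whose best cluster equals the
#' modal best cluster — 1.0 means every ligand binds best in the same
#' conformational cluster, the behaviour that validates a partition for
#' ensemble reduction.
#'
#' @param per_snapshot Tibble `(snapshot_id, ligand_id, feb)` from
#'   [snapshot_feb()].
#' @param partition An `rffr_partition` or a `(snapshot_id, cluster)` table
#'   covering every docked snapshot.
#' @return An object of class `rffr_feb_summary`: `medians` tibble
#'   `(ligand_id, cluster, median_feb, n_snapshots)`, `best` tibble
#'   `(ligand_id, best_cluster, median_feb, tied)`, `modal_cluster`,
#'   `concordance`, `n_ligands`.
#' @export
cluster_feb_summary <- function(per_snapshot, partition) {
  labs <- partition_label_table(partition)
  feb <- tibble::as_tibble(per_snapshot)
  stray <- setdiff(unique(feb$snapshot_id), labs$snapshot_id)
  if (length(stray)) {
    stop_rffr(
      sprintf("docked snapshot(s) absent from partition: %s%s",
              paste(head(stray, 5), collapse = ", "),
              if (length(stray) > 5) sprintf(" (+%d more)", length(stray) - 5) else ""),
      "rffr_join_error", missing_snapshots = stray
    )
  }
  medians <- feb |>
    dplyr::inner_join(labs, by = "snapshot_id") |>
    dplyr::summarise(median_feb = median(.data$feb),
                     n_snapshots = dplyr::n_distinct(.data$snapshot_id),
                     .by = c("ligand_id", "cluster")) |>
    dplyr::arrange(.data$ligand_id, .data$cluster)
  best <- medians |>
    dplyr::arrange(.data$ligand_id, .data$median_feb, .data$cluster) |>
    dplyr::mutate(tied = sum(.data$median_feb == min(.data$median_feb)) > 1,
                  .by = "ligand_id") |>
    dplyr::slice_head(n = 1, by = "ligand_id") |>
    dplyr::select("ligand_id", best_cluster = "cluster", "median_feb", "tied")
  tab <- table(best$best_cluster)
  modal <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
  structure(
    list(
      medians = medians,
      best = best,
      modal_cluster = modal,
      concordance = mean(best$best_cluster == modal),
      n_ligands = nrow(best)
    ),
    class = "rffr_feb_summary"
  )
}

#' @export
print.rffr_feb_summary <- function(x, ...) {
  cat(sprintf("<rffr_feb_summary> %d ligands x %d clusters\n",
              x$n_ligands, dplyr::n_distinct(x$medians$cluster)))
  cat(sprintf("  modal best cluster: %d; concordance = %.3f\n",
              x$modal_cluster, x$concordance))
  if (any(x$best$tied)) {
    cat(sprintf("  argmin ties (broken to lower cluster index) for: %s\n",
                paste(x$best$ligand_id[x$best$tied], collapse = ", ")))
  }
  invisible(x)
}

#' Rank consistency of cluster FEB orderings across ligands
#'
#' For every ligand pair, the Spearman rank correlation between the two
#' ligands' cluster orderings by median FEB (over the clusters both cover).
#' Values near 1 mean the clusters sort the same way for all ligands, i.e.
#' cavity geometry rather than ligand identity drives the FEB ranking.
#'
#' @param summary An `rffr_feb_summary` from [cluster_feb_summary()].
#' @return A tibble `(ligand_a, ligand_b, rho)` with attribute `mean_rho`,
#'   the mean over pairs.
#' @export
rank_consistency <- function(summary) {
  stopifnot(inherits(summary, "rffr_feb_summary"))
  wide <- tidyr::pivot_wider(summary$medians[, c("ligand_id", "cluster", "median_feb")],
                             names_from = "ligand_id", values_from = "median_feb")
  if (nrow(wide) < 2) {
    stop_rffr("rank consistency needs at least 2 clusters.", "rffr_undefined_rank")
  }
  ligs <- setdiff(names(wide), "cluster")
  if (length(ligs) < 2) {
    stop_rffr("rank consistency needs at least 2 ligands.", "rffr_empty_input")
  }
  pairs <- utils::combn(ligs, 2)
  rho <- apply(pairs, 2, function(p) {
    ok <- stats::complete.cases(wide[, p])
    cor(wide[[p[1]]][ok], wide[[p[2]]][ok], method = "spearman")
  })
  out <- tibble::tibble(ligand_a = pairs[1, ], ligand_b = pairs[2, ], rho = rho)
  attr(out, "mean_rho") <- mean(rho)
  out
}
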