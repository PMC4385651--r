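# ggplot2 views of the fitted objects.

#' Plot the three validity-index curves
#'
#' Davies-Bouldin, Dunn and gap-statistic curves versus the number of
#' clusters, faceted with free y scales; the gap panel carries simulation
#' standard-error bars. The per-index optimum is circled.
#'
#' @param object An `rffr_validity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rffr_validity <- function(object, ...) {
  v <- tibble::as_tibble(object)
  long <- tidy.rffr_validity(object)
  opt <- dplyr::bind_rows(
    tibble::tibble(index = "db", k = v$k[which.min(v$db)], value = min(v$db)),
    tibble::tibble(index = "dunn", k = v$k[which.max(v$dunn)], value = max(v$dunn)),
    tibble::tibble(index = "gap", k = v$k[which.max(v$gap)], value = max(v$gap))
  )
  se <- dplyr::mutate(v, index = "gap", value = .data$gap)
  labs <- c(db = "Davies-Bouldin (lower better)",
            dunn = "Dunn (higher better)",
            gap = "Gap (higher better)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_errorbar(
      data = se,
      ggplot2::aes(ymin = .data$value - .data$gap_se,
                   ymax = .data$value + .data$gap_se),
      width = 0.2, linewidth = 0.3
    ) +
    ggplot2::geom_point(data = opt, shape = 1, size = 4, stroke = 1) +
    ggplot2::facet_wrap(~index, scales = "free_y",
                        labeller = ggplot2::as_labeller(labs)) +
    ggplot2::labs(x = "number of clusters k", y = NULL,
                  title = "Cluster-validity criteria across the k-means sweep") +
    ggplot2::theme_bw()
}

#' Plot cluster membership along the trajectory
#'
#' Cluster label versus simulation time, the view that shows whether
#' conformational clusters recur across timescales or form contiguous
#' strips.
#'
#' @param object An `rffr_partition`.
#' @param data The feature table the partition was fitted on (for `time_ps`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rffr_partition <- function(object, data, ...) {
  aug <- augment.rffr_partition(object, data)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time_ps / 1000,
                                    y = factor(.data$.cluster),
                                    colour = factor(.data$.cluster))) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = "time (ns)", y = "cluster",
                  title = sprintf("Cluster membership along the trajectory (k = %d)",
                                  object$k)) +
    ggplot2::theme_bw()
}

#' Plot per-cluster median FEB across ligands
#'
#' One line per cluster over the ligand axis; the planted/observed best
#' cluster shows up as the line running lowest for every ligand.
#'
#' @param object An `rffr_feb_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rffr_feb_summary <- function(object, ...) {
  m <- dplyr::mutate(object$medians,
                     best = .data$cluster == object$modal_cluster)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$ligand_id, y = .data$median_feb,
                                  group = factor(.data$cluster),
                                  colour = factor(.data$cluster),
                                  linewidth = .data$best)) +
    ggplot2::geom_line() +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.4, `TRUE` = 1.2),
                                    guide = "none") +
    ggplot2::labs(x = "ligand", y = "median FEB (kcal/mol)", colour = "cluster",
                  title = "Per-cluster median free energy of binding by ligand") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
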