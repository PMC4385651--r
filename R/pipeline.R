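#' Configure an end-to-end trajectory-reduction run
#'
#' Bundles every tunable of the pipeline: the feature (and optionally
#' docking) inputs, the k sweep, the seed, the gap-statistic settings, the
#' selection rule, the FEB run-collapse policy and the RFFR coverage rule.
#' Validation happens here, before any stage runs.
#'
#' @param features Path to a feature CSV or a feature tibble.
#' @param docking Optional path to a docking CSV or a docking tibble;
#'   enables the FEB-validation stage.
#' @param out_dir Output directory for stage artifacts (created if needed).
#' @param k_min,k_max Sweep range (defaults 2..15); `k_min` must be >= 2.
#' @param seed Master seed; recorded in the run manifest and every derived
#'   stage seed.
#' @param n_restarts k-means restarts per k.
#' @param b_refs Gap-statistic reference datasets.
#' @param gap_rule `"max"` or `"se"`; see [select_partition()].
#' @param min_per_cluster RFFR coverage minimum per cluster.
#' @param feb_collapse `"min"` or `"mean"`; see [snapshot_feb()].
#' @param normalize Apply [minmax_normalize()] before clustering (default
#'   TRUE; disable only for pre-normalised inputs).
#' @return An object of class `rffr_pipeline_config`.
#' @export
pipeline_config <- function(features, docking = NULL, out_dir = tempfile("rffr_run_"),
                            k_min = 2L, k_max = 15L, seed = 1L, n_restarts = 10L,
                            b_refs = 50L, gap_rule = c("max", "se"),
                            min_per_cluster = 2L, feb_collapse = c("min", "mean"),
                            normalize = TRUE) {
  gap_rule <- match.arg(gap_rule)
  feb_collapse <- match.arg(feb_collapse)
  if (k_min < 2) {
    stop_rffr("`k_min` must be at least 2.", "rffr_invalid_spec")
  }
  if (k_max < k_min) {
    stop_rffr("`k_max` must be >= `k_min`.", "rffr_invalid_spec")
  }
  structure(
    list(features = features, docking = docking, out_dir = out_dir,
         k_min = as.integer(k_min), k_max = as.integer(k_max),
         seed = as.integer(seed), n_restarts = as.integer(n_restarts),
         b_refs = as.integer(b_refs), gap_rule = gap_rule,
         min_per_cluster = as.integer(min_per_cluster),
         feb_collapse = feb_collapse, normalize = isTRUE(normalize)),
    class = "rffr_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the fields of [pipeline_config()] as top-level YAML keys.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return An `rffr_pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- utils::modifyList(y, list(...))
  do.call(pipeline_config, args)
}

config_fingerprint <- function(config) {
  stable <- config[setdiff(names(config), c("features", "docking", "out_dir"))]
  stable$features <- if (is.character(config$features)) config$features else "<in-memory>"
  stable$docking <- if (is.character(config$docking)) config$docking
                    else if (is.null(config$docking)) NULL else "<in-memory>"
  rlang::hash(stable)
}

load_table <- function(input, reader) {
  if (is.character(input)) reader(input) else tibble::as_tibble(input)
}

#' Run the trajectory-reduction pipeline end to end
#'
#' Executes normalise -> k-means sweep -> validity indices -> k selection
#' -> (if docking data are configured) FEB validation -> RFFR ensemble, and
#' writes every stage artifact plus a JSON run manifest into
#' `config$out_dir`. The manifest records the configuration, its
#' fingerprint, the master seed and the per-stage output paths, so an
#' identical config and seed reproduce identical outputs byte for byte.
#' Stage timings are logged to stderr.
#'
#' @param config An [pipeline_config()] object.
#' @return The run manifest (list), invisibly classed `rffr_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rffr_pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop_rffr(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                "rffr_stage_error", stage = name, parent = e)
    })
    inform(sprintf("[rffr] stage %-12s %.2fs", name,
                   as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  outputs <- list()
  out <- function(name) file.path(config$out_dir, name)

  features <- stage("features", load_table(config$features, read_feature_table))
  nf <- stage("normalize", {
    if (config$normalize) minmax_normalize(features)
    else {
      m <- as.matrix(features[, rffr_feature_columns()])
      structure(list(values = m, column_min = apply(m, 2, min),
                     column_max = apply(m, 2, max), constant = character(0),
                     row_ids = as.character(features$snapshot_id)),
                class = "rffr_features")
    }
  })
  sweep <- stage("cluster", kmeans_sweep(nf, config$k_min, config$k_max,
                                         seed = config$seed,
                                         n_restarts = config$n_restarts))
  stage("write-labels", {
    for (p in sweep) {
      readr::write_csv(partition_labels(p), out(sprintf("labels_k%02d.csv", p$k)))
      outputs[[sprintf("labels_k%02d", p$k)]] <- out(sprintf("labels_k%02d.csv", p$k))
      cent <- dplyr::bind_cols(tibble::tibble(cluster = seq_len(p$k)),
                               tibble::as_tibble(p$centroids, .name_repair = ~rffr_feature_columns()))
      readr::write_csv(cent, out(sprintf("centroids_k%02d.csv", p$k)))
      outputs[[sprintf("centroids_k%02d", p$k)]] <- out(sprintf("centroids_k%02d.csv", p$k))
    }
    NULL
  })
  validity <- stage("validity", validity_sweep(nf, sweep, b_refs = config$b_refs,
                                               seed = config$seed))
  readr::write_csv(tibble::as_tibble(validity), out("validity.csv"))
  outputs$validity <- out("validity.csv")
  choice <- stage("select", select_partition(validity, gap_rule = config$gap_rule))
  jsonlite::write_json(
    list(chosen_k = choice$chosen_k, candidate_db = choice$candidate_db,
         candidate_dunn = choice$candidate_dunn, candidate_gap = choice$candidate_gap,
         gap_rule = choice$gap_rule, rationale = choice$rationale),
    out("selection.json"), auto_unbox = TRUE, pretty = TRUE
  )
  outputs$selection <- out("selection.json")
  chosen <- sweep[[sprintf("k=%d", choice$chosen_k)]]

  summary <- NULL
  if (!is.null(config$docking)) {
    docking <- stage("read-docking", load_table(config$docking, read_docking_table))
    per_snap <- stage("collapse-feb", snapshot_feb(docking, collapse = config$feb_collapse))
    summary <- stage("validate-feb", cluster_feb_summary(per_snap, chosen))
    readr::write_csv(summary$medians, out("feb_summary.csv"))
    readr::write_csv(summary$best, out("feb_best_clusters.csv"))
    rk <- rank_consistency(summary)
    jsonlite::write_json(
      list(concordance = summary$concordance, modal_cluster = summary$modal_cluster,
           n_ligands = summary$n_ligands, mean_rank_rho = attr(rk, "mean_rho")),
      out("concordance.json"), auto_unbox = TRUE, pretty = TRUE
    )
    outputs$feb_summary <- out("feb_summary.csv")
    outputs$feb_best_clusters <- out("feb_best_clusters.csv")
    outputs$concordance <- out("concordance.json")
  }
  ensemble <- stage("build-rffr", build_rffr(chosen, x = nf,
                                             min_per_cluster = config$min_per_cluster))
  write_rffr_ids(ensemble, out("rffr_ids.txt"))
  readr::write_csv(ensemble$counts, out("rffr_counts.csv"))
  outputs$rffr_ids <- out("rffr_ids.txt")
  outputs$rffr_counts <- out("rffr_counts.csv")

  manifest <- list(
    config = unclass(config)[setdiff(names(config), c("features", "docking"))],
    config_hash = config_fingerprint(config),
    seed = config$seed,
    n_snapshots = nrow(features),
    chosen_k = choice$chosen_k,
    concordance = if (!is.null(summary)) summary$concordance else NULL,
    n_rffr = nrow(ensemble$selected),
    outputs = lapply(outputs, basename)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  inform(sprintf("[rffr] pipeline done in %.2fs -> %s",
                 as.numeric(Sys.time() - t_start, units = "secs"), config$out_dir))
  invisible(structure(manifest, class = "rffr_manifest"))
}
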