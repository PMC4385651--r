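#' Feature-table schema
#'
#' The four substrate-binding-cavity descriptors used to cluster an MD
#' trajectory, in table-column order: accessible surface area
#' (\eqn{\mbox{\AA}^2}), cavity volume (\eqn{\mbox{\AA}^3}), heavy-atom
#' count, and backbone RMSD versus the first frame (\eqn{\mbox{\AA}}).
#'
#' @return Character vector of the four feature column names.
#' @export
rffr_feature_columns <- function() {
  c("area_A2", "volume_A3", "heavy_atoms", "rmsd_A")
}

feature_schema <- function() {
  c("snapshot_id", "time_ps", rffr_feature_columns())
}

#' Read a trajectory feature table from CSV
#'
#' Expects the exact header `snapshot_id,time_ps,area_A2,volume_A3,
#' heavy_atoms,rmsd_A` (comma separated, `.` decimal separator, UTF-8).
#' Validates the table invariants: unique snapshot ids, strictly increasing
#' time, non-negative area/volume/RMSD.
#'
#' @param path Path to the CSV file.
#' @return A tibble with typed columns in schema order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop_rffr(sprintf("feature table not found: %s", path), "rffr_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(feature_schema(), header)
  if (length(missing)) {
    stop_rffr(
      sprintf("feature table is missing column(s): %s", paste(missing, collapse = ", ")),
      "rffr_schema_error", missing_columns = missing
    )
  }
  tbl <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      snapshot_id = readr::col_character(),
      time_ps = readr::col_double(),
      area_A2 = readr::col_double(),
      volume_A3 = readr::col_double(),
      heavy_atoms = readr::col_integer(),
      rmsd_A = readr::col_double(),
      .default = readr::col_guess()
    ),
    show_col_types = FALSE
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    stop_rffr(
      sprintf("non-numeric or malformed cell(s) at row(s) %s of %s",
              paste(unique(probs$row), collapse = ", "), path),
      "rffr_parse_error", problems = probs
    )
  }
  validate_feature_table(tbl[, feature_schema()])
}

validate_feature_table <- function(tbl) {
  dup <- tbl$snapshot_id[duplicated(tbl$snapshot_id)]
  if (length(dup)) {
    stop_rffr(
      sprintf("duplicate snapshot_id(s): %s", paste(unique(dup), collapse = ", ")),
      "rffr_integrity_error"
    )
  }
  if (nrow(tbl) > 1 && any(diff(tbl$time_ps) <= 0)) {
    stop_rffr("`time_ps` must be strictly increasing in file order.",
              "rffr_integrity_error")
  }
  neg <- vapply(c("area_A2", "volume_A3", "rmsd_A", "heavy_atoms"),
                function(cl) any(tbl[[cl]] < 0), logical(1))
  if (any(neg)) {
    stop_rffr(
      sprintf("negative values in column(s): %s",
              paste(names(neg)[neg], collapse = ", ")),
      "rffr_integrity_error"
    )
  }
  tbl
}

#' Write a trajectory feature table to CSV
#'
#' Writes exactly the schema columns (any extra columns, such as the
#' generator's `.cluster_true`, are dropped).
#'
#' @param tbl Feature table (tibble or data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  missing <- setdiff(feature_schema(), names(tbl))
  if (length(missing)) {
    stop_rffr(
      sprintf("feature table is missing column(s): %s", paste(missing, collapse = ", ")),
      "rffr_schema_error", missing_columns = missing
    )
  }
  readr::write_csv(tbl[, feature_schema()], path)
  invisible(path)
}

#' Min-max normalise the cavity features to [0, 1]
#'
#' Maps each feature column by `(x - min) / (max - min)` so that all four
#' descriptors, which carry different units and scales, contribute
#' comparably to the Euclidean distances used by k-means and the validity
#' indices. Min-max is the unique affine map of a column onto `[0, 1]`.
#' A constant column (max equal to min) is mapped to all zeros with a
#' warning, so a fixed heavy-atom count remains a valid configuration and
#' the feature count stays four. The per-column minima and maxima are
#' retained so the transform can be inverted with [denormalize()].
#'
#' @param tbl Feature table containing the four feature columns (and
#'   optionally `snapshot_id`, used as row identifiers).
#' @return An `rffr_features` object: normalised `values` matrix (n x 4),
#'   `column_min`, `column_max`, `row_ids`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_clusters = 2, duration_ns = 0.05)
#' nf <- minmax_normalize(generate_feature_table(spec))
#' range(nf$values)
minmax_normalize <- function(tbl) {
  if (nrow(tbl) == 0) {
    stop_rffr("feature table is empty.", "rffr_empty_input")
  }
  missing <- setdiff(rffr_feature_columns(), names(tbl))
  if (length(missing)) {
    stop_rffr(
      sprintf("feature table is missing column(s): %s", paste(missing, collapse = ", ")),
      "rffr_schema_error", missing_columns = missing
    )
  }
  X <- as.matrix(tbl[, rffr_feature_columns()])
  storage.mode(X) <- "double"
  cmin <- apply(X, 2, min)
  cmax <- apply(X, 2, max)
  const <- cmax == cmin
  if (any(const)) {
    warn(sprintf("constant feature column(s) normalised to 0: %s",
                 paste(colnames(X)[const], collapse = ", ")),
         class = "rffr_constant_column")
  }
  range <- ifelse(const, 1, cmax - cmin)
  V <- sweep(sweep(X, 2, cmin, "-"), 2, range, "/")
  V[, const] <- 0
  ids <- if ("snapshot_id" %in% names(tbl)) as.character(tbl$snapshot_id)
         else as.character(seq_len(nrow(tbl)))
  rownames(V) <- NULL
  structure(
    list(values = V, column_min = cmin, column_max = cmax,
         constant = colnames(X)[const], row_ids = ids),
    class = "rffr_features"
  )
}

#' Invert a min-max normalisation
#'
#' @param x An `rffr_features` object from [minmax_normalize()].
#' @return A tibble with `snapshot_id` and the four feature columns in
#'   original units. Constant columns are restored to their original value.
#' @export
denormalize <- function(x) {
  stopifnot(inherits(x, "rffr_features"))
  rng <- x$column_max - x$column_min
  rng[rng == 0] <- 0 # constant columns: normalised 0 maps back to the min
  X <- sweep(sweep(x$values, 2, rng, "*"), 2, x$column_min, "+")
  dplyr::bind_cols(tibble::tibble(snapshot_id = x$row_ids), tibble::as_tibble(X))
}

#' @export
print.rffr_features <- function(x, ...) {
  cat(sprintf("<rffr_features> %d snapshots x %d features, normalised to [0,1]\n",
              nrow(x$values), ncol(x$values)))
  rng <- rbind(min = x$column_min, max = x$column_max)
  print(round(rng, 3))
  if (length(x$constant)) {
    cat("constant column(s):", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.rffr_features <- function(x, ...) x$values
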