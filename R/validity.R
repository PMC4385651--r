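#' Davies-Bouldin index of a partition
#'
#' Average over clusters of the worst within-to-between scatter ratio:
#' \deqn{DB = \frac{1}{k} \sum_i \max_{j \ne i} \frac{\bar d_i + \bar d_j}{d_{i,j}}}
#' where \eqn{\bar d_i} is the mean Euclidean distance of cluster-i points to
#' their centroid and \eqn{d_{i,j}} the distance between centroids i and j.
#' Lower values indicate compact, well-separated partitions.
#'
#' @param x Normalised features (`rffr_features` or numeric matrix).
#' @param partition An `rffr_partition` over the same rows.
#' @return Non-negative scalar.
#' @export
davies_bouldin <- function(x, partition) {
  X <- feature_values(x)
  stopifnot(inherits(partition, "rffr_partition"))
  k <- partition$k
  if (k < 2) {
    stop_rffr("Davies-Bouldin is undefined for fewer than 2 clusters.",
              "rffr_undefined_index")
  }
  lab <- partition$labels
  C <- partition$centroids
  dbar <- vapply(seq_len(k), function(i) {
    pts <- X[lab == i, , drop = FALSE]
    mean(sqrt(cross_sqdist(pts, C[i, , drop = FALSE])[, 1]))
  }, numeric(1))
  dcc <- sqrt(cross_sqdist(C, C))
  off <- dcc[upper.tri(dcc)]
  if (any(off == 0)) {
    stop_rffr("coincident centroids: between-cluster distance is zero.",
              "rffr_degenerate_partition")
  }
  R <- outer(dbar, dbar, "+") / dcc
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Dunn's index of a partition
#'
#' Minimum inter-cluster separation divided by the maximum intra-cluster
#' diameter: separation between two clusters is the minimum pointwise
#' Euclidean distance (single linkage) and a cluster's diameter is its
#' maximum pairwise distance. Compact, well-separated partitions score high.
#'
#' @inheritParams davies_bouldin
#' @return Non-negative scalar.
#' @export
dunn_index <- function(x, partition) {
  X <- feature_values(x)
  stopifnot(inherits(partition, "rffr_partition"))
  k <- partition$k
  if (k < 2) {
    stop_rffr("Dunn's index is undefined for fewer than 2 clusters.",
              "rffr_undefined_index")
  }
  lab <- partition$labels
  groups <- lapply(seq_len(k), function(i) X[lab == i, , drop = FALSE])
  diam <- vapply(groups, function(G) {
    if (nrow(G) < 2) return(0)
    sqrt(max(cross_sqdist(G, G)))
  }, numeric(1))
  max_diam <- max(diam)
  if (max_diam == 0) {
    stop_rffr("all clusters are singletons or duplicate points: diameter is zero.",
              "rffr_undefined_index")
  }
  sep <- Inf
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sep <- min(sep, min(cross_sqdist(groups[[i]], groups[[j]])))
    }
  }
  sqrt(sep) / max_diam
}

#' Pooled within-cluster dispersion W
#'
#' \eqn{W = \sum_r D_r / (2 n_r)} with \eqn{D_r} the sum of squared
#' Euclidean distances over all ordered pairs within cluster r — which is
#' algebraically the total within-cluster sum of squares about the cluster
#' means. This is the dispersion the gap statistic compares against its
#' reference distribution.
#'
#' @param x Normalised features (`rffr_features` or numeric matrix).
#' @param labels Integer cluster labels.
#' @return Non-negative scalar.
#' @export
within_dispersion <- function(x, labels) {
  X <- feature_values(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(X))
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    G <- X[idx, , drop = FALSE]
    sum(sweep(G, 2, colMeans(G))^2)
  }, numeric(1)))
}

#' Gap statistic across a k-means sweep
#'
#' Compares the log within-cluster dispersion of each fitted partition with
#' its expectation under a reference null of no cluster structure:
#' \deqn{Gap(k) = E^*[\log W_k] - \log W_k.}
#' The expectation is estimated from `b_refs` Monte-Carlo reference datasets
#' drawn uniformly over the per-feature [min, max] box of the observed
#' matrix (for min-max normalised features, the unit box) and clustered with
#' the same k-means settings as the observed sweep. The simulation standard
#' error is \eqn{s_k = sd_b[\log W_k^{(b)}] \sqrt{1 + 1/B}}.
#'
#' @param x Normalised features the sweep was fitted on.
#' @param partitions An `rffr_sweep` or list of `rffr_partition` objects.
#' @param b_refs Number of reference datasets (at least 2).
#' @param seed Integer seed for the reference draws and their clustering.
#' @return A tibble `(k, gap, gap_se, log_wk)`, one row per partition.
#' @export
gap_statistic <- function(x, partitions, b_refs = 50L, seed = 1L) {
  X <- feature_values(x)
  if (inherits(partitions, "rffr_partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1)
  if (b_refs < 2) {
    stop_rffr("`b_refs` must be at least 2.", "rffr_invalid_spec")
  }
  partitions <- unname(unclass(partitions))
  ks <- vapply(partitions, function(p) p$k, integer(1))
  n_restarts <- vapply(partitions, function(p) p$n_restarts, integer(1))
  log_wk <- vapply(partitions, function(p) {
    w <- within_dispersion(X, p$labels)
    if (w <= 0) {
      stop_rffr("degenerate dispersion: W = 0 (all clusters singletons or duplicates).",
                "rffr_degenerate_dispersion")
    }
    log(w)
  }, numeric(1))
  n <- nrow(X)
  cmin <- apply(X, 2, min)
  crange <- apply(X, 2, max) - cmin
  seeds <- derive_seeds(seed, b_refs * (length(ks) + 1L))
  log_wkb <- matrix(NA_real_, nrow = b_refs, ncol = length(ks))
  for (b in seq_len(b_refs)) {
    Xb <- withr::with_seed(seeds[(b - 1L) * (length(ks) + 1L) + 1L], {
      matrix(runif(n * ncol(X)), nrow = n)
    })
    Xb <- sweep(sweep(Xb, 2, crange, "*"), 2, cmin, "+")
    for (j in seq_along(ks)) {
      pb <- kmeans_partition(Xb, ks[j],
                             seed = seeds[(b - 1L) * (length(ks) + 1L) + 1L + j],
                             n_restarts = n_restarts[j])
      log_wkb[b, j] <- log(pb$inertia)
    }
  }
  gap <- colMeans(log_wkb) - log_wk
  se <- apply(log_wkb, 2, sd) * sqrt(1 + 1 / b_refs)
  tibble::tibble(k = ks, gap = gap, gap_se = se, log_wk = log_wk)
}

#' Validity indices for every partition of a sweep
#'
#' Computes the Davies-Bouldin index, Dunn's index and the gap statistic for
#' each partition, the three criteria used jointly to pick the number of
#' conformational clusters.
#'
#' @inheritParams gap_statistic
#' @param sweep An `rffr_sweep` from [kmeans_sweep()].
#' @return A tibble of class `rffr_validity` with columns
#'   `k, db, dunn, gap, gap_se, log_wk`, sorted by `k`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.15)
#' nf <- minmax_normalize(generate_feature_table(spec))
#' sw <- kmeans_sweep(nf, 2, 6, seed = 1, n_restarts = 5)
#' validity_sweep(nf, sw, b_refs = 5, seed = 1)
validity_sweep <- function(x, sweep, b_refs = 50L, seed = 1L) {
  stopifnot(inherits(sweep, "rffr_sweep") || is.list(sweep))
  parts <- unclass(sweep)
  gp <- gap_statistic(x, parts, b_refs = b_refs, seed = seed)
  out <- tibble::tibble(
    k = gp$k,
    db = vapply(parts, function(p) davies_bouldin(x, p), numeric(1)),
    dunn = vapply(parts, function(p) dunn_index(x, p), numeric(1)),
    gap = gp$gap,
    gap_se = gp$gap_se,
    log_wk = gp$log_wk
  )
  out <- dplyr::arrange(out, .data$k)
  class(out) <- c("rffr_validity", class(out))
  attr(out, "b_refs") <- as.integer(b_refs)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Choose the optimal number of clusters
#'
#' Each index nominates a candidate: the k minimising Davies-Bouldin, the k
#' maximising Dunn, and the k maximising the gap statistic. If all three
#' agree, that k is chosen. Otherwise the gap statistic is the decisive
#' criterion: among the distinct candidates, the one with the highest gap
#' wins; residual ties break by higher Dunn, then lower DB, then smaller k.
#' The `rationale` field records every comparison made.
#'
#' With `gap_rule = "se"`, the gap candidate is instead the smallest k with
#' `gap(k) >= gap(k+1) - se(k+1)` (the one-standard-error rule), a
#' conservative variant for noisy gap curves.
#'
#' @param validity An `rffr_validity` tibble from [validity_sweep()].
#' @param gap_rule `"max"` (default) or `"se"`.
#' @return An object of class `rffr_k_choice` with fields `chosen_k`,
#'   `candidate_db`, `candidate_dunn`, `candidate_gap`, `rationale`.
#' @export
select_partition <- function(validity, gap_rule = c("max", "se")) {
  gap_rule <- match.arg(gap_rule)
  v <- tibble::as_tibble(validity)
  if (nrow(v) == 0) {
    stop_rffr("validity sweep is empty.", "rffr_empty_input")
  }
  v <- dplyr::arrange(v, .data$k)
  cand_db <- v$k[which.min(v$db)]
  cand_dunn <- v$k[which.max(v$dunn)]
  cand_gap <- if (gap_rule == "max" || nrow(v) == 1) {
    v$k[which.max(v$gap)]
  } else {
    hit <- which(v$gap[-nrow(v)] >= v$gap[-1] - v$gap_se[-1])
    if (length(hit)) v$k[hit[1]] else v$k[which.max(v$gap)]
  }
  rationale <- c(
    sprintf("Davies-Bouldin minimised at k = %d (DB = %.4f).",
            cand_db, v$db[v$k == cand_db]),
    sprintf("Dunn maximised at k = %d (Dunn = %.4f).",
            cand_dunn, v$dunn[v$k == cand_dunn]),
    sprintf("Gap candidate (rule '%s') at k = %d (gap = %.4f).",
            gap_rule, cand_gap, v$gap[v$k == cand_gap])
  )
  cands <- unique(c(cand_db, cand_dunn, cand_gap))
  if (length(cands) == 1) {
    chosen <- cands
    rationale <- c(rationale, sprintf(
      "All three criteria agree: k = %d chosen unanimously.", chosen))
  } else {
    cv <- v[v$k %in% cands, ]
    ord <- order(-cv$gap, -cv$dunn, cv$db, cv$k)
    chosen <- cv$k[ord[1]]
    rationale <- c(rationale,
      sprintf("Candidates disagree (%s); gap statistic is the decisive criterion.",
              paste(sprintf("k=%d", sort(cands)), collapse = ", ")),
      sprintf("Gap over candidates: %s.",
              paste(sprintf("gap(%d)=%.4f", cv$k, cv$gap), collapse = ", ")),
      sprintf("Chosen k = %d (highest gap; ties would break by Dunn, then DB, then smaller k).",
              chosen))
  }
  structure(
    list(chosen_k = chosen, candidate_db = cand_db, candidate_dunn = cand_dunn,
         candidate_gap = cand_gap, gap_rule = gap_rule, rationale = rationale,
         validity = v),
    class = "rffr_k_choice"
  )
}

#' @export
print.rffr_k_choice <- function(x, ...) {
  cat(sprintf("<rffr_k_choice> chosen k = %d (candidates: DB %d, Dunn %d, gap %d)\n",
              x$chosen_k, x$candidate_db, x$candidate_dunn, x$candidate_gap))
  cat(paste0("  ", x$rationale, collapse = "\n"), "\n")
  invisible(x)
}
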