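#' Seeded k-means on the normalised cavity features
#'
#' Lloyd's algorithm with k-means++ initialisation, run `n_restarts` times
#' from different seedings; the restart with the lowest total within-cluster
#' sum of squares (inertia) is kept. Iterations stop when no label changes
#' or after `max_iter` iterations. Should a cluster empty during iteration,
#' it is repaired by reassigning to it the point currently farthest from its
#' own centroid, preserving the non-empty-cluster invariant the validity
#' indices require. Nearest-centroid ties break to the lowest cluster index,
#' making runs bit-reproducible for a given `(seed, n_restarts)`.
#'
#' @param x An `rffr_features` object from [minmax_normalize()], or a numeric
#'   matrix (rows = snapshots).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed controlling all initialisations.
#' @param n_restarts Number of independent k-means++ restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return An object of class `rffr_partition`: `k`, `labels` (integers in
#'   `1..k` aligned with `row_ids`), `centroids` (k x p), `sizes`, `inertia`,
#'   `iterations`, `converged`, `seed`, `n_restarts`.
#' @seealso [kmeans_sweep()] to run a range of `k`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.2)
#' nf <- minmax_normalize(generate_feature_table(spec))
#' part <- kmeans_partition(nf, k = 3, seed = 7)
#' part$sizes
kmeans_partition <- function(x, k, seed = 1L, n_restarts = 10L, max_iter = 300L) {
  X <- feature_values(x)
  n <- nrow(X)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop_rffr("`k` must be a positive integer.", "rffr_invalid_k")
  }
  k <- as.integer(k)
  if (k > n) {
    stop_rffr(sprintf("k = %d exceeds the number of points (%d).", k, n),
              "rffr_infeasible_k")
  }
  if (n_restarts < 1) {
    stop_rffr("`n_restarts` must be a positive integer.", "rffr_invalid_spec")
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      C0 <- kmeanspp_init(X, k)
      fit <- lloyd_iterate(X, C0, max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(
    list(
      k = k,
      labels = best$labels,
      centroids = best$centroids,
      sizes = tabulate(best$labels, k),
      inertia = best$inertia,
      iterations = best$iterations,
      converged = best$converged,
      row_ids = feature_row_ids(x),
      seed = as.integer(seed),
      n_restarts = as.integer(n_restarts)
    ),
    class = "rffr_partition"
  )
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, each
# subsequent centre sampled with probability proportional to the squared
# distance to the nearest centre chosen so far.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centres <- integer(k)
  centres[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- cross_sqdist(X, X[centres[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      tot <- sum(d2)
      centres[j] <- if (tot <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, cross_sqdist(X, X[centres[j], , drop = FALSE])[, 1])
    }
  }
  X[centres, , drop = FALSE]
}

lloyd_iterate <- function(X, C, max_iter = 300L) {
  n <- nrow(X)
  k <- nrow(C)
  prev <- rep(-1L, n)
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    D <- cross_sqdist(X, C)
    labels <- max.col(-D, ties.method = "first")
    if (identical(labels, prev)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    prev <- labels
    counts <- tabulate(labels, k)
    empty <- which(counts == 0L)
    for (j in empty) {
      # repair: hand the empty cluster the point farthest from its centroid
      far <- which.max(D[cbind(seq_len(n), labels)])
      labels[far] <- j
      D[far, ] <- 0 # excluded from further farthest-point searches this pass
      counts <- tabulate(labels, k)
      prev <- rep(-1L, n) # force another assignment pass
    }
    S <- rowsum(X, labels, reorder = TRUE)
    C <- S / counts
  }
  inertia <- sum(D[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = unname(C), inertia = inertia,
       iterations = it, converged = converged)
}

#' Run k-means across a range of cluster counts
#'
#' One [kmeans_partition()] fit per `k` in `k_min..k_max` (the trajectory
#' analysis sweeps k = 2..15 by default), with a per-k seed derived
#' deterministically from the master seed so the whole sweep is reproducible
#' and individual fits are independent.
#'
#' @inheritParams kmeans_partition
#' @param k_min,k_max Inclusive sweep range, `1 <= k_min <= k_max <= n`.
#' @return An object of class `rffr_sweep`: a list of `rffr_partition`
#'   objects named `"k=<k>"`, with the sweep settings as attributes.
#' @export
kmeans_sweep <- function(x, k_min = 2L, k_max = 15L, seed = 1L,
                         n_restarts = 10L, max_iter = 300L) {
  X <- feature_values(x)
  if (k_min < 1 || k_min > k_max) {
    stop_rffr("need 1 <= k_min <= k_max.", "rffr_invalid_k")
  }
  if (k_max > nrow(X)) {
    stop_rffr(sprintf("k_max = %d exceeds the number of points (%d).",
                      k_max, nrow(X)), "rffr_infeasible_k")
  }
  ks <- seq.int(k_min, k_max)
  seeds <- derive_seeds(seed, length(ks))
  parts <- purrr::map2(ks, seeds, function(k, s) {
    kmeans_partition(x, k, seed = s, n_restarts = n_restarts, max_iter = max_iter)
  })
  names(parts) <- sprintf("k=%d", ks)
  inert <- vapply(parts, function(p) p$inertia, numeric(1))
  bump <- which(diff(inert) > 0)
  if (length(bump)) {
    # inertia should be non-increasing in k; a rare marginal increase means a
    # restart landed in a local optimum — flagged, not fatal
    inform(sprintf("inertia increased at k = %s; consider more restarts",
                   paste(ks[bump + 1L], collapse = ", ")),
           class = "rffr_inertia_flag")
  }
  structure(parts, class = "rffr_sweep", k_range = range(ks),
            seed = as.integer(seed), n_restarts = as.integer(n_restarts))
}

#' @export
print.rffr_partition <- function(x, ...) {
  cat(sprintf("<rffr_partition> k = %d over %d snapshots; inertia = %.6g (%d iter%s)\n",
              x$k, length(x$labels), x$inertia, x$iterations,
              if (x$converged) ", converged" else ", max_iter reached"))
  cat("cluster sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.rffr_sweep <- function(x, ...) {
  kr <- attr(x, "k_range")
  cat(sprintf("<rffr_sweep> k = %d..%d (%d partitions), seed %d, %d restarts\n",
              kr[1], kr[2], length(x), attr(x, "seed"), attr(x, "n_restarts")))
  invisible(x)
}

#' Cluster labels of a partition as a tibble
#'
#' @param partition An `rffr_partition`.
#' @return A tibble `(snapshot_id, cluster)`.
#' @export
partition_labels <- function(partition) {
  stopifnot(inherits(partition, "rffr_partition"))
  tibble::tibble(snapshot_id = partition$row_ids,
                 cluster = as.integer(partition$labels))
}
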