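# Independent brute-force oracles: direct double loops and exhaustive
# enumeration, sharing no code with the implementation under test.

bf_davies_bouldin <- function(X, lab) {
  ks <- sort(unique(lab))
  cent <- t(sapply(ks, function(i) colMeans(X[lab == i, , drop = FALSE])))
  if (ncol(X) == 1) cent <- matrix(cent, ncol = 1)
  dbar <- sapply(seq_along(ks), function(ii) {
    pts <- X[lab == ks[ii], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - cent[ii, ])^2))))
  })
  terms <- sapply(seq_along(ks), function(ii) {
    max(sapply(setdiff(seq_along(ks), ii), function(jj) {
      (dbar[ii] + dbar[jj]) / sqrt(sum((cent[ii, ] - cent[jj, ])^2))
    }))
  })
  mean(terms)
}

bf_dunn <- function(X, lab) {
  ks <- sort(unique(lab))
  diam <- 0
  for (i in ks) {
    idx <- which(lab == i)
    if (length(idx) > 1) {
      for (a in idx) for (b in idx) {
        diam <- max(diam, sqrt(sum((X[a, ] - X[b, ])^2)))
      }
    }
  }
  sep <- Inf
  for (ii in seq_along(ks)) {
    for (jj in seq_along(ks)) {
      if (ii >= jj) next
      for (a in which(lab == ks[ii])) for (b in which(lab == ks[jj])) {
        sep <- min(sep, sqrt(sum((X[a, ] - X[b, ])^2)))
      }
    }
  }
  sep / diam
}

# literal pooled within-cluster dispersion: ordered-pair squared distances
bf_within_dispersion <- function(X, lab) {
  total <- 0
  for (i in sort(unique(lab))) {
    idx <- which(lab == i)
    Dr <- 0
    for (a in idx) for (b in idx) {
      Dr <- Dr + sum((X[a, ] - X[b, ])^2)
    }
    total <- total + Dr / (2 * length(idx))
  }
  total
}

# exhaustive global k-means optimum: enumerate every assignment of n points
# to k labels and minimise the within-cluster sum of squares (n <= 10)
bf_kmeans_optimum <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 10)
  best <- Inf
  lab <- integer(n)
  for (code in 0:(k^n - 1)) {
    c0 <- code
    for (i in seq_len(n)) {
      lab[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    wss <- 0
    for (j in unique(lab)) {
      G <- X[lab == j, , drop = FALSE]
      wss <- wss + sum(sweep(G, 2, colMeans(G))^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# wrap bare labels as a partition object for the validity functions
make_partition <- function(X, lab, seed = 0L) {
  lab <- as.integer(lab)
  k <- max(lab)
  cent <- t(vapply(seq_len(k), function(i) colMeans(X[lab == i, , drop = FALSE]),
                   numeric(ncol(X))))
  if (ncol(X) == 1) cent <- matrix(cent, ncol = 1)
  inertia <- sum(vapply(seq_len(k), function(i) {
    G <- X[lab == i, , drop = FALSE]
    sum(sweep(G, 2, colMeans(G))^2)
  }, numeric(1)))
  structure(
    list(k = k, labels = lab, centroids = unname(cent),
         sizes = tabulate(lab, k), inertia = inertia, iterations = 0L,
         converged = TRUE, row_ids = as.character(seq_len(nrow(X))),
         seed = seed, n_restarts = 1L),
    class = "rffr_partition"
  )
}

# small planted-blob matrix for validity/clustering tests
make_blobs <- function(n_per, centers, sd = 0.02, seed = 1) {
  k <- nrow(centers)
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                   sd = sd), nrow = n_per)
    }))
  })
  list(X = X, labels = rep(seq_len(k), each = n_per))
}
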