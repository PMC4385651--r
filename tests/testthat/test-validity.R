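test_that("Davies-Bouldin matches hand computations", {
  # two singleton clusters: zero within-scatter -> DB = 0
  X <- matrix(c(0, 5), ncol = 1)
  expect_equal(davies_bouldin(X, make_partition(X, c(1, 2))), 0)
  # {0,2} and {10,12}: dbar = 1 each, centroid distance 10 -> DB = 0.2
  X2 <- matrix(c(0, 2, 10, 12), ncol = 1)
  expect_equal(davies_bouldin(X2, make_partition(X2, c(1, 1, 2, 2))), 0.2)
})

test_that("Dunn matches hand computations and degenerates as defined", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(dunn_index(X, make_partition(X, c(1, 1, 2, 2))), 9)
  # duplicate point split across clusters -> zero separation
  X2 <- matrix(c(0, 1, 1, 5), ncol = 1)
  expect_equal(dunn_index(X2, make_partition(X2, c(1, 1, 2, 2))), 0)
  # all singletons: diameter zero -> undefined
  X3 <- matrix(c(0, 1, 2), ncol = 1)
  expect_error(dunn_index(X3, make_partition(X3, c(1, 2, 3))),
               class = "rffr_undefined_index")
})

test_that("DB and Dunn agree with brute-force double-loop oracles", {
  for (case in 1:5) {
    withr::with_seed(200 + case, {
      k <- sample(2:5, 1)
      n <- sample(50:200, 1)
      X <- matrix(runif(n * 4), ncol = 4)
      lab <- c(seq_len(k), sample.int(k, n - k, replace = TRUE)) # all non-empty
    })
    p <- make_partition(X, lab)
    expect_equal(davies_bouldin(X, p), bf_davies_bouldin(X, lab), tolerance = 1e-9)
    expect_equal(dunn_index(X, p), bf_dunn(X, lab), tolerance = 1e-9)
  }
})

test_that("indices are invariant under relabeling and row permutation", {
  blobs <- make_blobs(25, matrix(runif(12), ncol = 4), sd = 0.05, seed = 10)
  X <- blobs$X
  lab <- blobs$labels
  p <- make_partition(X, lab)
  relab <- c(3L, 1L, 2L)[lab]
  p_relab <- make_partition(X, relab)
  expect_equal(davies_bouldin(X, p_relab), davies_bouldin(X, p), tolerance = 1e-12)
  expect_equal(dunn_index(X, p_relab), dunn_index(X, p), tolerance = 1e-12)
  withr::with_seed(1, perm <- sample(nrow(X)))
  p_perm <- make_partition(X[perm, ], lab[perm])
  expect_equal(davies_bouldin(X[perm, ], p_perm), davies_bouldin(X, p),
               tolerance = 1e-12)
  expect_equal(dunn_index(X[perm, ], p_perm), dunn_index(X, p), tolerance = 1e-12)
  expect_equal(within_dispersion(X[perm, ], lab[perm]), within_dispersion(X, lab),
               tolerance = 1e-12)
})

test_that("Dunn is invariant under global scaling of the features", {
  blobs <- make_blobs(15, matrix(runif(8), ncol = 4) + 0.5, sd = 0.02, seed = 11)
  p <- make_partition(blobs$X, blobs$labels)
  p_scaled <- make_partition(blobs$X * 7, blobs$labels)
  expect_equal(dunn_index(blobs$X * 7, p_scaled), dunn_index(blobs$X, p),
               tolerance = 1e-9)
})

test_that("degenerate partitions raise index-specific errors", {
  X <- matrix(c(0, 0, 1, 1), ncol = 1)
  p <- make_partition(X, c(1, 1, 2, 2))
  expect_error(davies_bouldin(X, make_partition(X, c(1, 2, 1, 2))),
               class = "rffr_degenerate_partition") # coincident centroids
  one <- kmeans_partition(matrix(runif(10), ncol = 2), 1)
  expect_error(davies_bouldin(matrix(runif(10), ncol = 2), one),
               class = "rffr_undefined_index")
})

test_that("pooled dispersion W matches the literal pairwise formula and inertia", {
  # one cluster of two points at squared distance 1: D = 2, W = 2/(2*2) = 0.5
  X <- matrix(c(0, 1), ncol = 1)
  expect_equal(within_dispersion(X, c(1, 1)), 0.5)
  for (case in 1:4) {
    withr::with_seed(300 + case, {
      n <- sample(20:60, 1)
      X <- matrix(runif(n * 3), ncol = 3)
      lab <- c(1:3, sample.int(3, n - 3, replace = TRUE))
    })
    expect_equal(within_dispersion(X, lab), bf_within_dispersion(X, lab),
                 tolerance = 1e-9)
  }
  # centroid-assigned partitions: W equals the k-means inertia exactly
  withr::with_seed(12, X <- matrix(runif(120 * 4), ncol = 4))
  for (k in c(2, 4, 7)) {
    p <- kmeans_partition(X, k, seed = k)
    expect_equal(within_dispersion(X, p$labels), p$inertia, tolerance = 1e-9)
  }
})

test_that("gap statistic favours k = 1 on a single Gaussian blob", {
  hits <- 0
  for (rep in 1:20) {
    withr::with_seed(400 + rep,
      X <- matrix(rnorm(150 * 2, mean = 0.5, sd = 0.08), ncol = 2))
    parts <- lapply(1:5, function(k) kmeans_partition(X, k, seed = rep, n_restarts = 5))
    g <- gap_statistic(X, parts, b_refs = 8, seed = rep)
    if (all(g$gap[1] >= g$gap[2:5])) hits <- hits + 1
  }
  expect_gte(hits, 18) # >= 90% of 20 replicates
})

test_that("the selection rule applies the decisive gap criterion", {
  base <- tibble::tibble(k = 9:12, gap_se = 0.01, log_wk = 0)
  # DB prefers 11, Dunn and gap prefer 10, gap(10) > gap(11) -> 10
  v <- dplyr::mutate(base,
    db = c(1.0, 0.8, 0.7, 0.9)[match(k, 9:12)],
    dunn = c(0.2, 0.9, 0.5, 0.3)[match(k, 9:12)],
    gap = c(0.5, 1.4, 1.1, 0.6)[match(k, 9:12)]
  )
  sel <- select_partition(v)
  expect_equal(sel$candidate_db, 11)
  expect_equal(sel$candidate_dunn, 10)
  expect_equal(sel$candidate_gap, 10)
  expect_equal(sel$chosen_k, 10)
  expect_true(any(grepl("decisive", sel$rationale)))
  # unanimity short-circuits
  v2 <- dplyr::mutate(base,
    db = c(0.9, 0.4, 0.8, 1.0)[match(k, 9:12)],
    dunn = c(0.1, 0.8, 0.2, 0.2)[match(k, 9:12)],
    gap = c(0.3, 1.2, 0.9, 0.4)[match(k, 9:12)]
  )
  sel2 <- select_partition(v2)
  expect_equal(sel2$chosen_k, 10)
  expect_true(any(grepl("unanimous", sel2$rationale)))
  expect_error(select_partition(v[0, ]), class = "rffr_empty_input")
})

test_that("a secondary Dunn optimum at k = 2 is rejected by DB and gap", {
  v <- tibble::tibble(
    k = c(2, 9, 10, 11),
    db = c(1.5, 0.9, 0.6, 0.7),
    dunn = c(1.1, 0.3, 0.9, 0.4), # bimodal: spurious optimum at k = 2
    gap = c(0.2, 0.8, 1.3, 1.0),
    gap_se = 0.01, log_wk = 0
  )
  sel <- select_partition(v)
  expect_equal(sel$candidate_dunn, 2)
  expect_false(sel$chosen_k == 2)
  expect_equal(sel$chosen_k, 10)
})

test_that("the one-standard-error gap rule is more conservative than argmax", {
  v <- tibble::tibble(
    k = 2:6,
    db = c(1, 0.9, 0.8, 0.85, 0.9),
    dunn = c(0.2, 0.3, 0.45, 0.4, 0.35),
    gap = c(0.50, 0.58, 0.60, 0.61, 0.615),
    gap_se = c(0.05, 0.05, 0.05, 0.05, 0.05),
    log_wk = 0
  )
  # first k with gap(k) >= gap(k+1) - se(k+1): 0.58 >= 0.60 - 0.05 at k = 3
  expect_equal(select_partition(v, gap_rule = "se")$candidate_gap, 3)
  expect_equal(select_partition(v, gap_rule = "max")$candidate_gap, 6)
})

test_that("model selection recovers planted cluster counts", {
  for (c_true in c(3, 5, 10)) {
    hits <- 0
    for (rep in 1:20) {
      spec <- synthetic_spec(n_clusters = c_true, duration_ns = 0.04 * c_true,
                             seed = 1000 * c_true + rep)
      nf <- minmax_normalize(generate_feature_table(spec))
      sw <- kmeans_sweep(nf, 2, c_true + 3, seed = rep, n_restarts = 6)
      v <- validity_sweep(nf, sw, b_refs = 8, seed = rep)
      if (select_partition(v)$chosen_k == c_true) hits <- hits + 1
    }
    expect_gte(hits, 18) # >= 90% of 20 seeded replicates
  }
})
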