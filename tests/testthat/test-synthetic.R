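test_that("snapshot count follows floor(duration_ns * 1000 / interval_ps)", {
  expect_equal(synthetic_spec(duration_ns = 0.001, interval_ps = 1)$n_snapshots, 1L)
  tiny <- generate_feature_table(synthetic_spec(duration_ns = 0.001, interval_ps = 1))
  expect_equal(nrow(tiny), 1L)
  expect_equal(tiny$time_ps, 1)
  expect_equal(synthetic_spec(duration_ns = 1.5, interval_ps = 4)$n_snapshots, 375L)
  expect_error(synthetic_spec(duration_ns = 0), class = "rffr_invalid_spec")
  expect_error(synthetic_spec(interval_ps = -1), class = "rffr_invalid_spec")
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(n_clusters = 3, mixing_weights = c(0.5, 0.5, 0.1)),
               class = "rffr_invalid_spec")
  expect_error(synthetic_spec(n_clusters = 3, mixing_weights = c(0.6, 0.4, 0)),
               class = "rffr_invalid_spec")
  expect_error(synthetic_spec(n_clusters = 3, feb_cluster_offset = c(-2, -2, 0)),
               class = "rffr_invalid_spec")
  expect_error(synthetic_spec(n_clusters = 2, ligand_ids = c("A", "A")),
               class = "rffr_invalid_spec")
})

test_that("same seed gives identical feature and docking tables", {
  spec <- synthetic_spec(n_clusters = 4, duration_ns = 0.3, seed = 11,
                         ligand_ids = c("L1", "L2"), runs_per_pair = 3)
  t1 <- generate_feature_table(spec)
  t2 <- generate_feature_table(spec)
  expect_identical(t1, t2)
  d1 <- generate_docking_table(spec, t1$.cluster_true)
  d2 <- generate_docking_table(spec, t1$.cluster_true)
  expect_identical(d1, d2)
  t3 <- generate_feature_table(synthetic_spec(n_clusters = 4, duration_ns = 0.3,
                                              seed = 12, ligand_ids = c("L1", "L2")))
  expect_false(identical(t1$area_A2, t3$area_A2))
})

test_that("planted labels are recoverable by nearest-centroid at high separation", {
  means <- rbind(c(600, 900, 310, 0.8), c(1100, 1400, 360, 2.4))
  sds <- matrix(rep(c(5, 6, 1, 0.02), each = 2), nrow = 2)
  spec <- synthetic_spec(n_clusters = 2, duration_ns = 0.2, cluster_means = means,
                         cluster_sds = sds, seed = 5)
  expect_gte(min_cluster_separation(spec), 20)
  tr <- generate_feature_table(spec)
  X <- as.matrix(tr[, rffr_feature_columns()])
  # brute-force nearest-mean assignment of every generated point
  nearest <- apply(X, 1, function(p) {
    which.min(c(sum((p - means[1, ])^2), sum((p - means[2, ])^2)))
  })
  expect_equal(as.integer(nearest), tr$.cluster_true)
})

test_that("per-cluster feature means converge to the planted means", {
  spec <- synthetic_spec(duration_ns = 3, seed = 3)
  tr <- generate_feature_table(spec)
  for (cl in seq_len(spec$n_clusters)) {
    rows <- tr$.cluster_true == cl
    n_r <- sum(rows)
    expect_gte(n_r, 100)
    emp <- colMeans(as.matrix(tr[rows, rffr_feature_columns()]))
    tol <- 3 * spec$cluster_sds[cl, ] / sqrt(n_r)
    expect_true(all(abs(emp - spec$cluster_means[cl, ]) <= tol),
                info = sprintf("cluster %d mean outside 3 sd/sqrt(n)", cl))
  }
})

test_that("features respect domain constraints even near zero", {
  means <- rbind(c(5, 5, 2, 0.03), c(8, 9, 4, 0.05))
  sds <- matrix(rep(c(4, 4, 2, 0.05), each = 2), nrow = 2)
  spec <- synthetic_spec(n_clusters = 2, duration_ns = 0.5, cluster_means = means,
                         cluster_sds = sds, seed = 9)
  tr <- generate_feature_table(spec)
  expect_true(all(tr$area_A2 >= 0))
  expect_true(all(tr$volume_A3 >= 0))
  expect_true(all(tr$rmsd_A >= 0))
  expect_true(is.integer(tr$heavy_atoms) && all(tr$heavy_atoms >= 0))
})

test_that("zero-noise docking values equal base plus cluster offset", {
  spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.005,
                         ligand_ids = c("L1", "L2"), feb_noise_sd = 0,
                         runs_per_pair = 4,
                         feb_cluster_offset = c(-2, 0.3, 0.7))
  d <- generate_docking_table(spec, labels = c(2L, 1L, 3L, 2L, 1L))
  expected <- spec$feb_base[d$ligand_id] +
    spec$feb_cluster_offset[c(2L, 1L, 3L, 2L, 1L)[match(d$snapshot_id,
                                                        unique(d$snapshot_id))]]
  expect_equal(d$feb_kcal_mol, unname(expected))
})

test_that("docking table has runs_per_pair rows per (snapshot, ligand)", {
  spec <- synthetic_spec(n_clusters = 2, duration_ns = 0.01,
                         ligand_ids = c("A", "B"), runs_per_pair = 25)
  d <- generate_docking_table(spec, labels = rep(1L, 10))
  expect_equal(nrow(d), 10 * 2 * 25)
  expect_equal(nrow(dplyr::distinct(d, snapshot_id, ligand_id, run)), nrow(d))
})

test_that("planted best cluster attains the minimal median FEB for every ligand", {
  spec <- synthetic_spec(n_clusters = 4, duration_ns = 0.2,
                         ligand_ids = sprintf("L%d", 1:5),
                         feb_cluster_offset = c(0, -2, 0.5, 1),
                         feb_noise_sd = 0.1, runs_per_pair = 5, seed = 21)
  labels <- rep(1:4, each = 50)
  d <- generate_docking_table(spec, labels)
  med <- d |>
    dplyr::mutate(cluster = labels[match(snapshot_id,
                                         sprintf("snap_%06d", 1:200))]) |>
    dplyr::summarise(m = median(feb_kcal_mol), .by = c(ligand_id, cluster))
  best <- med |> dplyr::slice_min(m, by = ligand_id)
  expect_true(all(best$cluster == 2L))
})

test_that("labels outside 1..n_clusters are rejected", {
  spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.01)
  expect_error(generate_docking_table(spec, labels = c(1L, 4L)),
               class = "rffr_invalid_label")
  expect_error(generate_docking_table(spec, labels = c(0L, 1L)),
               class = "rffr_invalid_label")
})

test_that("default spec plants well-separated clusters at trajectory scale", {
  spec <- synthetic_spec()
  expect_equal(spec$n_snapshots, 20000L)
  expect_equal(spec$n_clusters, 10L)
  expect_equal(length(spec$ligand_ids), 20L)
  expect_equal(spec$runs_per_pair, 25L)
  expect_gte(min_cluster_separation(spec), 10)
  expect_equal(sum(spec$feb_cluster_offset == min(spec$feb_cluster_offset)), 1L)
})
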