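mini_docking <- function(febs, snapshot = "s1", ligand = "L1") {
  tibble::tibble(snapshot_id = snapshot, ligand_id = ligand,
                 run = seq_along(febs), feb_kcal_mol = febs)
}

test_that("runs collapse to the most favourable FEB by default", {
  d <- mini_docking(c(-8.1, -7.9, -8.4))
  expect_equal(snapshot_feb(d)$feb, -8.4)
  expect_equal(attr(snapshot_feb(d), "collapse"), "min")
  expect_equal(snapshot_feb(mini_docking(-7.7))$feb, -7.7)
  expect_equal(snapshot_feb(mini_docking(c(-8, -6)), collapse = "mean")$feb, -7)
})

test_that("docking tables round-trip and validate", {
  spec <- synthetic_spec(n_clusters = 2, duration_ns = 0.005,
                         ligand_ids = c("A", "B"), runs_per_pair = 2)
  d <- generate_docking_table(spec, labels = rep(1L, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  expect_equal(read_docking_table(path), d)
  dup <- dplyr::bind_rows(d, d[1, ])
  expect_error(validate_docking_table(dup), class = "rffr_integrity_error")
})

test_that("per-cluster medians and best clusters are computed per ligand", {
  per_snap <- tibble::tibble(
    snapshot_id = sprintf("s%d", 1:6),
    ligand_id = "L1",
    feb = c(-8, -7, -9, -5, -4, -6)
  )
  labs <- tibble::tibble(snapshot_id = sprintf("s%d", 1:6),
                         cluster = rep(1:2, each = 3))
  s <- cluster_feb_summary(per_snap, labs)
  expect_equal(s$medians$median_feb, c(-8, -5))
  expect_equal(s$best$best_cluster, 1L)
  expect_equal(s$concordance, 1.0)
})

test_that("planted best cluster yields full concordance; split plants halve it", {
  spec <- synthetic_spec(n_clusters = 3, duration_ns = 0.06,
                         ligand_ids = sprintf("L%d", 1:4),
                         feb_cluster_offset = c(0.3, -2, 0.8),
                         feb_noise_sd = 0.2, runs_per_pair = 5, seed = 17)
  tr <- generate_feature_table(spec)
  d <- generate_docking_table(spec, tr$.cluster_true)
  labs <- tibble::tibble(snapshot_id = tr$snapshot_id, cluster = tr$.cluster_true)
  s <- cluster_feb_summary(snapshot_feb(d), labs)
  expect_equal(unique(s$best$best_cluster), 2L)
  expect_equal(s$concordance, 1.0)
  # two ligands planted on different best clusters -> concordance 0.5
  per_snap <- tibble::tibble(
    snapshot_id = rep(sprintf("s%d", 1:4), 2),
    ligand_id = rep(c("A", "B"), each = 4),
    feb = c(-9, -9, -5, -5, -5, -5, -9, -9)
  )
  labs2 <- tibble::tibble(snapshot_id = sprintf("s%d", 1:4),
                          cluster = c(1L, 1L, 2L, 2L))
  s2 <- cluster_feb_summary(per_snap, labs2)
  expect_equal(s2$concordance, 0.5)
})

test_that("docked snapshots missing from the partition are named in the error", {
  per_snap <- tibble::tibble(snapshot_id = c("s1", "ghost"), ligand_id = "L1",
                             feb = c(-8, -7))
  labs <- tibble::tibble(snapshot_id = "s1", cluster = 1L)
  err <- expect_error(cluster_feb_summary(per_snap, labs), class = "rffr_join_error")
  expect_match(conditionMessage(err), "ghost")
})

test_that("medians are invariant under within-cluster row permutation", {
  spec <- synthetic_spec(n_clusters = 2, duration_ns = 0.02,
                         ligand_ids = c("A", "B"), runs_per_pair = 3, seed = 4)
  tr <- generate_feature_table(spec)
  d <- generate_docking_table(spec, tr$.cluster_true)
  labs <- tibble::tibble(snapshot_id = tr$snapshot_id, cluster = tr$.cluster_true)
  per <- snapshot_feb(d)
  withr::with_seed(2, shuffled <- per[sample(nrow(per)), ])
  expect_equal(cluster_feb_summary(shuffled, labs)$medians,
               cluster_feb_summary(per, labs)$medians)
})

test_that("rank consistency detects identical and reversed cluster orderings", {
  medians <- tidyr::expand_grid(ligand_id = c("A", "B", "C"), cluster = 1:4) |>
    dplyr::mutate(feb = -8 + 0.5 * cluster,
                  feb = ifelse(ligand_id == "C", -8 - 0.5 * cluster, feb))
  per_snap <- dplyr::transmute(medians, snapshot_id = sprintf("s%d", cluster),
                               ligand_id, feb)
  labs <- tibble::tibble(snapshot_id = sprintf("s%d", 1:4), cluster = 1:4)
  s <- cluster_feb_summary(per_snap, labs)
  rc <- rank_consistency(s)
  ab <- rc$rho[rc$ligand_a == "A" & rc$ligand_b == "B"]
  expect_equal(ab, 1.0)
  expect_equal(rc$rho[rc$ligand_b == "C" | rc$ligand_a == "C"], c(-1, -1))
})

test_that("rank consistency is near zero under independent random FEBs", {
  mean_rhos <- vapply(1:20, function(rep) {
    spec <- synthetic_spec(
      n_clusters = 10, duration_ns = 0.04, ligand_ids = sprintf("L%02d", 1:20),
      feb_cluster_offset = seq(-0.001, 0.001, length.out = 10), # effectively null
      feb_noise_sd = 1, runs_per_pair = 1, seed = 600 + rep
    )
    tr <- generate_feature_table(spec)
    d <- generate_docking_table(spec, tr$.cluster_true)
    labs <- tibble::tibble(snapshot_id = tr$snapshot_id, cluster = tr$.cluster_true)
    attr(rank_consistency(cluster_feb_summary(snapshot_feb(d), labs)), "mean_rho")
  }, numeric(1))
  expect_lt(abs(mean(mean_rhos)), 0.25)
})
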