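test_that("k-means on nodes honours the ordering convention and k = 1", {
  st <- random_table(70, seed = 2, tasks = default_tasks())
  m <- batch_train(st, som_config(grid_rows = 4, grid_cols = 4))
  one <- kmeans_nodes(m, k = 1, seed = 5)
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(m$weights)))
  expect_true(all(one$node_labels == 1))

  sol <- kmeans_nodes(m, k = 3, seed = 5)
  gm <- rowMeans(sol$centroids)
  expect_true(all(diff(gm) <= 1e-9)) # grand means non-increasing in label
  expect_setequal(unique(sol$node_labels), 1:3)
  expect_error(kmeans_nodes(m, k = 17), "exceeds")

  # determinism
  sol2 <- kmeans_nodes(m, k = 3, seed = 5)
  expect_identical(sol$node_labels, sol2$node_labels)
  expect_identical(sol$centroids, sol2$centroids)
})

test_that("k-means with restarts finds the exhaustive optimum on 6 nodes", {
  for (i in 1:100) {
    set.seed(1500 + i)
    W <- matrix(rnorm(6 * 2), 6)
    colnames(W) <- c("a", "b")
    m <- model_from_weights(W, 2, 3, tasks = c("a", "b"))
    sol <- kmeans_nodes(m, k = 2, n_restarts = 30, seed = i)
    brute <- kmeans_brute(W, 2)
    expect_equal(sol$inertia, brute$ss, tolerance = 1e-9)
    expect_equal(mclust::adjustedRandIndex(sol$node_labels, brute$labels), 1)
  }
})

test_that("four separated blobs cluster with the highest-mean blob as cluster 1", {
  set.seed(9)
  blob <- function(center, n = 16) {
    matrix(rnorm(n * 4, 0, 0.5), n) + matrix(center, n, 4, byrow = TRUE)
  }
  W <- rbind(blob(c(130, 130, 130, 130)), blob(c(105, 105, 105, 105)),
             blob(c(90, 110, 90, 110)), blob(c(70, 70, 70, 70)))
  colnames(W) <- default_tasks()
  m <- model_from_weights(W, 8, 8)
  sol <- kmeans_nodes(m, k = 4, seed = 3)
  expect_equal(sol$node_labels, rep(1:4, each = 16))
})

test_that("participant allocation composes BMU lookup with the node labels", {
  st <- random_table(40, seed = 6, tasks = default_tasks())
  m <- batch_train(st, som_config(grid_rows = 4, grid_cols = 4))
  sol <- kmeans_nodes(m, k = 3, seed = 8)
  alloc <- allocate_to_clusters(m, sol, st)
  for (i in seq_len(40)) {
    bmu <- best_matching_unit(st$scores[i, ], m$weights)
    expect_identical(alloc$bmu[i], bmu)
    expect_identical(alloc$cluster[i], sol$node_labels[bmu])
  }
  # participant sitting exactly on a node gets that node's cluster
  probe <- score_table(m$weights[9, , drop = FALSE], "probe", st$task_names)
  expect_identical(allocate_to_clusters(m, sol, probe)$cluster,
                   sol$node_labels[9])
  # identical participants collapse into a single cluster
  same <- score_table(matrix(100, 7, 4), sprintf("s%d", 1:7), st$task_names)
  expect_length(unique(allocate_to_clusters(m, sol, same)$cluster), 1L)
})

test_that("silhouette diagnostics match hand computation and conventions", {
  # 4-point hand example in 1D: clusters {0, 1} and {10, 12}
  x <- matrix(c(0, 1, 10, 12, 0, 0, 0, 0), 4, 2)
  colnames(x) <- c("a", "b")
  m <- model_from_weights(x, 2, 2, tasks = c("a", "b"))
  d <- as.matrix(dist(x))
  lab <- c(1, 1, 2, 2)
  sil_hand <- vapply(1:4, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(4) != i])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  scan <- silhouette_scan(m, k_range = 2, seed = 4)
  expect_equal(scan$mean_silhouette, mean(sil_hand), tolerance = 1e-9)

  # two tight far-apart blobs: mean silhouette > 0.9
  set.seed(10)
  W <- rbind(matrix(rnorm(16, 0, 0.1), 8), matrix(rnorm(16, 50, 0.1), 8))
  colnames(W) <- c("a", "b")
  m2 <- model_from_weights(W, 4, 4, tasks = c("a", "b"))
  expect_gt(silhouette_scan(m2, k_range = 2, seed = 4)$mean_silhouette, 0.9)

  # all-singleton solution scores 0 by convention; k < 2 is excluded
  expect_equal(silhouette_scan(m, k_range = 4, seed = 1)$mean_silhouette, 0)
  expect_warning(res <- silhouette_scan(m2, k_range = 1:2, seed = 4),
                 "undefined")
  expect_identical(res$k, 2L)
})

test_that("retrain stability is perfect for identical seeds and degrades without structure", {
  sep <- simulate_baseline_cohort(default_baseline_spec(n_participants = 250,
                                                        seed = 14,
                                                        within_sd = 4))
  rep1 <- stability_analysis(sep, som_config(), k = 4, n_reps = 6, seed = 99)
  rep2 <- stability_analysis(sep, som_config(), k = 4, n_reps = 6, seed = 99)
  expect_identical(rep1$pairwise_agreement, rep2$pairwise_agreement)
  expect_true(all(rep1$pairwise_agreement >= -1 &
                    rep1$pairwise_agreement <= 1))
  expect_gt(rep1$mean, 0.8)

  iso <- simulate_baseline_cohort(cohort_spec(250, matrix(100, 1, 4),
                                              diag(225, 4), 1, seed = 15))
  rep_iso <- stability_analysis(iso, som_config(), k = 4, n_reps = 6, seed = 99)
  expect_lt(rep_iso$mean, rep1$mean)

  flat <- score_table(matrix(100, 10, 4), sprintf("f%d", 1:10), default_tasks())
  expect_error(stability_analysis(flat, som_config(), 4, n_reps = 2),
               "degenerate")
})

test_that("profile summaries reproduce whole-table and hand-computed statistics", {
  st <- random_table(30, seed = 19, tasks = default_tasks())
  alloc <- data.frame(participant_id = st$participant_id,
                      bmu = 1L, cluster = 1L)
  s <- profile_summary(alloc, st)
  expect_equal(s$mean, unname(colMeans(st$scores)))
  expect_equal(s$ci_upper - s$ci_lower, 2 * 1.96 * s$se)

  # two-cluster hand fixture
  sc <- matrix(c(10, 20, 30, 40, 1, 2, 3, 4), 4, 2)
  st2 <- score_table(sc, c("w", "x", "y", "z"), c("t1", "t2"))
  alloc2 <- data.frame(participant_id = c("w", "x", "y", "z"),
                       bmu = 1L, cluster = c(1L, 1L, 2L, 2L))
  s2 <- profile_summary(alloc2, st2)
  expect_equal(s2$mean[s2$cluster == 1 & s2$task == "t1"], 15)
  expect_equal(s2$se[s2$cluster == 1 & s2$task == "t1"], sd(c(10, 20)) / sqrt(2))
  expect_equal(s2$mean[s2$cluster == 2 & s2$task == "t2"], 3.5)

  # empty cluster reported with NA statistics and a warning
  alloc3 <- data.frame(participant_id = c("w", "x", "y", "z"),
                       bmu = 1L, cluster = c(1L, 1L, 3L, 3L))
  expect_warning(s3 <- profile_summary(alloc3, st2), "empty")
  expect_true(all(is.na(s3$mean[s3$cluster == 2])))
})
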