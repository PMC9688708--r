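test_that("every method recovers well-separated blobs at the true k", {
  blob <- make_blobs(3, n_per = 10, sep = 12, sd = 0.1, seed = 5)
  for (m in c("kmeans", "kmedoids", "hierarchical", "gmm", "som")) {
    res <- run_method(blob$points, m, k = 3, seed = 2)
    expect_equal(res$n_clusters_found, 3L)
    expect_true(all(res$labels %in% 0:2))
    expect_equal(adjusted_rand_index(res$labels, blob$labels), 1,
                 info = m)
  }
  res <- run_method(blob$points, "dbscan", seed = 2)
  expect_equal(res$n_clusters_found, 3L)
  expect_equal(adjusted_rand_index(res$labels, blob$labels), 1)
})

test_that("results are deterministic for fixed seeds and labels 0-based", {
  blob <- make_blobs(4, n_per = 8, sep = 5, sd = 0.6, seed = 9)
  for (m in c("kmeans", "kmedoids", "hierarchical", "gmm", "som")) {
    a <- run_method(blob$points, m, k = 4, seed = 3)
    b <- run_method(blob$points, m, k = 4, seed = 3)
    expect_identical(a$labels, b$labels, info = m)
    expect_setequal(unique(a$labels), 0:(a$n_clusters_found - 1))
  }
})

test_that("k bounds and degenerate inputs give errors, not crashes", {
  blob <- make_blobs(2, n_per = 5, seed = 1)
  expect_error(run_method(blob$points, "kmeans", k = 10), "k must satisfy")
  expect_error(run_method(blob$points, "kmeans", k = 1), "k must satisfy")
  dup <- matrix(1, nrow = 6, ncol = 2) # one duplicated point
  for (m in c("kmeans", "kmedoids", "hierarchical", "gmm", "som")) {
    expect_error(run_method(dup, m, k = 2), "distinct", info = m)
  }
  expect_error(run_method(blob$points, "bogus", k = 2))
})

test_that("restarted k-means never does worse than a single start", {
  blob <- make_blobs(4, n_per = 10, sep = 3, sd = 1.2, seed = 13)
  single <- withr::with_seed(1, kmeans(blob$points, 4, nstart = 1))
  multi <- withr::with_seed(1, kmeans(blob$points, 4, nstart = 50))
  expect_lte(multi$tot.withinss, single$tot.withinss)
})

test_that("dbscan labels a far point as noise and counts clusters without it", {
  blob <- make_blobs(2, n_per = 6, sep = 8, sd = 0.2, seed = 7)
  pts <- rbind(blob$points, c(200, 200))
  res <- dbscan_sweep(pts, min_pts = 3)
  expect_equal(res$labels[nrow(pts)], -1L)
  expect_equal(res$n_clusters_found, 2L)
  # ... while k-means at k = 3 must give the outlier its own cluster
  km <- run_method(pts, "kmeans", k = 3, seed = 1)
  expect_equal(sum(km$labels == km$labels[nrow(pts)]), 1L)
})

test_that("an epsilon above the data diameter leaves one skippable cluster", {
  blob <- make_blobs(2, n_per = 5, sep = 4, sd = 0.3, seed = 3)
  runs <- run_method(blob$points, "dbscan", seed = 1,
                     params = list(eps = 1e6))
  expect_equal(runs$n_clusters_found, 1L)
  # the sweep skips such runs and still lands on the 2-cluster solution
  swept <- dbscan_sweep(blob$points, min_pts = 3)
  expect_equal(swept$n_clusters_found, 2L)
  expect_equal(adjusted_rand_index(swept$labels, blob$labels), 1)
  expect_error(dbscan_sweep(blob$points, eps_grid = c(1e6)),
               "widen eps_grid")
})

test_that("adjusted Rand index matches its closed form and conventions", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(7, 7, 3, 3)), 1)
  # any permutation of labels is still identity agreement
  labs <- withr::with_seed(2, sample(1:3, 12, replace = TRUE))
  perm <- c(2, 3, 1)[labs]
  expect_equal(adjusted_rand_index(labs, perm), 1)
  # one-cluster partition against multi-group truth scores 0
  expect_equal(adjusted_rand_index(rep(1, 9), rep(1:3, 3)), 0)
  # random partitions agree with the contingency-table formula
  for (seed in 1:20) {
    ab <- withr::with_seed(seed, list(a = sample(1:3, 15, replace = TRUE),
                                      b = sample(1:4, 15, replace = TRUE)))
    expect_equal(adjusted_rand_index(ab$a, ab$b), naive_ari(ab$a, ab$b),
                 tolerance = 1e-12)
  }
  # noise exclusion is pairwise
  expect_equal(adjusted_rand_index(c(-1, 0, 0, 1, 1),
                                   c(5, 5, 5, 6, -1)), 1)
  expect_error(adjusted_rand_index(c(-1, -1, 1), c(1, 1, -1)), "fewer than 2")
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("downstream indices ignore the labeling permutation", {
  blob <- make_blobs(3, n_per = 7, sep = 6, sd = 0.5, seed = 17)
  res <- run_method(blob$points, "kmeans", k = 3, seed = 1)
  perm <- c(2L, 0L, 1L)[res$labels + 1L]
  expect_equal(silhouette_mean(blob$points, res$labels),
               silhouette_mean(blob$points, perm))
  expect_equal(calinski_harabasz(blob$points, res$labels),
               calinski_harabasz(blob$points, perm))
  expect_equal(davies_bouldin(blob$points, res$labels),
               davies_bouldin(blob$points, perm))
})
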