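two_pair <- list(points = c(0, 1, 10, 11), labels = c("A", "A", "B", "B"))

test_that("indices agree with hand computation on the two-pair instance", {
  s <- silhouette_samples(two_pair$points, two_pair$labels)
  expect_equal(s, c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(silhouette_mean(two_pair$points, two_pair$labels),
               (9.5 / 10.5 + 8.5 / 9.5) / 2)
  expect_equal(calinski_harabasz(two_pair$points, two_pair$labels), 200)
  expect_equal(davies_bouldin(two_pair$points, two_pair$labels), 0.1)
})

test_that("silhouette conventions: singletons, duplicates, bounds", {
  # singleton cluster member scores 0
  s <- silhouette_samples(c(0, 1, 50), c("A", "A", "B"))
  expect_equal(s[3], 0)
  # duplicated points alone in their clusters: a = 0 so s = 1
  s2 <- silhouette_samples(c(0, 0, 9, 9), c("A", "A", "B", "B"))
  expect_equal(s2, rep(1, 4))
  expect_error(silhouette_samples(1:4, rep("A", 4)), "k=1")
  # mean within per-sample bounds, all within [-1, 1]
  inst <- random_instance(99)
  sam <- silhouette_samples(inst$points, inst$labels)
  expect_true(all(sam >= -1 & sam <= 1))
  m <- silhouette_mean(inst$points, inst$labels)
  expect_gte(m, min(sam)); expect_lte(m, max(sam))
})

test_that("indices match cluster::silhouette and brute force on random data", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    mine <- silhouette_samples(inst$points, inst$labels)
    expect_equal(mine, naive_silhouette(inst$points, inst$labels),
                 tolerance = 1e-9)
    ref <- cluster::silhouette(as.integer(factor(inst$labels)),
                               dist(inst$points))
    expect_equal(mine, unname(ref[, "sil_width"]), tolerance = 1e-9)
    expect_equal(calinski_harabasz(inst$points, inst$labels),
                 naive_ch(inst$points, inst$labels), tolerance = 1e-9)
    expect_equal(davies_bouldin(inst$points, inst$labels),
                 naive_db(inst$points, inst$labels), tolerance = 1e-9)
  }
})

test_that("indices are invariant to relabeling, reordering and isometries", {
  inst <- random_instance(7)
  pts <- inst$points; labs <- inst$labels
  base <- c(silhouette_mean(pts, labs), calinski_harabasz(pts, labs),
            davies_bouldin(pts, labs))
  # relabeling
  relab <- c(10, 20, 30, 40)[labs]
  expect_equal(c(silhouette_mean(pts, relab),
                 calinski_harabasz(pts, relab),
                 davies_bouldin(pts, relab)), base)
  # reordering points
  ord <- withr::with_seed(1, sample(nrow(pts)))
  expect_equal(silhouette_mean(pts[ord, , drop = FALSE], labs[ord]),
               base[1])
  # translation
  shifted <- pts + 100
  expect_equal(c(silhouette_mean(shifted, labs),
                 calinski_harabasz(shifted, labs),
                 davies_bouldin(shifted, labs)), base)
  # rotation (orthogonal map)
  if (ncol(pts) >= 2) {
    q <- qr.Q(qr(withr::with_seed(2, matrix(rnorm(ncol(pts)^2), ncol(pts)))))
    rot <- pts %*% q
    expect_equal(c(silhouette_mean(rot, labs),
                   calinski_harabasz(rot, labs),
                   davies_bouldin(rot, labs)), base)
  }
  # uniform positive scaling
  expect_equal(c(silhouette_mean(pts * 3.7, labs),
                 calinski_harabasz(pts * 3.7, labs),
                 davies_bouldin(pts * 3.7, labs)), base)
})

test_that("perfect separation triggers the CH sentinel", {
  pts <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(calinski_harabasz(pts, c(1, 1, 2, 2)), Inf)
  expect_error(davies_bouldin(pts, c(1, 2, 1, 2)), "coincident")
  # one point per cluster: zero spreads, DB = 0
  expect_equal(davies_bouldin(matrix(c(0, 5, 9)), c(1, 2, 3)), 0)
})

test_that("tightening clusters never worsens Davies-Bouldin", {
  blob <- make_blobs(3, n_per = 8, sep = 6, sd = 0.5, seed = 11)
  centers <- do.call(rbind, lapply(1:3, function(g)
    colMeans(blob$points[blob$labels == g, ])))
  prev <- Inf
  for (shrink in c(1, 0.5, 0.25, 0.1)) {
    pts <- centers[blob$labels, ] + shrink *
      (blob$points - centers[blob$labels, ])
    cur <- davies_bouldin(pts, blob$labels)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("optimal_k finds planted blob counts and breaks ties downward", {
  for (k_true in 2:3) {
    blob <- make_blobs(k_true, n_per = 10, sep = 10, sd = 0.1, seed = k_true)
    for (crit in c("silhouette", "calinski_harabasz", "davies_bouldin")) {
      expect_equal(optimal_k(blob$points, "kmeans", crit, k_range = 2:9,
                             seed = 1), k_true)
    }
  }
})

test_that("consensus k takes the majority and silhouette on splits", {
  expect_equal(consensus_k(c(silhouette = 3, calinski_harabasz = 7,
                             davies_bouldin = 3)), 3L)
  expect_equal(consensus_k(c(silhouette = 5, calinski_harabasz = 5,
                             davies_bouldin = 9)), 5L)
  expect_equal(consensus_k(c(silhouette = 2, calinski_harabasz = 3,
                             davies_bouldin = 4)), 2L)
  expect_error(consensus_k(c(silhouette = 2, calinski_harabasz = 3)),
               "named exactly")
})

test_that("fraction_above counts strict exceedances", {
  expect_equal(fraction_above(c(0.7, 0.5, 0.9, 0.61)), 0.75)
  expect_equal(fraction_above(c(0.1, 0.2)), 0)
  expect_equal(fraction_above(c(0.1, 0.2), threshold = -1), 1)
  expect_equal(fraction_above(c(0.6, 0.7)), 0.5) # 0.6 itself not counted
  expect_error(fraction_above(numeric(0)), "non-empty")
})

test_that("validity_report assembles votes, consensus and silhouettes", {
  blob <- make_blobs(3, n_per = 8, sep = 10, sd = 0.15, seed = 21)
  vr <- validity_report(blob$points, "kmeans", k_range = 2:6, seed = 1)
  expect_equal(vr$consensus_k, 3L)
  expect_equal(sort(unique(vr$per_k$k)), 2:6)
  expect_true(all(vr$per_k$silhouette >= -1 & vr$per_k$silhouette <= 1))
  expect_true(all(vr$per_k$calinski_harabasz >= 0))
  expect_true(all(vr$per_k$davies_bouldin >= 0))
  expect_length(vr$per_sample_silhouette, nrow(blob$points))
  expect_equal(vr$fraction_above,
               mean(vr$per_sample_silhouette > 0.6))
  expect_equal(adjusted_rand_index(vr$consensus_result$labels,
                                   blob$labels), 1)
})
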