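clustering_method_names <- function() {
  c("kmeans", "kmedoids", "hierarchical", "gmm", "som", "dbscan")
}

# relabel to 0..m-1 in order of first appearance; -1 (noise) preserved
.normalize_labels <- function(raw) {
  noise <- raw == -1
  u <- unique(raw[!noise])
  out <- rep(-1L, length(raw))
  out[!noise] <- match(raw[!noise], u) - 1L
  out
}

new_clustering_result <- function(method, k_requested, labels, seed,
                                  method_params = list()) {
  labels <- .normalize_labels(as.integer(labels))
  structure(
    list(method = method, k_requested = k_requested, labels = labels,
         seed = seed, method_params = method_params,
         n_clusters_found = length(unique(labels[labels >= 0]))),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s: %d cluster(s)%s over %d points\n",
              x$method, x$n_clusters_found,
              if (any(x$labels == -1))
                sprintf(" + %d noise", sum(x$labels == -1)) else "",
              length(x$labels)))
  invisible(x)
}

#' Run one clustering method under the uniform hard-label contract
#'
#' Dispatches to one of six methods and returns hard labels `0..m-1`
#' (DBSCAN may additionally emit `-1` for noise; every other method labels
#' every point). All methods are deterministic for a fixed
#' `(points, method, k, seed, params)`.
#'
#' Methods: `kmeans` (Lloyd with k-means++-style greedy seeding via
#' seeded multiple restarts, best objective kept), `kmedoids` (PAM
#' build+swap on Euclidean distances), `hierarchical` (Ward linkage by
#' default, dendrogram cut at `k`), `gmm` (Gaussian mixture fitted by EM,
#' hard labels by maximum responsibility; full covariances with fallback to
#' simpler covariance structures if degenerate), `som` (self-organizing map
#' with a 1-by-`k` output grid, each unit one cluster, points assigned to
#' their best-matching unit), `dbscan` (density-based; `k` is ignored and
#' an epsilon sweep is used unless `params$eps` is given).
#'
#' @param points numeric matrix of observations (e.g. PCA scores).
#' @param method one of `"kmeans"`, `"kmedoids"`, `"hierarchical"`,
#'   `"gmm"`, `"som"`, `"dbscan"`.
#' @param k requested number of clusters, `2 <= k <= n-1` (ignored by
#'   DBSCAN).
#' @param seed integer seed.
#' @param params method-specific parameters: `nstart` (kmeans, default 50),
#'   `linkage` (hierarchical, default `"ward.D2"`), `epochs` (som),
#'   `eps`/`min_pts`/`eps_grid` (dbscan).
#' @return a `clustering_result`.
#' @examples
#' pts <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
#' run_method(pts, "kmeans", k = 2, seed = 1)$n_clusters_found
#' @export
run_method <- function(points, method = clustering_method_names(),
                       k = NULL, seed = 1, params = list()) {
  method <- match.arg(method)
  points <- as_point_matrix(points)
  n <- nrow(points)
  if (method != "dbscan") {
    if (is.null(k)) stopf("method %s requires k", method)
    k <- as.integer(k)
    if (k < 2 || k > n - 1)
      stopf("k must satisfy 2 <= k <= n-1 (got k=%d, n=%d)", k, n)
    n_distinct <- nrow(unique(points))
    if (n_distinct < k)
      stopf("k=%d exceeds the %d distinct points", k, n_distinct)
  }
  labels <- switch(
    method,
    kmeans = {
      nstart <- params$nstart %||% 50
      fit <- withr::with_seed(as.integer(seed),
        kmeans(points, centers = k, nstart = nstart, iter.max = 100))
      fit$cluster - 1L
    },
    kmedoids = {
      fit <- cluster::pam(points, k = k, metric = "euclidean",
                          keep.diss = FALSE, keep.data = FALSE)
      fit$clustering - 1L
    },
    hierarchical = {
      linkage <- params$linkage %||% "ward.D2"
      cutree(hclust(dist(points), method = linkage), k = k) - 1L
    },
    gmm = {
      models <- params$model %||%
        if (ncol(points) == 1) c("V", "E") else c("VVV", "VVI", "VII", "EII")
      fit <- NULL
      for (m in models) {
        fit <- withr::with_seed(as.integer(seed), suppressWarnings(
          tryCatch(Mclust(points, G = k, modelNames = m, verbose = FALSE),
                   error = function(e) NULL)))
        if (!is.null(fit) && !any(is.na(fit$classification))) break
        fit <- NULL
      }
      if (is.null(fit))
        stopf("GMM covariance degenerate at k=%d for all model structures", k)
      fit$classification - 1L
    },
    som = som_cluster(points, k, seed = seed,
                      epochs = params$epochs %||% 50),
    dbscan = {
      if (!is.null(params$eps)) {
        .dbscan_labels(points, eps = params$eps,
                       min_pts = params$min_pts %||% 3)
      } else {
        return(dbscan_sweep(points, min_pts = params$min_pts %||% 3,
                            eps_grid = params$eps_grid, seed = seed))
      }
    })
  new_clustering_result(method, if (method == "dbscan") NULL else k,
                        labels, seed, params)
}

# 1 x k self-organizing map used as a clustering: each map unit is one
# cluster. Codebook initialized on first-principal-component order, online
# training with Gaussian neighborhood and learning rate both decaying over
# epochs (neighborhood radius shrinking toward 0 makes the final sweeps
# plain competitive learning), then every point is assigned to its
# best-matching unit.
som_cluster <- function(points, k, seed = 1, epochs = 50,
                        lr0 = 0.5, lr1 = 0.01) {
  n <- nrow(points)
  pc1 <- prcomp(points, center = TRUE, scale. = FALSE)$x[, 1]
  ord <- order(pc1)
  chunk <- split(ord, cut(seq_len(n), breaks = k, labels = FALSE))
  codebook <- t(vapply(chunk, function(ix)
    colMeans(points[ix, , drop = FALSE]), numeric(ncol(points))))
  sigma0 <- max(k / 2, 0.5); sigma1 <- 0.05
  withr::with_seed(as.integer(seed), {
    for (e in seq_len(epochs)) {
      frac <- (e - 1) / max(epochs - 1, 1)
      sigma <- sigma0 * (sigma1 / sigma0)^frac
      lr <- lr0 * (lr1 / lr0)^frac
      for (i in sample(n)) {
        x <- points[i, ]
        d2 <- rowSums(sweep(codebook, 2, x)^2)
        bmu <- which.min(d2)
        h <- exp(-((seq_len(k) - bmu)^2) / (2 * sigma^2))
        codebook <- codebook + lr * h * sweep(-codebook, 2, x, `+`)
      }
    }
  })
  d <- as.matrix(dist(rbind(codebook, points)))[seq_len(k), -seq_len(k),
                                                drop = FALSE]
  apply(d, 2, which.min) - 1L
}

# classic DBSCAN by BFS region growing; a point is core if at least
# min_pts points (itself included) lie within eps.
.dbscan_labels <- function(points, eps, min_pts = 3) {
  n <- nrow(points)
  dmat <- as.matrix(dist(points))
  neighbors <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (nb in neighbors[[j]]) {
        if (is.na(labels[nb]) || labels[nb] == -1L) {
          newly <- is.na(labels[nb])
          labels[nb] <- cl
          if (newly && core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

dbscan_all_runs <- function(points, min_pts = 3, eps_grid = NULL) {
  points <- as_point_matrix(points)
  if (is.null(eps_grid)) {
    dd <- as.vector(dist(points))
    dd <- dd[dd > 0]
    if (!length(dd)) stopf("all points coincide; DBSCAN grid undefined")
    eps_grid <- unique(quantile(dd, probs = seq(0.05, 1, length.out = 20),
                                names = FALSE))
  }
  if (!length(eps_grid) || is.unsorted(eps_grid))
    stopf("eps_grid must be non-empty and ascending")
  lapply(eps_grid, function(eps)
    new_clustering_result("dbscan", NULL,
                          .dbscan_labels(points, eps, min_pts),
                          seed = NA,
                          method_params = list(eps = eps,
                                               min_pts = min_pts)))
}

#' DBSCAN over an epsilon grid
#'
#' Runs DBSCAN at every epsilon of the grid (default: 20 quantiles of the
#' positive pairwise-distance distribution), scores each run by the mean
#' silhouette of its non-noise points, skips runs with fewer than two
#' clusters among non-noise points, and returns the best run. Noise points
#' keep label `-1` and are excluded from `n_clusters_found`.
#'
#' @param points numeric matrix of observations.
#' @param min_pts minimum neighborhood size for a core point (default 3,
#'   suited to small cohorts).
#' @param eps_grid ascending numeric vector of neighborhood radii, or
#'   `NULL` for the quantile default.
#' @param seed recorded in the result (the sweep itself is deterministic).
#' @return a `clustering_result` with `method_params$eps` set to the chosen
#'   radius and a `sweep` attribute tabulating every scored run.
#' @export
dbscan_sweep <- function(points, min_pts = 3, eps_grid = NULL, seed = 1) {
  points <- as_point_matrix(points)
  runs <- dbscan_all_runs(points, min_pts = min_pts, eps_grid = eps_grid)
  scores <- vapply(runs, function(r) {
    keep <- r$labels >= 0
    if (r$n_clusters_found < 2 || sum(keep) < 3) return(NA_real_)
    mean(.silhouette_from_dmat(
      as.matrix(dist(points[keep, , drop = FALSE])), r$labels[keep]))
  }, numeric(1))
  if (all(is.na(scores)))
    stopf(paste("no epsilon yielded >= 2 clusters;",
                "widen eps_grid or lower min_pts"))
  best <- runs[[which.max(scores)]]
  best$seed <- seed
  attr(best, "sweep") <- data.frame(
    eps = vapply(runs, function(r) r$method_params$eps, numeric(1)),
    n_clusters = vapply(runs, `[[`, integer(1), "n_clusters_found"),
    n_noise = vapply(runs, function(r) sum(r$labels == -1L), integer(1)),
    silhouette = scores)
  best
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two hard partitions; 1 iff they are
#' identical up to relabeling. Positions where either labeling marks noise
#' (`-1`) are excluded pairwise before comparison.
#'
#' @param labels_a,labels_b equal-length label vectors; `-1` marks noise.
#' @return scalar `<= 1`.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(5, 5, 9, 9))
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors must have equal length")
  keep <- labels_a != -1 & labels_b != -1 &
    !is.na(labels_a) & !is.na(labels_b)
  if (sum(keep) < 2)
    stopf("fewer than 2 points retained after noise exclusion")
  adjustedRandIndex(labels_a[keep], labels_b[keep])
}
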