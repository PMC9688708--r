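check_labels <- function(points, labels) {
  if (nrow(points) != length(labels))
    stopf("labels must match the number of points")
  if (any(is.na(labels))) stopf("labels must not contain NA")
  labels
}

.silhouette_from_dmat <- function(dmat, labels) {
  labs <- unique(labels)
  if (length(labs) < 2) stopf("silhouette undefined for k=1")
  n <- length(labels)
  idx <- lapply(labs, function(l) which(labels == l))
  names(idx) <- as.character(labs)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- idx[[as.character(labels[i])]]
    if (length(own) == 1L) { s[i] <- 0; next }  # singleton convention
    a <- sum(dmat[i, own]) / (length(own) - 1L)
    b <- min(vapply(labs[labs != labels[i]], function(l)
      mean(dmat[i, idx[[as.character(l)]]]), numeric(1)))
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  s
}

#' Per-sample silhouette values
#'
#' Rousseeuw's silhouette with Euclidean distances: for each point,
#' `s = (b - a) / max(a, b)` where `a` is the mean distance to the other
#' members of its own cluster and `b` the smallest mean distance to any
#' other cluster. Members of singleton clusters get `s = 0` by convention.
#'
#' @param points numeric matrix (rows = observations) or vector.
#' @param labels hard cluster assignment, one label per point; at least two
#'   distinct clusters.
#' @return numeric vector of values in `[-1, 1]`.
#' @examples
#' silhouette_samples(c(0, 1, 10, 11), c("A", "A", "B", "B"))
#' @export
silhouette_samples <- function(points, labels) {
  points <- as_point_matrix(points)
  labels <- check_labels(points, labels)
  .silhouette_from_dmat(as.matrix(dist(points)), labels)
}

#' Mean silhouette of a partition
#'
#' @inheritParams silhouette_samples
#' @return scalar in `[-1, 1]`; higher indicates better-separated clusters.
#' @export
silhouette_mean <- function(points, labels) {
  mean(silhouette_samples(points, labels))
}

#' Calinski-Harabasz index
#'
#' Between- to within-cluster dispersion ratio scaled by degrees of
#' freedom: `(B / (k - 1)) / (W / (n - k))`. Higher is better. If the
#' within-cluster dispersion is exactly zero (every cluster collapsed onto
#' its centroid) the index is reported as `Inf`, a "perfect separation"
#' sentinel.
#'
#' @inheritParams silhouette_samples
#' @return non-negative scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as_point_matrix(points)
  labels <- check_labels(points, labels)
  labs <- unique(labels)
  k <- length(labs)
  n <- nrow(points)
  if (k < 2) stopf("Calinski-Harabasz requires >= 2 clusters")
  if (k >= n) stopf("Calinski-Harabasz requires k < n")
  grand <- colMeans(points)
  B <- 0; W <- 0
  for (l in labs) {
    sub <- points[labels == l, , drop = FALSE]
    cen <- colMeans(sub)
    B <- B + nrow(sub) * sum((cen - grand)^2)
    W <- W + sum(sweep(sub, 2, cen)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' Average, over clusters, of the worst-case ratio of summed within-cluster
#' spreads to centroid separation:
#' `(1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij`, with `S` the mean
#' distance of a cluster's points to its centroid and `M` the distance
#' between centroids. Lower is better.
#'
#' @inheritParams silhouette_samples
#' @return non-negative scalar.
#' @export
davies_bouldin <- function(points, labels) {
  points <- as_point_matrix(points)
  labels <- check_labels(points, labels)
  labs <- unique(labels)
  k <- length(labs)
  if (k < 2) stopf("Davies-Bouldin requires >= 2 clusters")
  cen <- do.call(rbind, lapply(labs, function(l)
    colMeans(points[labels == l, , drop = FALSE])))
  S <- vapply(seq_along(labs), function(i) {
    sub <- points[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(sub, 2, cen[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(cen))
  off <- M[upper.tri(M)]
  if (any(off < 1e-12)) stopf("Davies-Bouldin undefined for coincident centroids")
  mean(vapply(seq_len(k), function(i)
    max(((S[i] + S[-i]) / M[i, -i])), numeric(1)))
}

validity_criteria <- function() {
  c("silhouette", "calinski_harabasz", "davies_bouldin")
}

criterion_value <- function(points, labels, criterion, dmat = NULL) {
  switch(criterion,
         silhouette = if (is.null(dmat)) silhouette_mean(points, labels)
                      else mean(.silhouette_from_dmat(dmat, labels)),
         calinski_harabasz = calinski_harabasz(points, labels),
         davies_bouldin = davies_bouldin(points, labels),
         stopf("unknown criterion '%s'", criterion))
}

#' Optimal number of clusters under one criterion
#'
#' Runs a clustering method at every `k` in the range and returns the `k`
#' optimizing the criterion (maximum for silhouette and Calinski-Harabasz,
#' minimum for Davies-Bouldin). Ties break toward smaller `k` (parsimony).
#' A `k` at which the method fails is skipped with a warning.
#'
#' @param points numeric matrix of observations (e.g. PCA scores).
#' @param method one of the six methods of [run_method()].
#' @param criterion `"silhouette"`, `"calinski_harabasz"` or
#'   `"davies_bouldin"`.
#' @param k_range integer vector of candidate cluster numbers (default
#'   2..9).
#' @param seed integer seed making the sweep deterministic.
#' @param params method parameters, passed to [run_method()].
#' @return the optimal `k` (integer).
#' @export
optimal_k <- function(points, method = "kmeans",
                      criterion = validity_criteria(),
                      k_range = 2:9, seed = 1, params = list()) {
  criterion <- match.arg(criterion)
  points <- as_point_matrix(points)
  if (nrow(points) <= max(k_range))
    stopf("need more points than max(k_range)")
  vals <- vapply(k_range, function(k) {
    tryCatch({
      res <- run_method(points, method, k = k, seed = seed, params = params)
      keep <- res$labels >= 0
      criterion_value(points[keep, , drop = FALSE], res$labels[keep],
                      criterion)
    }, error = function(e) {
      warnf("method %s failed at k=%d: %s", method, k, conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  if (all(is.na(vals))) stopf("method %s failed at every k", method)
  if (criterion == "davies_bouldin") vals <- -vals
  as.integer(k_range[which.max(vals)])  # first max: ties go to smaller k
}

#' Majority-vote consensus on the number of clusters
#'
#' Takes the per-criterion optimal `k` votes of the three validity criteria
#' and returns the majority value; when all three disagree the silhouette
#' criterion's vote wins (the combination search that precedes this step is
#' itself silhouette-driven).
#'
#' @param votes named numeric/integer vector with exactly the three
#'   elements `silhouette`, `calinski_harabasz`, `davies_bouldin`.
#' @return consensus `k` (integer).
#' @examples
#' consensus_k(c(silhouette = 3, calinski_harabasz = 7, davies_bouldin = 3))
#' @export
consensus_k <- function(votes) {
  need <- validity_criteria()
  if (length(votes) != 3L || !setequal(names(votes), need))
    stopf("votes must be named exactly: %s", paste(need, collapse = ", "))
  votes <- votes[need]
  tab <- table(votes)
  if (max(tab) >= 2) return(as.integer(names(tab)[which.max(tab)]))
  as.integer(votes[["silhouette"]])
}

#' Fraction of values strictly above a threshold
#'
#' Used to report the share of subjects with a per-sample silhouette above
#' 0.6, the conventional cutoff for a well-separated assignment.
#'
#' @param values non-empty numeric vector.
#' @param threshold scalar; default 0.6.
#' @return fraction in `[0, 1]`.
#' @export
fraction_above <- function(values, threshold = 0.6) {
  if (!length(values)) stopf("values must be non-empty")
  mean(values > threshold)
}

#' Validity report for one method over a k range
#'
#' Runs one clustering method across the candidate `k` range, evaluates all
#' three validity criteria at each `k`, extracts each criterion's optimal
#' `k` and their majority-vote consensus, and reports the per-subject
#' silhouettes of the consensus partition. DBSCAN, which has no `k`
#' parameter, is swept over an epsilon grid instead and its runs are
#' indexed by the realized number of clusters (noise points are excluded
#' from index computation). The distance metric (Euclidean) and the
#' singleton-silhouette convention (0) are recorded in the report.
#'
#' @inheritParams optimal_k
#' @param silhouette_threshold cutoff used for the reported fraction of
#'   well-separated subjects.
#' @return an object of class `validity_report`: `method`, `per_k` (data
#'   frame with k, the three indices, n_clusters), `optimal_k_per_criterion`,
#'   `consensus_k`, `consensus_result` (a `clustering_result`),
#'   `per_sample_silhouette` (NA for noise points), `fraction_above`.
#' @export
validity_report <- function(points, method = "kmeans", k_range = 2:9,
                            seed = 1, params = list(),
                            silhouette_threshold = 0.6) {
  points <- as_point_matrix(points)
  runs <- if (identical(method, "dbscan")) {
    sweep_runs <- dbscan_all_runs(points,
                                  min_pts = params$min_pts %||% 3,
                                  eps_grid = params$eps_grid)
    # per realized cluster count keep the best-silhouette run
    ks <- vapply(sweep_runs, `[[`, integer(1), "n_clusters_found")
    keep <- ks %in% k_range
    sweep_runs <- sweep_runs[keep]; ks <- ks[keep]
    lapply(sort(unique(ks)), function(k) {
      cand <- sweep_runs[ks == k]
      sil <- vapply(cand, function(r) {
        m <- r$labels >= 0
        mean(.silhouette_from_dmat(as.matrix(dist(points[m, , drop = FALSE])),
                                   r$labels[m]))
      }, numeric(1))
      cand[[which.max(sil)]]
    })
  } else {
    out <- list()
    for (k in k_range) {
      res <- tryCatch(
        run_method(points, method, k = k, seed = seed, params = params),
        error = function(e) {
          warnf("method %s failed at k=%d: %s", method, k,
                conditionMessage(e))
          NULL
        })
      if (!is.null(res)) out <- c(out, list(res))
    }
    out
  }
  if (!length(runs))
    stopf("method %s produced no valid clusterings over the k range", method)
  per_k <- do.call(rbind, lapply(runs, function(res) {
    keep <- res$labels >= 0
    pts <- points[keep, , drop = FALSE]
    labs <- res$labels[keep]
    val <- function(crit) tryCatch(criterion_value(pts, labs, crit),
                                   error = function(e) NA_real_)
    data.frame(k = res$n_clusters_found,
               silhouette = val("silhouette"),
               calinski_harabasz = val("calinski_harabasz"),
               davies_bouldin = val("davies_bouldin"),
               n_noise = sum(!keep))
  }))
  pick <- function(crit) {
    v <- per_k[[crit]]
    if (crit == "davies_bouldin") v <- -v
    v[is.na(v)] <- -Inf
    per_k$k[which.max(v)]
  }
  votes <- c(silhouette = pick("silhouette"),
             calinski_harabasz = pick("calinski_harabasz"),
             davies_bouldin = pick("davies_bouldin"))
  ck <- consensus_k(votes)
  consensus_result <- runs[[which(per_k$k == ck)[1]]]
  keep <- consensus_result$labels >= 0
  sil <- rep(NA_real_, nrow(points))
  sil[keep] <- silhouette_samples(points[keep, , drop = FALSE],
                                  consensus_result$labels[keep])
  structure(
    list(method = method, per_k = per_k,
         optimal_k_per_criterion = votes, consensus_k = ck,
         consensus_result = consensus_result,
         per_sample_silhouette = sil,
         fraction_above = fraction_above(sil[keep], silhouette_threshold),
         silhouette_threshold = silhouette_threshold,
         metric = "euclidean", singleton_silhouette = 0),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %s: consensus k = %d (votes: %s)\n",
              x$method, x$consensus_k,
              paste(sprintf("%s=%d", names(x$optimal_k_per_criterion),
                            x$optimal_k_per_criterion), collapse = ", ")))
  cat(sprintf("  mean silhouette at consensus: %.3f; fraction > %.2g: %.2f\n",
              mean(x$per_sample_silhouette, na.rm = TRUE),
              x$silhouette_threshold, x$fraction_above))
  invisible(x)
}
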