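# Independent brute-force implementations of the validity indices, written
# as literal double loops over the definitions; used only as test oracles.

naive_silhouette <- function(points, labels) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 1)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  vapply(seq_len(n), function(i) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) return(0)
    a <- mean(vapply(same, d, numeric(1), i = i))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      others <- which(labels == l)
      b <- min(b, mean(vapply(others, d, numeric(1), i = i)))
    }
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

naive_ch <- function(points, labels) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 1)
  n <- nrow(points)
  labs <- unique(labels)
  k <- length(labs)
  grand <- colMeans(points)
  B <- 0; W <- 0
  for (l in labs) {
    sub <- points[labels == l, , drop = FALSE]
    cen <- colMeans(sub)
    B <- B + nrow(sub) * sum((cen - grand)^2)
    for (i in seq_len(nrow(sub))) W <- W + sum((sub[i, ] - cen)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

naive_db <- function(points, labels) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 1)
  labs <- unique(labels)
  k <- length(labs)
  cen <- list(); S <- numeric(k)
  for (i in seq_len(k)) {
    sub <- points[labels == labs[i], , drop = FALSE]
    cen[[i]] <- colMeans(sub)
    S[i] <- mean(vapply(seq_len(nrow(sub)), function(r)
      sqrt(sum((sub[r, ] - cen[[i]])^2)), numeric(1)))
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      M <- sqrt(sum((cen[[i]] - cen[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    total <- total + worst
  }
  total / k
}

naive_ari <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maximum <- (si + sj) / 2
  if (maximum == expected) return(1)
  (sij - expected) / (maximum - expected)
}

# random labeled instance with every cluster realized
random_instance <- function(seed, n_max = 25, d_max = 4, k_max = 4) {
  withr::with_seed(seed, {
    n <- sample(5:n_max, 1)
    d <- sample(1:d_max, 1)
    k <- sample(2:min(k_max, n - 1), 1)
    list(points = matrix(rnorm(n * d), n, d),
         labels = sample(rep(seq_len(k), length.out = n)))
  })
}

# k tight Gaussian blobs with well-separated centers on a diagonal grid
make_blobs <- function(k, n_per = 10, d = 2, sep = 10, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(k), function(g)
      matrix(rnorm(n_per * d, mean = g * sep, sd = sd), n_per, d)))
    list(points = pts, labels = rep(seq_len(k), each = n_per))
  })
}

informative_combo <- c("HHb-PFC", "O2Hb-VC", "PETCO2", "SC", "SpO2")
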