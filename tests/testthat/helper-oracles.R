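# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive algorithms, not the package's code paths.

# Floyd-Warshall global efficiency: edge length 1/w, disconnected pairs
# contribute zero.
oracle_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (n * (n - 1))
}

# Onnela weighted clustering by explicit triplet enumeration.
oracle_clustering <- function(w) {
  n <- nrow(w)
  mw <- max(w)
  if (mw == 0) return(0)
  wh <- w / mw
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k) {
        j <- nb[a]; l <- nb[b]
        tri <- tri + (wh[i, j] * wh[i, l] * wh[j, l])^(1 / 3)
      }
    ci[i] <- tri / (k * (k - 1) / 2)
  }
  mean(ci)
}

# All set partitions of 1..n as membership vectors (restricted growth).
set_partitions <- function(n) {
  res <- list()
  rec <- function(assign, maxl) {
    i <- length(assign) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- assign
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(assign, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  res
}

# Weighted Newman modularity of a given membership vector.
partition_q <- function(w, membership) {
  m2 <- sum(w)
  k <- rowSums(w)
  B <- w - outer(k, k) / m2
  same <- outer(membership, membership, `==`)
  sum(B[same]) / m2
}

# Exhaustive-search maximum modularity (n <= 8).
oracle_max_modularity <- function(w) {
  parts <- set_partitions(nrow(w))
  max(vapply(parts, function(p) partition_q(w, p), numeric(1)))
}

# Per-edge two-sample pooled-variance t (group1 - group2), formula level.
oracle_two_sample_t <- function(y1, y2) {
  n1 <- nrow(y1); n2 <- nrow(y2)
  m1 <- colMeans(y1); m2 <- colMeans(y2)
  v1 <- apply(y1, 2, stats::var); v2 <- apply(y2, 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
}

# Hand-rolled Benjamini-Hochberg step-up rejection set.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  thresh <- alpha * seq_len(m) / m
  passed <- which(p[ord] <= thresh)
  reject <- rep(FALSE, m)
  if (length(passed) > 0) reject[ord[seq_len(max(passed))]] <- TRUE
  reject
}

# Ideal band-pass by direct DFT sums (independent of stats::fft).
oracle_bandpass <- function(x, band, tr) {
  n <- length(x)
  j <- 0:(n - 1)
  out <- numeric(n)
  for (f in 0:(n - 1)) {
    fr <- f / (n * tr)
    fr <- min(fr, 1 / tr - fr)
    if (fr < band[1] || fr > band[2]) next
    coef <- sum(x * exp(-2i * pi * f * j / n))
    out <- out + Re(coef * exp(2i * pi * f * j / n)) / n
  }
  out
}

# Toy tractogram fixture with a full-column-rank operator: a fully
# mapped 3x3x3 grid (one node per voxel) admits 81 straight spans; spans
# on one line are independent (length <= 3), parallel lines have
# disjoint support, and spans of different axes are separated by their
# distinct stick-attenuation profiles across volumes.
make_recovery_fixture <- function(seed = 7L, n_streamlines = 50L) {
  gs <- c(3L, 3L, 3L)
  nm <- seq_len(27L)
  toy <- gen_toy_tractogram(gs, n_streamlines, nm, seed = seed)
  c(toy, list(grid_shape = gs, node_map = nm, n_nodes = 27L))
}

# Small cohort settings reused by unit tests (kept light).
small_config <- function(seed = 1L, ...) {
  synth_config(n_patients = 12L, n_controls = 14L, n_nodes = 30L,
               n_subnet = 5L, seed = seed, ...)
}
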