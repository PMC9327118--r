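rand_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  e <- runif(sum(ut)) < p
  w <- ifelse(e, runif(sum(ut), 0.2, 1), 0)
  m[ut] <- w
  m + t(m)
}

test_that("density and mean strength on hand-checkable graphs", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(graph_density(k4), 1)
  expect_equal(graph_density(matrix(0, 4, 4)), 0)
  g5 <- matrix(0, 5, 5); g5[1, 2] <- g5[2, 1] <- 1; g5[3, 4] <- g5[4, 3] <- 1
  expect_equal(graph_density(g5), 0.2)

  dy <- matrix(0, 2, 2); dy[1, 2] <- dy[2, 1] <- 0.7
  expect_equal(mean_strength(dy), 0.7)
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1; tri[1, 3] <- tri[3, 1] <- 2
  tri[2, 3] <- tri[3, 2] <- 3
  expect_equal(mean_strength(tri), 4)  # strengths (3, 4, 5)
  # an isolated node dilutes the mean
  tri4 <- rbind(cbind(tri, 0), 0)
  expect_lt(mean_strength(tri4), mean_strength(tri))
})

test_that("global efficiency matches shortest-path enumeration", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(global_efficiency(k4), 1)
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 1; chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(global_efficiency(chain), (1 + 1 + 0.5) * 2 / 6)
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- 1; dyads[3, 4] <- dyads[4, 3] <- 1
  expect_equal(global_efficiency(dyads), (1 + 1) * 2 / 12)
  # weighted path shorter through a relay than the direct edge
  g <- matrix(0, 3, 3)
  g[1, 2] <- g[2, 1] <- 10; g[2, 3] <- g[3, 2] <- 10; g[1, 3] <- g[3, 1] <- 1
  expect_equal(global_efficiency(g), oracle_efficiency(g))
  expect_error(global_efficiency(-k4))
})

test_that("clustering coefficient matches brute-force triplet counting", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_coefficient(tri), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_coefficient(star), 0)
  # 4-clique minus one edge
  g <- matrix(1, 4, 4); diag(g) <- 0
  g[3, 4] <- g[4, 3] <- 0
  expect_equal(clustering_coefficient(g), oracle_clustering(g),
               tolerance = 1e-12)
  # degree-3 nodes close 2 of their 3 triplets; degree-2 nodes close 1 of 1
  expect_equal(clustering_coefficient(g), mean(c(2 / 3, 2 / 3, 1, 1)))
})

test_that("spectral modularity finds planted partitions", {
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- 1; dyads[3, 4] <- dyads[4, 3] <- 1
  md <- modularity_spectral(dyads)
  expect_equal(md$Q, 0.5)
  expect_equal(length(unique(md$membership)), 2)
  expect_equal(md$Q, oracle_max_modularity(dyads), tolerance = 1e-12)

  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  mk <- modularity_spectral(k5)
  expect_equal(mk$Q, 0)
  expect_equal(length(unique(mk$membership)), 1)

  # two 5-cliques joined by one edge: optimum is the two cliques
  g <- matrix(0, 10, 10)
  g[1:5, 1:5] <- 1; g[6:10, 6:10] <- 1; diag(g) <- 0
  g[5, 6] <- g[6, 5] <- 1
  mg <- modularity_spectral(g)
  expect_equal(length(unique(mg$membership)), 2)
  expect_equal(mg$membership[1:5], rep(mg$membership[1], 5))
  # brute force restricted to 2-block partitions
  best2 <- max(vapply(1:(2^9), function(code) {
    partition_q(g, as.integer(intToBits(code - 1))[1:10])
  }, numeric(1)))
  expect_equal(mg$Q, best2, tolerance = 1e-12)
  expect_error(modularity_spectral(matrix(0, 3, 3)), "empty")
})

test_that("metrics are invariant under node relabeling", {
  g <- rand_graph(8, seed = 5)
  perm <- sample(8)
  gp <- g[perm, perm]
  expect_equal(graph_density(gp), graph_density(g))
  expect_equal(mean_strength(gp), mean_strength(g))
  expect_equal(global_efficiency(gp), global_efficiency(g))
  expect_equal(clustering_coefficient(gp), clustering_coefficient(g))
  expect_equal(modularity_spectral(gp)$Q, modularity_spectral(g)$Q,
               tolerance = 1e-12)
})

test_that("efficiency is monotone under edge-weight increase", {
  g <- rand_graph(8, seed = 6)
  e0 <- global_efficiency(g)
  g2 <- g
  ij <- which(g2 > 0, arr.ind = TRUE)[1, ]
  g2[ij[1], ij[2]] <- g2[ij[2], ij[1]] <- g2[ij[1], ij[2]] * 2
  expect_gte(global_efficiency(g2), e0)
  g3 <- g * 2
  expect_gte(global_efficiency(g3), e0)
})

test_that("weighted metrics reduce to binary definitions on 0/1 graphs", {
  for (s in 1:5) {
    g <- rand_graph(8, p = 0.4, seed = 20 + s)
    b <- (g > 0) * 1
    if (sum(b) == 0) next
    ig <- igraph::graph_from_adjacency_matrix(b, mode = "undirected")
    # efficiency against unweighted igraph shortest paths
    d <- igraph::distances(ig)
    inv <- 1 / d; diag(inv) <- 0; inv[is.infinite(d)] <- 0
    expect_equal(global_efficiency(b), sum(inv) / (8 * 7))
    # clustering against igraph local transitivity (zeros for deg < 2)
    lt <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    expect_equal(clustering_coefficient(b), mean(lt), tolerance = 1e-12)
  }
})

test_that("spectral modularity is cross-checked by igraph on a planted graph", {
  set.seed(8)
  g <- matrix(0, 12, 12)
  g[1:6, 1:6] <- runif(36, 0.5, 1); g[7:12, 7:12] <- runif(36, 0.5, 1)
  g[1, 7] <- 0.1
  g[lower.tri(g)] <- t(g)[lower.tri(g)]
  diag(g) <- 0
  ours <- modularity_spectral(g)
  ig <- igraph::graph_from_adjacency_matrix(g, mode = "undirected",
                                            weighted = TRUE)
  cle <- igraph::cluster_leading_eigen(ig, weights = igraph::E(ig)$weight)
  expect_equal(sort(unique(ours$membership)),
               sort(unique(igraph::membership(cle))))
  expect_equal(ours$Q, igraph::modularity(ig, igraph::membership(cle),
                                          weights = igraph::E(ig)$weight),
               tolerance = 1e-6)
})
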