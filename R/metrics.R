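#' @name graph-metrics
#' @title Global weighted graph metrics
#' @description Five global metrics of weighted undirected connectomes:
#' density, mean strength, global efficiency, (Onnela) weighted
#' clustering coefficient and Newman spectral modularity. All expect a
#' symmetric nonnegative matrix with zero diagonal.
NULL

check_adjacency <- function(g, min_n = 2L) {
  g <- as.matrix(g)
  if (nrow(g) != ncol(g) || nrow(g) < min_n)
    stop("need a square matrix with at least ", min_n, " nodes")
  if (max(abs(g - t(g))) > 1e-10) stop("matrix must be symmetric")
  if (any(g < 0)) stop("edge weights must be nonnegative")
  diag(g) <- 0
  g
}

#' @rdname graph-metrics
#' @param g symmetric nonnegative weight matrix, zero diagonal.
#' @return `graph_density`: fraction of possible edges that are nonzero.
#' @export
graph_density <- function(g) {
  g <- check_adjacency(g)
  mean(g[upper.tri(g)] != 0)
}

#' @rdname graph-metrics
#' @return `mean_strength`: average over nodes of the summed incident
#'   edge weights.
#' @export
mean_strength <- function(g) {
  g <- check_adjacency(g, min_n = 1L)
  mean(rowSums(g))
}

#' @rdname graph-metrics
#' @return `global_efficiency`: mean over ordered node pairs of the
#'   inverse weighted shortest-path length (edge length = 1/weight);
#'   disconnected pairs contribute 0.
#' @export
global_efficiency <- function(g) {
  g <- check_adjacency(g)
  n <- nrow(g)
  ig <- igraph::graph_from_adjacency_matrix(g, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  if (igraph::ecount(ig) == 0) return(0)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' @rdname graph-metrics
#' @return `clustering_coefficient`: average over nodes of the Onnela
#'   weighted clustering (geometric-mean triangle intensity, weights
#'   normalised by the network maximum); nodes with binary degree < 2
#'   contribute 0.
#' @export
clustering_coefficient <- function(g) {
  g <- check_adjacency(g)
  mw <- max(g)
  if (mw == 0) return(0)
  w3 <- (g / mw)^(1 / 3)
  cyc3 <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(g > 0)
  ci <- ifelse(k >= 2, cyc3 / (k * (k - 1)), 0)
  mean(ci)
}

# One Kernighan-Lin-style fine-tuning round over a +-1 split vector:
# repeatedly flip the single node giving the best change in s' B s (each
# node moved at most once per pass), keep the best intermediate state,
# iterate passes while the objective improves. Ties go to the lowest
# node index.
kl_refine <- function(Bg, s, tol = 1e-12) {
  n <- length(s)
  qval <- function(sv) as.numeric(t(sv) %*% Bg %*% sv)
  best_q <- qval(s)
  repeat {
    s_work <- s
    moved <- rep(FALSE, n)
    pass_q <- numeric(n)
    pass_s <- vector("list", n)
    for (step in seq_len(n)) {
      gains <- -4 * s_work * as.numeric(Bg %*% s_work) + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      s_work[i] <- -s_work[i]
      moved[i] <- TRUE
      pass_q[step] <- qval(s_work)
      pass_s[[step]] <- s_work
    }
    bi <- which.max(pass_q)
    if (pass_q[bi] > best_q + tol) {
      s <- pass_s[[bi]]
      best_q <- pass_q[bi]
    } else break
  }
  s
}

#' Newman spectral modularity with fine-tuning
#'
#' Recursive leading-eigenvector bisection of the (generalised)
#' modularity matrix B = W - k k' / 2m, with Kernighan-Lin-style
#' single-node fine-tuning after each split, stopping when no split
#' yields a positive modularity gain. Deterministic: the eigenvector is
#' oriented so its first nonzero component is positive and ties in
#' fine-tuning go to the lowest node index.
#'
#' @param g symmetric nonnegative weight matrix, zero diagonal (at least
#'   one edge).
#' @param tol gain tolerance for accepting a split.
#' @return List: `Q` (weighted modularity of the final partition) and
#'   `membership` (integer community labels).
#' @export
modularity_spectral <- function(g, tol = 1e-10) {
  g <- check_adjacency(g)
  n <- nrow(g)
  m2 <- sum(g)
  if (m2 == 0) stop("modularity is undefined for an empty graph")
  k <- rowSums(g)
  B <- g - outer(k, k) / m2

  membership <- integer(n)
  next_label <- 1L
  queue <- list(seq_len(n))
  while (length(queue) > 0) {
    idx <- queue[[1]]
    queue <- queue[-1]
    divided <- FALSE
    if (length(idx) > 1) {
      Bg <- B[idx, idx, drop = FALSE]
      diag(Bg) <- diag(Bg) - rowSums(Bg)
      eig <- eigen(Bg, symmetric = TRUE)
      if (eig$values[1] > tol) {
        v <- eig$vectors[, 1]
        fz <- which(abs(v) > 1e-12)[1]
        if (!is.na(fz) && v[fz] < 0) v <- -v
        s <- ifelse(v >= 0, 1, -1)
        s <- kl_refine(Bg, s)
        dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * m2)
        if (dq > tol && length(unique(s)) == 2) {
          queue <- c(queue, list(idx[s > 0]), list(idx[s < 0]))
          divided <- TRUE
        }
      }
    }
    if (!divided) {
      membership[idx] <- next_label
      next_label <- next_label + 1L
    }
  }
  same <- outer(membership, membership, `==`)
  list(Q = sum(B[same]) / m2, membership = membership)
}

#' All five global metrics of a connectome
#'
#' @param g symmetric nonnegative weight matrix.
#' @return List: `density`, `mean_strength`, `global_efficiency`,
#'   `clustering_coefficient`, `modularity`, `membership`.
#' @export
graph_metrics <- function(g) {
  mod <- if (sum(check_adjacency(g)) > 0) modularity_spectral(g) else
    list(Q = NA_real_, membership = rep(1L, nrow(g)))
  list(density = graph_density(g),
       mean_strength = mean_strength(g),
       global_efficiency = global_efficiency(g),
       clustering_coefficient = clustering_coefficient(g),
       modularity = mod$Q,
       membership = mod$membership)
}
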