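#' Merge cerebellar parcels of an AAL-style node table
#'
#' Collapses the 116-region automated anatomical labelling parcellation to
#' the 100 nodes used for connectome construction: all vermis subdivisions
#' become a single vermis node and each pair of homologous cerebellar
#' hemisphere regions is merged into one node. Cerebral nodes pass through
#' unchanged.
#'
#' @param nodes data.frame with columns `node_id`, `name`,
#'   `is_cerebellar_hemispheric`, `is_vermis`, `homologue_id` (NA for
#'   unpaired nodes).
#' @return List with `nodes` (merged table, new consecutive `node_id`s)
#'   and `mapping` (integer vector: input node -> output node).
#' @export
merge_cerebellar <- function(nodes) {
  req <- c("node_id", "name", "is_cerebellar_hemispheric", "is_vermis",
           "homologue_id")
  if (!all(req %in% names(nodes))) stop("node table lacks required columns")
  if (anyDuplicated(nodes$node_id)) stop("node ids must be unique")
  n <- nrow(nodes)
  idx <- match(nodes$node_id, nodes$node_id)  # identity; rows keyed by id
  mapping <- integer(n)
  out_names <- character(0)
  vermis_out <- NA_integer_

  hemi <- which(nodes$is_cerebellar_hemispheric)
  for (i in hemi) {
    h <- nodes$homologue_id[i]
    if (is.na(h) || !h %in% nodes$node_id ||
        !nodes$is_cerebellar_hemispheric[match(h, nodes$node_id)] ||
        nodes$homologue_id[match(h, nodes$node_id)] != nodes$node_id[i])
      stop("unpaired cerebellar hemispheric node: ", nodes$name[i])
  }

  for (i in seq_len(n)) {
    if (nodes$is_vermis[i]) {
      if (is.na(vermis_out)) {
        out_names <- c(out_names, "Vermis")
        vermis_out <- length(out_names)
      }
      mapping[i] <- vermis_out
    } else if (nodes$is_cerebellar_hemispheric[i]) {
      j <- match(nodes$homologue_id[i], nodes$node_id)
      if (mapping[j] > 0) {
        mapping[i] <- mapping[j]
      } else {
        out_names <- c(out_names, sub("_(L|R)$", "", nodes$name[i]))
        mapping[i] <- length(out_names)
      }
    } else {
      out_names <- c(out_names, nodes$name[i])
      mapping[i] <- length(out_names)
    }
  }
  list(nodes = data.frame(node_id = seq_along(out_names), name = out_names,
                          stringsAsFactors = FALSE),
       mapping = mapping)
}

#' Bundle edge weight from streamline weights and lengths
#'
#' The quantitative edge weight of a bundle of N streamlines with
#' intra-axonal signal fractions x_k and lengths l_k:
#' `a = sum(x_k * l_k) / (sum(l_k) / N)`, i.e. the length-weighted total
#' signal fraction divided by the mean streamline length.
#'
#' @param weights nonnegative streamline weights (signal-fraction units).
#' @param lengths positive streamline lengths (mm).
#' @return The bundle weight (signal-fraction units).
#' @export
bundle_edge_weight <- function(weights, lengths) {
  if (length(weights) == 0 || length(weights) != length(lengths))
    stop("weights and lengths must be nonempty and equal length")
  if (any(lengths <= 0)) stop("streamline lengths must be > 0")
  if (any(weights < 0)) stop("streamline weights must be >= 0")
  sum(weights * lengths) / (sum(lengths) / length(lengths))
}

#' Assemble the structural connectome from fitted streamline weights
#'
#' Groups streamlines by endpoint node pair and applies
#' [bundle_edge_weight()] per bundle. Self-connections are excluded;
#' streamlines with endpoints outside the node table are skipped with a
#' warning.
#'
#' @param tractogram a `tractogram`.
#' @param fitted a `streamline_weights` (or plain numeric vector of
#'   per-streamline weights).
#' @param nodes node table with `node_id` (defines the matrix order).
#' @return List of class `structural_connectome`: `weights` (symmetric,
#'   zero diagonal), `n_streamlines` (symmetric count matrix) and `nodes`.
#' @export
assemble_structural <- function(tractogram, fitted, nodes) {
  x <- if (inherits(fitted, "streamline_weights")) fitted$x else
    as.numeric(fitted)
  sl <- tractogram$streamlines
  if (length(x) != length(sl))
    stop("one weight per streamline required")
  ids <- nodes$node_id
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(nodes$name, nodes$name))
  cnt <- matrix(0L, n, n, dimnames = dimnames(w))

  ep <- t(vapply(sl, function(s) s$endpoints, numeric(2)))
  len <- vapply(sl, function(s) s$length, numeric(1))
  i <- match(pmin(ep[, 1], ep[, 2]), ids)
  j <- match(pmax(ep[, 1], ep[, 2]), ids)
  unknown <- is.na(i) | is.na(j)
  if (any(unknown))
    warning(sum(unknown), " streamline(s) with unknown endpoint node skipped")
  keep <- !unknown & i != j
  for (key in unique(paste(i[keep], j[keep]))) {
    k <- keep & paste(i, j) == key
    ii <- i[k][1]; jj <- j[k][1]
    w[ii, jj] <- w[jj, ii] <- bundle_edge_weight(x[k], len[k])
    cnt[ii, jj] <- cnt[jj, ii] <- sum(k)
  }
  structure(list(weights = w, n_streamlines = cnt, nodes = nodes),
            class = "structural_connectome")
}

#' Prevalence filtering of cohort structural connectomes
#'
#' Removes edges present (nonzero) in fewer than half of the healthy
#' controls; the resulting mask is applied to every subject. With an odd
#' number of controls an edge is removed when its presence count is
#' strictly below N/2 (i.e. count <= floor(N/2)).
#'
#' @param matrices list of symmetric weight matrices (all subjects).
#' @param hc_ids indices into `matrices` identifying the controls.
#' @return List: `matrices` (filtered), `mask` (logical matrix of kept
#'   edges), `n_removed` (edges removed among those present anywhere).
#' @export
prevalence_filter <- function(matrices, hc_ids) {
  if (length(hc_ids) < 1) stop("at least one control subject required")
  n <- nrow(matrices[[1]])
  presence <- Reduce(`+`, lapply(matrices[hc_ids], function(m) m != 0))
  mask <- presence >= length(hc_ids) / 2
  diag(mask) <- FALSE
  any_edge <- Reduce(`|`, lapply(matrices, function(m) m != 0))
  list(matrices = lapply(matrices, function(m) ifelse(mask, m, 0)),
       mask = mask,
       n_removed = sum(any_edge[upper.tri(any_edge)] &
                         !mask[upper.tri(mask)]))
}

#' Confound regression and band-pass filtering of node time series
#'
#' Residualises each node series on the confound regressors (an intercept
#' is always included), then applies an ideal band-pass filter by Fourier
#' masking: frequency bins with `band[1] <= f <= band[2]` Hz are kept,
#' all others (including DC) are zeroed, so each output series has mean
#' ~0.
#'
#' @param series numeric matrix, time x nodes.
#' @param confounds numeric matrix of regressors (time x q), or `NULL`
#'   for intercept-only.
#' @param band length-2 numeric, pass band in Hz (default 0.008-0.09).
#' @param tr repetition time in seconds.
#' @return Cleaned series, same dimensions.
#' @export
clean_series <- function(series, confounds = NULL, band = c(0.008, 0.09),
                         tr = 2.5) {
  series <- as.matrix(series)
  nt <- nrow(series)
  X <- cbind(rep(1, nt), confounds)
  if (nt <= 2 * ncol(X)) stop("series too short for the confound model")
  nyq <- 1 / (2 * tr)
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] < nyq + 1e-12))
    stop("band must satisfy 0 <= low < high < Nyquist")
  if (any(apply(series, 2, stats::sd) == 0))
    warning("constant node series: residual is zero")
  res <- as.matrix(stats::lm.fit(X, series)$residuals)

  freqs <- (seq_len(nt) - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # fold to physical frequency
  keep <- freqs >= band[1] & freqs <= band[2]
  out <- apply(res, 2, function(x) Re(stats::fft(stats::fft(x) * keep,
                                                 inverse = TRUE)) / nt)
  dimnames(out) <- dimnames(series)
  out
}

#' Fisher-z functional connectome from node time series
#'
#' Edge (i, j) is atanh of the Pearson correlation between the series of
#' nodes i and j; the diagonal is zero.
#'
#' @param series numeric matrix, time x nodes (>= 3 time points).
#' @return Symmetric matrix of Fisher-z weights (class
#'   `functional_connectome` attribute not enforced; plain matrix).
#' @export
fisher_connectome <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3) stop("at least 3 time points required")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) stop("constant node series cannot be correlated")
  r <- stats::cor(series)
  diag(r) <- 0
  if (any(abs(r) >= 1 - 1e-12)) {
    bad <- which(abs(r) >= 1 - 1e-12, arr.ind = TRUE)[1, ]
    stop("perfect correlation between nodes ", bad[1], " and ", bad[2],
         ": Fisher z is infinite")
  }
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Absolutise and proportionally threshold a functional connectome
#'
#' Takes absolute edge values, then keeps exactly
#' `floor(density * n * (n - 1) / 2)` of the largest-magnitude edges,
#' zeroing the rest. Ties are broken deterministically: larger magnitude
#' first, then lexicographic node pair.
#'
#' @param fc symmetric matrix of (signed) Fisher-z weights.
#' @param density fraction of possible edges to retain (0 < density <= 1).
#' @return Symmetric nonnegative matrix with exactly the retained edges
#'   nonzero and attribute `density_applied`.
#' @export
absolutize_and_threshold <- function(fc, density = 0.20) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n <- nrow(fc)
  a <- abs(fc)
  diag(a) <- 0
  m_keep <- floor(density * n * (n - 1) / 2)
  if (m_keep < 1) stop("density retains no edges for this network size")
  ut <- which(upper.tri(a), arr.ind = TRUE)
  vals <- a[ut]
  ord <- order(-vals, ut[, 1], ut[, 2])
  drop <- ord[-seq_len(m_keep)]
  out <- matrix(0, n, n, dimnames = dimnames(fc))
  keep_idx <- ut[ord[seq_len(m_keep)], , drop = FALSE]
  out[keep_idx] <- a[keep_idx]
  out[keep_idx[, 2:1, drop = FALSE]] <- a[keep_idx]
  attr(out, "density_applied") <- density
  out
}
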