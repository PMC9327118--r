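#' Configuration for network-based statistics
#'
#' @param thresholds primary t-thresholds to sweep (default 2.0 to 4.0 by
#'   0.1).
#' @param n_perm number of permutations (>= 100).
#' @param size_measure component size measure: `"intensity"` (sum of
#'   supra-threshold t values) or `"extent"` (edge count).
#' @param alpha family-wise error level.
#' @param seed integer seed for the permutation draw.
#' @param contrast direction string `"A<B"` or `"A>B"` over the two group
#'   levels; supra-threshold evidence is counted in this direction.
#' @return List of class `nbs_config`.
#' @export
nbs_config <- function(thresholds = seq(2.0, 4.0, by = 0.1),
                       n_perm = 5000L,
                       size_measure = c("intensity", "extent"),
                       alpha = 0.05, seed = 1L,
                       contrast = "patient<control") {
  size_measure <- match.arg(size_measure)
  stopifnot(all(thresholds > 0), n_perm >= 100, alpha > 0, alpha < 1)
  structure(list(thresholds = thresholds, n_perm = as.integer(n_perm),
                 size_measure = size_measure, alpha = alpha,
                 seed = as.integer(seed), contrast = contrast),
            class = "nbs_config")
}

# Parse "A<B" / "A>B" against the factor levels of `group`; returns the
# sign to apply to the t-statistic of the second-level dummy so that
# positive values are evidence FOR the contrast.
contrast_sign <- function(contrast, group) {
  m <- regmatches(contrast, regexec("^\\s*(\\S+?)\\s*([<>])\\s*(\\S+?)\\s*$",
                                    contrast))[[1]]
  if (length(m) != 4) stop("contrast must look like 'groupA<groupB'")
  lv <- levels(group)
  if (!all(c(m[2], m[4]) %in% lv))
    stop("contrast names unknown group level(s); levels are: ",
         paste(lv, collapse = ", "))
  # dummy codes lv[2]; coefficient = mean(lv[2]) - mean(lv[1])
  lower <- if (m[3] == "<") m[2] else m[4]   # the side claimed smaller
  if (lower == lv[2]) -1 else 1
}

# Upper-triangle extraction of a subject list into a subjects x edges
# matrix restricted to `mask_idx` (indices into the upper triangle).
edges_matrix <- function(matrices, mask_idx) {
  ut <- upper.tri(matrices[[1]])
  t(vapply(matrices, function(m) m[ut][mask_idx],
           numeric(length(mask_idx))))
}

#' Mass-univariate edgewise GLM t-statistics
#'
#' Fits, at every edge, an ordinary linear model of the edge weight on
#' group plus nuisance covariates, and returns the t-statistic of the
#' group contrast as a symmetric matrix (positive = evidence for the
#' contrast direction).
#'
#' @param matrices list of symmetric subject matrices (same node set).
#' @param design data.frame with a two-level factor column `group`; all
#'   other columns enter as nuisance covariates.
#' @param contrast direction string, see [nbs_config()].
#' @param mask logical matrix of edges to test; defaults to edges nonzero
#'   in at least one subject.
#' @return Symmetric t matrix with `NA` outside the mask; attribute
#'   `mask`.
#' @export
edge_stats <- function(matrices, design, contrast = "patient<control",
                       mask = NULL) {
  n_sub <- length(matrices)
  if (nrow(design) != n_sub) stop("design rows must match subjects")
  group <- design$group
  if (!is.factor(group) || nlevels(group) != 2)
    stop("design$group must be a two-level factor")
  covs <- design[setdiff(names(design), "group")]
  X <- stats::model.matrix(~ ., data = cbind(group = group, covs))
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (n_sub < ncol(X) + 2) stop("too few subjects for the design")

  n <- nrow(matrices[[1]])
  ut <- upper.tri(matrices[[1]])
  if (is.null(mask)) {
    any_edge <- Reduce(`|`, lapply(matrices, function(m) m != 0))
    mask <- any_edge | t(any_edge)
    diag(mask) <- FALSE
  }
  mask_idx <- which(mask[ut])
  Y <- edges_matrix(matrices, mask_idx)
  sgn <- contrast_sign(contrast, group)
  tv <- glm_t(X, Y, gcol = 2L) * sgn

  tmat <- matrix(NA_real_, n, n, dimnames = dimnames(matrices[[1]]))
  utc <- which(ut)
  tmat[utc[mask_idx]] <- tv
  tmat[lower.tri(tmat)] <- t(tmat)[lower.tri(tmat)]
  attr(tmat, "mask") <- mask
  tmat
}

# Vectorised OLS t-statistic of column `gcol` of X across all columns of
# Y (subjects x edges).
glm_t <- function(X, Y, gcol = 2L) {
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(pmax(sigma2 * XtXi[gcol, gcol], .Machine$double.eps))
  as.numeric(beta[gcol, ] / se)
}

#' Connected components of supra-threshold edges
#'
#' @param t_map symmetric t matrix (as from [edge_stats()]; `NA` edges
#'   are ignored).
#' @param threshold primary threshold; edges with t > threshold are kept.
#' @return List of components, each with `nodes`, `edges` (2-column
#'   matrix), `extent` (edge count) and `intensity` (sum of edge t).
#'   Sorted by decreasing intensity.
#' @export
supra_components <- function(t_map, threshold) {
  ut <- which(upper.tri(t_map) & !is.na(t_map) & t_map > threshold,
              arr.ind = TRUE)
  if (nrow(ut) == 0) return(list())
  comps <- components_of_edges(ut[, 1], ut[, 2],
                               t_map[ut], nrow(t_map))
  comps[order(-vapply(comps, `[[`, numeric(1), "intensity"))]
}

# Union-find over an edge list; returns per-component summaries.
components_of_edges <- function(ei, ej, tv, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (q in seq_along(ei)) {
    ra <- find(ei[q]); rb <- find(ej[q])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(ei, find, integer(1))
  lapply(unique(roots), function(r) {
    sel <- roots == r
    list(nodes = sort(unique(c(ei[sel], ej[sel]))),
         edges = cbind(ei[sel], ej[sel]),
         extent = sum(sel),
         intensity = sum(tv[sel]))
  })
}

# Largest component size (per the chosen measure) at each threshold, for
# a vector of edge t values on a fixed edge list.
max_comp_sizes <- function(ei, ej, tv, thresholds, n_nodes, measure) {
  vapply(thresholds, function(th) {
    sel <- which(tv > th)
    if (length(sel) == 0) return(0)
    comps <- components_of_edges(ei[sel], ej[sel], tv[sel], n_nodes)
    max(vapply(comps, `[[`, numeric(1),
               if (measure == "intensity") "intensity" else "extent"))
  }, numeric(1))
}

#' Network-based statistics with permutation FWER control
#'
#' Four-step NBS: edgewise GLM t-statistics for the group contrast with
#' nuisance covariates, primary thresholding, connected-component
#' formation, and a family-wise-error-corrected p-value per component
#' from the permutation distribution of the maximal component size.
#' Permutation follows Freedman-Lane: residuals from the nuisance-only
#' model are permuted and added back to the nuisance fit before the full
#' model is re-estimated. The add-one estimator
#' p = (1 + #\{null >= observed\}) / (n_perm + 1) is used.
#'
#' @param matrices list of symmetric subject matrices.
#' @param design data.frame with factor `group` plus nuisance covariates.
#' @param config an [nbs_config()].
#' @param mask logical edge mask (e.g. from [prevalence_filter()]).
#' @return List of class `nbs_result`: per-threshold component lists with
#'   FWER p-values, the permutation null matrix (n_perm x thresholds) and
#'   the config.
#' @export
nbs_test <- function(matrices, design, config = nbs_config(), mask = NULL) {
  group <- design$group
  if (min(table(group)) < 2) stop("need at least 2 subjects per group")
  n_sub <- length(matrices)
  n_nodes <- nrow(matrices[[1]])
  covs <- design[setdiff(names(design), "group")]
  X <- stats::model.matrix(~ ., data = cbind(group = group, covs))
  sgn <- contrast_sign(config$contrast, group)

  ut <- upper.tri(matrices[[1]])
  if (is.null(mask)) {
    any_edge <- Reduce(`|`, lapply(matrices, function(m) m != 0))
    mask <- any_edge | t(any_edge)
    diag(mask) <- FALSE
  }
  mask_idx <- which(mask[ut])
  utc_ij <- which(ut, arr.ind = TRUE)[mask_idx, , drop = FALSE]
  Y <- edges_matrix(matrices, mask_idx)

  t_obs <- glm_t(X, Y, 2L) * sgn
  obs_by_thr <- lapply(config$thresholds, function(th) {
    sel <- which(t_obs > th)
    if (length(sel) == 0) return(list())
    comps <- components_of_edges(utc_ij[sel, 1], utc_ij[sel, 2],
                                 t_obs[sel], n_nodes)
    comps[order(-vapply(comps, `[[`, numeric(1), "intensity"))]
  })

  # Freedman-Lane: reduced (nuisance-only) model fit and residuals
  Z <- X[, -2L, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  fitted_z <- Hz %*% Y
  resid_z <- Y - fitted_z

  n_distinct <- suppressWarnings(factorial(n_sub))
  exhaustive <- is.finite(n_distinct) && n_distinct <= config$n_perm
  if (exhaustive) {
    warning("n_perm exceeds the number of distinct permutations; ",
            "enumerating all ", n_distinct, " permutations")
    perms <- all_permutations(n_sub)
  } else {
    set.seed(config$seed)
    perms <- lapply(seq_len(config$n_perm), function(i) sample.int(n_sub))
  }

  null_max <- matrix(0, length(perms), length(config$thresholds))
  for (p in seq_along(perms)) {
    Yp <- fitted_z + resid_z[perms[[p]], , drop = FALSE]
    tp <- glm_t(X, Yp, 2L) * sgn
    null_max[p, ] <- max_comp_sizes(utc_ij[, 1], utc_ij[, 2], tp,
                                    config$thresholds, n_nodes,
                                    config$size_measure)
  }

  results <- lapply(seq_along(config$thresholds), function(ti) {
    comps <- obs_by_thr[[ti]]
    lapply(comps, function(cc) {
      size <- if (config$size_measure == "intensity") cc$intensity else
        cc$extent
      cc$size <- size
      cc$p_fwer <- (1 + sum(null_max[, ti] >= size)) / (length(perms) + 1)
      cc$significant <- cc$p_fwer <= config$alpha
      cc
    })
  })
  names(results) <- format(config$thresholds)
  structure(list(components = results, null_max = null_max,
                 thresholds = config$thresholds, config = config),
            class = "nbs_result")
}

# All permutations of 1..n (n small), deterministic order.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  q <- 0L
  for (s in sub) {
    for (i in seq_len(n)) {
      q <- q + 1L
      out[[q]] <- as.integer(append(s, n, after = i - 1L))
    }
  }
  out
}
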