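test_that("cerebellar merging collapses vermis and homologue pairs", {
  nodes <- aal116_nodes()
  m <- merge_cerebellar(nodes)
  expect_equal(nrow(m$nodes), 100)
  expect_equal(sum(m$nodes$name == "Vermis"), 1)
  expect_length(m$mapping, 116)
  expect_setequal(m$mapping, m$nodes$node_id)  # mapping covers all outputs
  # cerebral nodes unchanged (first 90 rows)
  expect_equal(m$nodes$name[m$mapping[1:90]], nodes$name[1:90])

  # identity on a cerebrum-only table
  cer <- nodes[1:10, ]
  m2 <- merge_cerebellar(cer)
  expect_equal(m2$nodes$name, cer$name)
  expect_equal(m2$mapping, 1:10)

  # a single homologue pair merges to one node
  pair <- data.frame(node_id = 1:2,
                     name = c("Cerebelum_X_L", "Cerebelum_X_R"),
                     is_cerebellar_hemispheric = TRUE, is_vermis = FALSE,
                     homologue_id = c(2L, 1L))
  m3 <- merge_cerebellar(pair)
  expect_equal(nrow(m3$nodes), 1)
  expect_equal(m3$nodes$name, "Cerebelum_X")

  # unpaired flagged node errors
  bad <- pair[1, ]
  bad$homologue_id <- NA_integer_
  expect_error(merge_cerebellar(bad), "unpaired")
})

test_that("bundle edge weight equals the length-weighted formula", {
  expect_equal(bundle_edge_weight(c(0.5, 0.25), c(10, 20)),
               10 / 15, tolerance = 1e-12)
  expect_equal(bundle_edge_weight(0.7, 42), 0.7)    # single streamline
  # constant weights, equal lengths: reduces to N * c
  expect_equal(bundle_edge_weight(rep(0.3, 5), rep(12, 5)), 1.5)
  expect_error(bundle_edge_weight(numeric(0), numeric(0)))
  expect_error(bundle_edge_weight(0.5, 0), "> 0")
})

test_that("structural assembly matches an independent per-bundle oracle", {
  fx <- make_recovery_fixture(seed = 21, n_streamlines = 30)
  nn <- fx$n_nodes
  nodes <- data.frame(node_id = seq_len(nn), name = paste0("roi_", 1:nn))
  sc <- assemble_structural(fx$tractogram, fx$truth$streamline_weights,
                            nodes)
  expect_equal(sc$weights, t(sc$weights))
  expect_true(all(diag(sc$weights) == 0))

  # oracle: group streamlines by endpoint pair, apply the formula
  ep <- t(vapply(fx$tractogram$streamlines, `[[`, numeric(2), "endpoints"))
  len <- vapply(fx$tractogram$streamlines, `[[`, numeric(1), "length")
  w <- fx$truth$streamline_weights
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
    sel <- (pmin(ep[, 1], ep[, 2]) == i) & (pmax(ep[, 1], ep[, 2]) == j)
    expected <- if (any(sel))
      sum(w[sel] * len[sel]) / (sum(len[sel]) / sum(sel)) else 0
    expect_equal(sc$weights[i, j], expected, tolerance = 1e-12)
    expect_equal(sc$n_streamlines[i, j], sum(sel))
  }

  # a streamline with an endpoint outside the node table is skipped
  drop_id <- fx$tractogram$streamlines[[1]]$endpoints[1]
  expect_warning(
    assemble_structural(fx$tractogram, fx$truth$streamline_weights,
                        nodes[nodes$node_id != drop_id, ]), "skipped")

  # zero weights give a zero matrix but preserved streamline counts
  sc0 <- assemble_structural(fx$tractogram, rep(0, 30), nodes)
  expect_true(all(sc0$weights == 0))
  expect_equal(sc0$n_streamlines, sc$n_streamlines)
})

test_that("prevalence filtering implements the strict-half rule", {
  n_hc <- 49
  base <- matrix(0, 4, 4)
  mk <- function(present) {
    m <- base
    if (present) m[1, 2] <- m[2, 1] <- 1
    m[3, 4] <- m[4, 3] <- 1  # edge in everyone
    m
  }
  # edge (1,2) present in exactly 24 controls -> removed
  mats <- c(lapply(1:24, function(i) mk(TRUE)),
            lapply(25:n_hc, function(i) mk(FALSE)))
  pf <- prevalence_filter(mats, seq_len(n_hc))
  expect_false(pf$mask[1, 2])
  expect_true(pf$mask[3, 4])
  # present in 25 of 49 -> kept
  mats25 <- c(lapply(1:25, function(i) mk(TRUE)),
              lapply(26:n_hc, function(i) mk(FALSE)))
  expect_true(prevalence_filter(mats25, seq_len(n_hc))$mask[1, 2])

  # patient-only edges are removed by the control-derived mask
  pat <- base; pat[1, 3] <- pat[3, 1] <- 5
  pf2 <- prevalence_filter(c(mats, list(pat)), seq_len(n_hc))
  expect_equal(pf2$matrices[[n_hc + 1]][1, 3], 0)

  # idempotence
  pf3 <- prevalence_filter(pf$matrices, seq_len(n_hc))
  expect_equal(pf3$matrices, pf$matrices)
  expect_error(prevalence_filter(mats, integer(0)), "control")
})

test_that("series cleaning matches a direct DFT band-pass oracle", {
  set.seed(42)
  tr <- 2.5
  x <- rnorm(64)
  cleaned <- clean_series(matrix(x), confounds = NULL, tr = tr)
  expect_equal(as.numeric(cleaned), oracle_bandpass(x - mean(x),
                                                    c(0.008, 0.09), tr),
               tolerance = 1e-10)
  expect_lt(abs(mean(cleaned)), 1e-10)

  # a series equal to a confound column residualises to ~0
  conf <- matrix(rnorm(64))
  out <- clean_series(matrix(conf[, 1]), conf, tr = tr)
  expect_lt(max(abs(out)), 1e-10)

  # an out-of-band 0.2 Hz sinusoid is suppressed below 1% power
  t_s <- (0:199) * tr
  sine <- sin(2 * pi * 0.2 * t_s + 0.3)
  filt <- clean_series(matrix(sine), tr = tr)
  expect_lt(sum(filt^2) / sum(sine^2), 0.01)
})

test_that("Fisher-z connectome matches atanh of Pearson correlation", {
  set.seed(1)
  n <- 40
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  s <- cbind(a, b, rnorm(n))
  z <- fisher_connectome(s)
  expect_equal(z[1, 2], atanh(cor(a, b)))
  expect_true(all(diag(z) == 0))
  expect_equal(z, t(z))
  # node relabeling permutes rows/columns consistently
  perm <- c(3, 1, 2)
  expect_equal(fisher_connectome(s[, perm]), z[perm, perm],
               ignore_attr = TRUE)
  expect_error(fisher_connectome(cbind(a, a)), "perfect|infinite")
  expect_error(fisher_connectome(s[1:2, ]), "3 time points")
})

test_that("proportional thresholding keeps exactly the largest edges", {
  set.seed(9)
  n <- 5
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- rnorm(10)
  m <- m + t(m)
  thr <- absolutize_and_threshold(m, density = 0.2)
  expect_equal(sum(thr[upper.tri(thr)] != 0), 2)  # floor(0.2 * 10)
  kept <- sort(abs(m[upper.tri(m)]), decreasing = TRUE)[1:2]
  expect_setequal(thr[upper.tri(thr)][thr[upper.tri(thr)] != 0], kept)
  expect_true(all(thr >= 0))

  # density 1: absolutisation only
  expect_equal(absolutize_and_threshold(m, 1), abs(m), ignore_attr = TRUE)

  # all-equal weights: lexicographically first pairs are kept
  eq <- matrix(1, 4, 4); diag(eq) <- 0
  thr_eq <- absolutize_and_threshold(eq, density = 2 / 6)
  expect_equal(which(thr_eq[upper.tri(thr_eq)] != 0), c(1L, 2L))

  # idempotence at the same density
  expect_equal(absolutize_and_threshold(thr, 0.2), thr, ignore_attr = TRUE)
  expect_error(absolutize_and_threshold(m, 0.001), "no edges")
})
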