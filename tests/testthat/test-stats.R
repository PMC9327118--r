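test_that("robust ANCOVA agrees with classical ANCOVA on homoscedastic data", {
  set.seed(11)
  n <- 60
  group <- factor(rep(c("a", "b"), each = n / 2))
  age <- rnorm(n, 40, 10)
  y <- 1 + 0.5 * (group == "b") + 0.02 * age + rnorm(n)
  covs <- data.frame(age = age)
  ra <- robust_ancova(y, group, covs, robust = TRUE)
  cl <- robust_ancova(y, group, covs, robust = FALSE)
  expect_lt(abs(ra$p_value - cl$p_value) / cl$p_value, 0.10)
  # classical matches summary.lm directly
  fit <- lm(y ~ group + age)
  expect_equal(cl$p_value, summary(fit)$coefficients["groupb", 4])
  expect_error(robust_ancova(rep(1, n), group, covs), "constant")
})

test_that("BH step-up matches the hand-computed oracle", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  res <- bh_fdr(p, 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$reject, oracle_bh_reject(p, 0.05))
  expect_equal(res$p_adjusted, p.adjust(p, "BH"))

  expect_false(any(bh_fdr(rep(1, 5), 0.05)$reject))
  expect_true(bh_fdr(0.03, 0.05)$reject)
  expect_length(bh_fdr(numeric(0), 0.05)$reject, 0)

  # random vectors against the oracle; rejections monotone in alpha
  set.seed(3)
  for (i in 1:20) {
    pv <- runif(15)^2
    expect_equal(bh_fdr(pv, 0.05)$reject, oracle_bh_reject(pv, 0.05))
    expect_true(all(bh_fdr(pv, 0.01)$reject <= bh_fdr(pv, 0.05)$reject))
  }
})

test_that("control-referenced z-scores match a closed-form fixture", {
  # 5 controls on an exact line plus residuals orthogonal to age
  age <- c(1, 2, 3, 4, 5)
  e <- c(1, -2, 0, 2, -1)           # sum 0, orthogonal to centered age
  vals_hc <- 2 * age + e
  sd_e <- sd(e)
  # patient at age 3, exactly 2 residual-SDs above the prediction
  vals <- c(vals_hc, 2 * 3 + 2 * sd_e)
  covs <- data.frame(age = c(age, 3))
  z <- zscore_vs_hc(vals, covs, hc_ids = 1:5)
  expect_equal(z[6], 2.0, tolerance = 1e-10)
  expect_lt(abs(mean(z[1:5])), 1e-10)
  expect_error(zscore_vs_hc(c(2 * age, 6), covs, 1:5), "zero")
})

test_that("disruption index averages edgewise z-scores", {
  ch <- gen_cohort(small_config(seed = 8), modalities = "structural")
  cv <- ch$covariates
  hc <- which(cv$group == "control")
  edges <- ch$ground_truth$subnet_edges
  di <- disruption_index(ch$struct, edges, cv, hc, "structural")
  expect_lt(abs(mean(di[hc])), 1e-8)
  expect_lt(mean(di[cv$group == "patient"]), 0)
  # single-edge subnetwork equals that edge's z-score
  one <- edges[1, , drop = FALSE]
  vals <- vapply(ch$struct, function(m) m[one[1], one[2]], numeric(1))
  expect_equal(disruption_index(ch$struct, one, cv, hc, "structural"),
               zscore_vs_hc(vals, cv[c("age", "sex")], hc))
  # invariant to edge ordering
  expect_equal(disruption_index(ch$struct, edges[nrow(edges):1, ], cv, hc,
                                "structural"), di)
  expect_error(disruption_index(ch$struct, edges[0, ], cv, hc), "empty")
})

test_that("Cohen's d from summary statistics", {
  expect_equal(cohens_d(10, 3, 1, 10, 3, 1), 0)
  # hand check: pooled SD of equal groups is sqrt(mean of variances)
  expect_equal(cohens_d(20, 1, 2, 20, 0, 2), 0.5)
  expect_error(cohens_d(5, 1, 0, 5, 1, 0))
})

test_that("percentage-bend correlation is robust and exact at the poles", {
  set.seed(4)
  x <- rnorm(30)
  expect_equal(pbcor(x, x), 1)
  expect_equal(pbcor(x, -x), -1)
  # a gross outlier barely moves pbcor but wrecks Pearson
  y <- x + rnorm(30, 0, 0.1)
  y2 <- y; y2[1] <- 50
  expect_lt(abs(pbcor(x, y2) - pbcor(x, y)), 0.1)
  expect_gt(abs(cor(x, y2) - cor(x, y)), 0.3)
  expect_error(pbcor(x, rep(1, 30)), "constant")
})

test_that("robust partial correlation recovers the generating association", {
  set.seed(12)
  n <- 80
  z <- rnorm(n)
  x <- 0.8 * z + rnorm(n, 0, 0.6)
  y <- 0.7 * x + 1.5 * z + rnorm(n, 0, 0.5)
  res <- robust_corr_boot(x, y, data.frame(z = z), n_boot = 300, seed = 2)
  # partial correlation of the generating model
  true_r <- 0.7 * 0.6 / sqrt((0.7 * 0.6)^2 + 0.5^2)
  expect_gt(res$ci[1], 0)
  expect_true(res$ci[1] <= true_r && true_r <= res$ci[2])
  expect_lt(res$p_value, 0.01)

  ident <- robust_corr_boot(x, x + rnorm(n, 0, 1e-8), n_boot = 100,
                            seed = 1)
  expect_gt(ident$r, 0.999)
  expect_gt(ident$ci[1], 0.9)
  # deterministic given the seed
  res2 <- robust_corr_boot(x, y, data.frame(z = z), n_boot = 300, seed = 2)
  expect_identical(res, res2)
})

test_that("moderation fit recovers noiseless coefficients exactly", {
  set.seed(14)
  n <- 40
  disr <- rnorm(n, -0.6, 0.4)
  devi <- rnorm(n, 0.1, 0.5)
  age <- rnorm(n, 42, 13)
  sex <- rbinom(n, 1, 0.5)
  betas <- c(16.364, 15.809, -10.793, -28.636, -0.070, -0.681)
  score <- betas[1] + betas[2] * disr + betas[3] * devi +
    betas[4] * disr * devi + betas[5] * age + betas[6] * sex
  fit <- suppressWarnings(moderation_fit(score, disr, devi, age, sex))
  expect_equal(unname(fit$coefficients), betas, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # CI contains the point estimate
  expect_true(all(fit$ci[, 1] <= fit$coefficients &
                    fit$coefficients <= fit$ci[, 2]))
  # permutation of subjects leaves estimates unchanged
  p <- sample(n)
  fit2 <- suppressWarnings(
    moderation_fit(score[p], disr[p], devi[p], age[p], sex[p]))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_error(moderation_fit(score, disr, disr, age, sex), "collinear")
})

test_that("simple slopes are the affine contrasts of the fit", {
  set.seed(15)
  n <- 50
  disr <- rnorm(n); devi <- rnorm(n)
  score <- 2 + 3 * disr - 1 * devi + 0.5 * disr * devi + rnorm(n, 0, 0.1)
  fit <- moderation_fit(score, disr, devi, rnorm(n, 40, 5),
                        rbinom(n, 1, 0.5))
  ss <- simple_slopes(fit, moderator_levels = c(-1, 0, 1))
  b <- fit$coefficients
  expect_equal(ss$slope[2], unname(b["disruption"]))
  expect_equal(ss$slope, unname(b["disruption"] +
                                  b["interaction"] * c(-1, 0, 1)))
  # slopes are affine in the moderator level: collinear points
  expect_equal(diff(ss$slope)[1], diff(ss$slope)[2], tolerance = 1e-12)
  # worked value with the reference coefficient vector
  fit$coefficients["disruption"] <- 15.809
  fit$coefficients["interaction"] <- -28.636
  ss2 <- simple_slopes(fit, moderator_levels = 0.26)
  expect_equal(ss2$slope, 15.809 - 28.636 * 0.26, tolerance = 1e-12)
})
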