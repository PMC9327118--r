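#' Covariate-adjusted group comparison with robust standard errors
#'
#' Ordinary least squares of the metric on group plus covariates, with
#' heteroscedasticity-consistent (HC3 sandwich) standard errors for the
#' group term by default; `robust = FALSE` gives the classical ANCOVA
#' t-test on the same model.
#'
#' @param values per-subject metric.
#' @param group two-level factor.
#' @param covariates data.frame of nuisance covariates (or `NULL`).
#' @param robust use HC3 sandwich standard errors.
#' @return List: `estimate` (adjusted group difference, second level
#'   minus first), `statistic` (t), `p_value`, `df`.
#' @export
robust_ancova <- function(values, group, covariates = NULL, robust = TRUE) {
  if (stats::sd(values) == 0) stop("metric is constant across subjects")
  if (!is.factor(group)) group <- factor(group)
  dat <- data.frame(.y = values, group = group)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::lm(.y ~ ., data = dat)
  gterm <- grep("^group", names(stats::coef(fit)), value = TRUE)[1]
  if (robust) {
    ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC3"))
    est <- ct[gterm, "Estimate"]
    tt <- ct[gterm, "t value"]
    pp <- ct[gterm, "Pr(>|t|)"]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[gterm, "Estimate"]
    tt <- sm[gterm, "t value"]
    pp <- sm[gterm, "Pr(>|t|)"]
  }
  list(estimate = unname(est), statistic = unname(tt),
       p_value = unname(pp), df = fit$df.residual)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure on a vector of p-values.
#'
#' @param pvals p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return List: `reject` (logical), `p_adjusted`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0)
    return(list(reject = logical(0), p_adjusted = numeric(0)))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = adj <= alpha, p_adjusted = adj)
}

#' Healthy-control-referenced z-scores
#'
#' Fits a linear model of the quantity on covariates in the control
#' subjects only, and standardises every subject's observation against
#' that normative model: z = (observed - predicted) / SD of the control
#' residuals.
#'
#' @param values per-subject quantity.
#' @param covariates data.frame of adjustment covariates.
#' @param hc_ids indices of the control subjects (>= 3).
#' @return Numeric z-score per subject.
#' @export
zscore_vs_hc <- function(values, covariates, hc_ids) {
  if (length(hc_ids) < 3) stop("need at least 3 controls")
  dat <- data.frame(.y = values)
  if (!is.null(covariates) && ncol(covariates) > 0)
    dat <- cbind(dat, covariates)
  fit <- stats::lm(.y ~ ., data = dat[hc_ids, , drop = FALSE])
  s <- stats::sd(stats::residuals(fit))
  if (s <= 1e-12 * max(1, stats::sd(values)))
    stop("control residual SD is zero")
  as.numeric(values - stats::predict(fit, newdata = dat)) / s
}

#' Subnetwork disruption / deviation index
#'
#' For every edge of the subnetwork, references the edge weight of each
#' subject to the covariate-adjusted healthy-control distribution
#' ([zscore_vs_hc()]) and averages the z-scores per subject. Structural
#' mode uses raw weights adjusted for age and sex; functional mode uses
#' absolute weights adjusted for age, sex and motion, so positive values
#' reflect increased functional connectivity relative to controls.
#'
#' @param connectomes list of symmetric subject matrices.
#' @param subnet_edges 2-column matrix of node index pairs.
#' @param covariates data.frame with columns `age`, `sex` (and `motion`
#'   for functional mode).
#' @param hc_ids control indices.
#' @param modality `"structural"` or `"functional"`.
#' @return Numeric index per subject (z units).
#' @export
disruption_index <- function(connectomes, subnet_edges, covariates, hc_ids,
                             modality = c("structural", "functional")) {
  modality <- match.arg(modality)
  subnet_edges <- as.matrix(subnet_edges)
  if (nrow(subnet_edges) == 0) stop("empty subnetwork")
  adj_cols <- if (modality == "structural") c("age", "sex") else
    c("age", "sex", "motion")
  if (!all(adj_cols %in% names(covariates)))
    stop("covariates must contain: ", paste(adj_cols, collapse = ", "))
  covs <- covariates[adj_cols]
  z <- vapply(seq_len(nrow(subnet_edges)), function(q) {
    v <- vapply(connectomes,
                function(m) m[subnet_edges[q, 1], subnet_edges[q, 2]],
                numeric(1))
    if (modality == "functional") v <- abs(v)
    zscore_vs_hc(v, covs, hc_ids)
  }, numeric(length(connectomes)))
  rowMeans(z)
}

#' Cohen's d from group summary statistics
#'
#' (mean1 - mean2) divided by the pooled standard deviation with
#' (n - 1)-weighted pooling.
#'
#' @param n1,mean1,sd1 first group size, mean and SD.
#' @param n2,mean2,sd2 second group size, mean and SD.
#' @return Cohen's d.
#' @export
cohens_d <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0 || sd2 > 0)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled SD is zero")
  (mean1 - mean2) / pooled
}

# Percentage-bend measure of location (Wilcox).
pbos <- function(x, beta = 0.2) {
  n <- length(x)
  med <- stats::median(x)
  w <- sort(abs(x - med))
  om <- w[floor((1 - beta) * n + 0.5)]
  if (om == 0) return(med)
  psi <- (x - med) / om
  i1 <- sum(psi < -1)
  i2 <- sum(psi > 1)
  sx <- x
  sx[psi < -1] <- 0
  sx[psi > 1] <- 0
  (sum(sx) + om * (i2 - i1)) / (n - i1 - i2)
}

#' Percentage-bend correlation
#'
#' Robust correlation that downweights the `beta` most extreme fraction
#' of observations in each margin (bend constant default 0.2).
#'
#' @param x,y numeric vectors.
#' @param beta bend constant in (0, 0.5).
#' @return Correlation in \[-1, 1\].
#' @export
pbcor <- function(x, y, beta = 0.2) {
  n <- length(x)
  if (n != length(y) || n < 3) stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input to pbcor")
  bend1 <- function(v) {
    w <- sort(abs(v - stats::median(v)))
    om <- w[floor((1 - beta) * n + 0.5)]
    if (om == 0) om <- max(w)
    a <- (v - pbos(v, beta)) / om
    pmin(1, pmax(-1, a))
  }
  a <- bend1(x)
  b <- bend1(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Robust (partial) correlation with bootstrap confidence interval
#'
#' Percentage-bend correlation of x and y after residualising both on
#' the covariates; the p-value uses the t approximation
#' t = r sqrt((n-2)/(1-r^2)) and the 95% CI is a percentile bootstrap
#' over subjects.
#'
#' @param x,y numeric vectors (n >= 5).
#' @param covariates data.frame of covariates to partial out, or `NULL`.
#' @param n_boot bootstrap replications (>= 100).
#' @param seed integer seed for the bootstrap.
#' @param beta bend constant.
#' @return List: `r`, `p_value`, `ci` (length 2), `n`, `n_boot`.
#' @export
robust_corr_boot <- function(x, y, covariates = NULL, n_boot = 1000L,
                             seed = 1L, beta = 0.2) {
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant x or y")
  part <- function(v, cv) {
    if (is.null(cv) || ncol(cv) == 0) return(v)
    stats::residuals(stats::lm(v ~ ., data = cv))
  }
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  k <- if (is.null(cv)) 0L else ncol(cv)
  df <- n - 2L - k   # partial-correlation degrees of freedom
  if (df < 1) stop("too few observations for the covariate set")
  r <- pbcor(part(x, cv), part(y, cv), beta)
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)

  set.seed(seed)
  rb <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    cb <- if (is.null(cv)) NULL else cv[idx, , drop = FALSE]
    rb[b] <- tryCatch(pbcor(part(xb, cb), part(yb, cb), beta),
                      error = function(e) NA_real_)
  }
  ci <- stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(r = r, p_value = p, ci = ci, n = n, n_boot = n_boot)
}

#' Moderated multiple regression of cognition on network indices
#'
#' OLS of the cognitive score on structural disruption, functional
#' deviation, their interaction, age and sex.
#'
#' @param score cognitive score per subject.
#' @param disruption structural disruption index.
#' @param deviation functional deviation index.
#' @param age,sex covariates (sex coded 0/1).
#' @param conf_level confidence level for the intervals.
#' @return List of class `moderation_fit`: `coefficients` (named:
#'   constant, disruption, deviation, interaction, age, sex), `se`, `ci`
#'   (matrix), `p_values`, `r_squared`, `model_p`, `fit` (the `lm`
#'   object) and `moderator` (the deviation values, for simple slopes).
#' @export
moderation_fit <- function(score, disruption, deviation, age, sex,
                           conf_level = 0.95) {
  n <- length(score)
  if (n <= 6) stop("need more subjects than coefficients (n > 6)")
  dat <- data.frame(score = score, disruption = disruption,
                    deviation = deviation, age = age, sex = sex)
  fit <- stats::lm(score ~ disruption * deviation + age + sex, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("collinear predictors: ", paste(bad, collapse = ", "))
  }
  ord <- c("(Intercept)", "disruption", "deviation",
           "disruption:deviation", "age", "sex")
  sm <- summary(fit)
  co <- sm$coefficients[ord, , drop = FALSE]
  ci <- stats::confint(fit, level = conf_level)[ord, , drop = FALSE]
  fstat <- sm$fstatistic
  nice <- c("constant", "disruption", "deviation", "interaction",
            "age", "sex")
  structure(list(
    coefficients = stats::setNames(co[, "Estimate"], nice),
    se = stats::setNames(co[, "Std. Error"], nice),
    ci = structure(ci, dimnames = list(nice, colnames(ci))),
    p_values = stats::setNames(co[, "Pr(>|t|)"], nice),
    r_squared = sm$r.squared,
    model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    fit = fit, moderator = deviation), class = "moderation_fit")
}

#' Simple slopes of disruption at fixed moderator levels
#'
#' The conditional effect of structural disruption on the score at given
#' levels of functional deviation:
#' slope(v) = beta_disruption + beta_interaction * v. Default levels are
#' the moderator mean and mean +/- 1 SD.
#'
#' @param fit a [moderation_fit()].
#' @param moderator_levels numeric levels of the deviation index; `NULL`
#'   for mean and mean +/- 1 SD.
#' @return data.frame: `level`, `slope`, `se`.
#' @export
simple_slopes <- function(fit, moderator_levels = NULL) {
  if (is.null(moderator_levels)) {
    mu <- mean(fit$moderator)
    s <- stats::sd(fit$moderator)
    moderator_levels <- c(mu - s, mu, mu + s)
  }
  b <- fit$coefficients
  V <- stats::vcov(fit$fit)
  slopes <- b["disruption"] + b["interaction"] * moderator_levels
  se <- sqrt(V["disruption", "disruption"] +
               moderator_levels^2 * V["disruption:deviation",
                                      "disruption:deviation"] +
               2 * moderator_levels * V["disruption",
                                        "disruption:deviation"])
  data.frame(level = moderator_levels, slope = unname(slopes),
             se = unname(se))
}
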