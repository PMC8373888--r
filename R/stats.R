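#' Inferential machinery
#'
#' One-way MANOVA with Pillai's trace (Wilks' lambda as a clearly labelled
#' secondary statistic), univariate one-way ANOVA, pooled-error Bonferroni
#' post-hoc contrasts, Pearson partial correlation with covariates,
#' chi-square tests of independence and Bonferroni family thresholds.
#'
#' The Pillai statistic is computed from the between- (`H`) and within-group
#' (`E`) sums-of-squares-and-cross-products matrices as
#' `V = trace(H (H + E)^{-1})`, with the standard F approximation
#' `F = ((2n + s + 1) / (2m + s + 1)) * V / (s - V)` on
#' `df1 = s(2m + s + 1)`, `df2 = s(2n + s + 1)`, where
#' `s = min(p, g - 1)`, `m = (|p - (g - 1)| - 1)/2`, `n = (N - g - p - 1)/2`
#' for `p` dependent variables, `g` groups and `N` subjects.
#'
#' @name conncoh-stats
NULL

#' One-way MANOVA with Pillai's trace
#'
#' @param group_labels Factor or character vector of group membership.
#' @param dv_matrix `N x p` numeric matrix of dependent variables (no
#'   missing values; each group needs at least `p + 1` members).
#' @return List of class `manova_result`: `pillai_V`, `F`, `df1`, `df2`,
#'   `p`, `wilks_lambda` (secondary statistic), `groups`, `n_per_group`.
#' @export
manova_pillai <- function(group_labels, dv_matrix) {
  dv_matrix <- as.matrix(dv_matrix)
  g <- factor(group_labels)
  if (nrow(dv_matrix) != length(g)) stop("group labels and DV rows differ in length")
  if (anyNA(dv_matrix)) stop("dependent variables must not contain missing values")
  p <- ncol(dv_matrix)
  ng <- table(g)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  if (any(ng < p + 1L)) {
    stop("each group needs at least p + 1 = ", p + 1L, " members; sizes: ",
         paste(ng, collapse = ", "))
  }
  n_tot <- nrow(dv_matrix)
  k <- nlevels(g)
  grand <- colMeans(dv_matrix)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(g)) {
    rows <- dv_matrix[g == lev, , drop = FALSE]
    mg <- colMeans(rows)
    d <- mg - grand
    H <- H + nrow(rows) * tcrossprod(d)
    cen <- sweep(rows, 2L, mg)
    E <- E + crossprod(cen)
  }
  Tm <- H + E
  Tinv <- tryCatch(solve(Tm), error = function(e) {
    stop("total SSCP matrix is rank-deficient (collinear or constant DVs): ",
         conditionMessage(e))
  })
  V <- sum(diag(H %*% Tinv))
  s <- min(p, k - 1L)
  m <- (abs(p - (k - 1L)) - 1) / 2
  nn <- (n_tot - k - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fstat <- ((2 * nn + s + 1) / (2 * m + s + 1)) * V / (s - V)
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  wilks <- det(E) / det(Tm)
  structure(list(pillai_V = V, F = Fstat, df1 = df1, df2 = df2, p = pval,
                 wilks_lambda = wilks, groups = levels(g),
                 n_per_group = as.integer(ng)),
            class = "manova_result")
}

#' One-way ANOVA
#'
#' Classical between/within decomposition with equal-variance pooling
#' (delegates to [stats::oneway.test()] with `var.equal = TRUE`).
#'
#' @param group_labels Group membership vector.
#' @param dv Numeric response vector.
#' @return List of class `anova_result`: `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(group_labels, dv) {
  g <- factor(group_labels)
  if (length(dv) != length(g)) stop("group labels and response differ in length")
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  if (length(dv) <= nlevels(g)) stop("total N must exceed the number of groups")
  ht <- stats::oneway.test(dv ~ g, var.equal = TRUE)
  structure(list(F = unname(ht$statistic),
                 df1 = as.integer(unname(ht$parameter["num df"])),
                 df2 = as.integer(unname(ht$parameter["denom df"])),
                 p = unname(ht$p.value)),
            class = "anova_result")
}

#' Pairwise post-hoc contrasts with pooled error and Bonferroni correction
#'
#' Pairwise t-tests using the pooled within-group error variance of the
#' omnibus ANOVA (error df `N - g`); raw two-sided p-values are multiplied
#' by the number of pairs (`choose(g, 2)`) and capped at 1 — the classical
#' "Bonferroni" post-hoc.
#'
#' @inheritParams anova_oneway
#' @return `data.frame` with one row per pair: `group_a`, `group_b`,
#'   `mean_diff` (a minus b), `t`, `df`, `p_raw`, `p_bonferroni`.
#' @export
posthoc_bonferroni <- function(group_labels, dv) {
  g <- factor(group_labels)
  if (length(dv) != length(g)) stop("group labels and response differ in length")
  levs <- levels(g)
  k <- length(levs)
  if (k < 2L) stop("at least 2 groups are required")
  ng <- tapply(dv, g, length)
  mg <- tapply(dv, g, mean)
  ssw <- sum(tapply(dv, g, function(x) sum((x - mean(x))^2)))
  df_err <- length(dv) - k
  if (df_err <= 0L) stop("no error degrees of freedom")
  mse <- ssw / df_err
  pairs <- utils::combn(levs, 2L)
  mult <- ncol(pairs)
  a <- pairs[1, ]; b <- pairs[2, ]
  diff <- unname(mg[a] - mg[b])
  se <- sqrt(mse * (1 / unname(ng[a]) + 1 / unname(ng[b])))
  tt <- diff / se
  p_raw <- 2 * stats::pt(-abs(tt), df_err)
  data.frame(group_a = a, group_b = b, mean_diff = diff, t = tt,
             df = df_err, p_raw = p_raw,
             p_bonferroni = pmin(1, mult * p_raw),
             stringsAsFactors = FALSE)
}

#' Pearson partial correlation with covariates
#'
#' The partial correlation of `x` and `y` given covariates is the Pearson
#' correlation of their least-squares residuals on `[1, covariates]`. The
#' test statistic is `t = r * sqrt(df / (1 - r^2))` with `df = N - 2 - k`
#' for `k` covariates; p-values are two-sided from the t distribution. With
#' `covariates = NULL` this is the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors of equal length `N`.
#' @param covariates Optional numeric vector or `N x k` matrix of
#'   covariates (full rank required).
#' @return List of class `partial_corr_result`: `r_partial`, `df`, `t`,
#'   `p_two_sided`, `n`, `k`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (is.null(covariates)) {
    z <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    z <- as.matrix(covariates)
    if (nrow(z) != n) stop("covariates must have N rows")
  }
  k <- ncol(z)
  if (n < k + 4L) stop("need N >= k + 4 observations, got N = ", n, ", k = ", k)
  design <- cbind(1, z)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("covariates are rank-deficient")
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300)) {
    stop("zero residual variance; partial correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  structure(list(r_partial = r, df = df, t = tt, p_two_sided = p, n = n, k = k),
            class = "partial_corr_result")
}

#' Two-sided p-value for a reported partial correlation
#'
#' Closed-form significance of a (partial) correlation coefficient `r`
#' observed on `n` subjects with `k` covariates: `df = n - 2 - k`,
#' `t = r * sqrt(df / (1 - r^2))`, two-sided t-distribution tail.
#' Useful for checking reported `(r, n)` pairs.
#'
#' @param r Correlation coefficient in `(-1, 1)`.
#' @param n Number of subjects.
#' @param k Number of covariates partialled out (default 1, e.g. age).
#' @return Two-sided p-value.
#' @export
partial_cor_p <- function(r, n, k = 1L) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  df <- n - 2L - k
  if (any(df < 1L)) stop("non-positive degrees of freedom")
  tt <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tt), df)
}

#' Chi-square test of independence
#'
#' Pearson chi-square without continuity correction;
#' `df = (rows - 1) * (cols - 1)`.
#'
#' @param tab `r x c` matrix of non-negative integer counts.
#' @return List of class `chisq_result`: `chi2`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative and complete")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin; expected counts would be zero")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(chi2 = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
                 p = unname(ht$p.value), expected = ht$expected),
            class = "chisq_result")
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level in `(0, 1)`.
#' @param m Number of comparisons in the family (>= 1).
#' @return `alpha / m` at full precision (human-readable reports round to 3
#'   decimals, e.g. 0.05/9 prints as 0.006).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  alpha / m
}
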