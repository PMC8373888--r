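test_that("Pillai MANOVA reports the cohort degrees of freedom", {
  set.seed(1)
  g <- rep(c("IDHmut", "IDHwt", "control"), c(15, 14, 27))
  y <- matrix(stats::rnorm(56 * 3), 56, 3)
  mv <- manova_pillai(g, y)
  expect_identical(mv$df1, 6)
  expect_identical(mv$df2, 104)
  expect_true(mv$pillai_V >= 0 && mv$pillai_V <= 2)
  expect_identical(sort(mv$n_per_group), c(14L, 15L, 27L))
})

test_that("Pillai statistic, F and p match the stats::manova oracle", {
  set.seed(2)
  for (i in 1:10) {
    k <- sample(2:4, 1); p <- sample(2:4, 1)
    n_per <- sample((p + 2):12, k, replace = TRUE)
    g <- factor(rep(letters[1:k], n_per))
    y <- matrix(stats::rnorm(sum(n_per) * p), ncol = p)
    y[, 1] <- y[, 1] + as.integer(g) * stats::runif(1, 0, 1)
    mv <- manova_pillai(g, y)
    ref <- summary(stats::manova(y ~ g), test = "Pillai")$stats
    expect_equal(mv$pillai_V, unname(ref["g", "Pillai"]), tolerance = 1e-10)
    expect_equal(mv$F, unname(ref["g", "approx F"]), tolerance = 1e-8)
    expect_equal(mv$df1, unname(ref["g", "num Df"]), tolerance = 1e-10)
    expect_equal(mv$df2, unname(ref["g", "den Df"]), tolerance = 1e-10)
    expect_equal(mv$p, unname(ref["g", "Pr(>F)"]), tolerance = 1e-8)
    refw <- summary(stats::manova(y ~ g), test = "Wilks")$stats
    expect_equal(mv$wilks_lambda, unname(refw["g", "Wilks"]), tolerance = 1e-10)
  }
})

test_that("MANOVA with one DV reduces to the univariate ANOVA", {
  set.seed(3)
  g <- rep(c("a", "b", "c"), c(9, 8, 10))
  y <- stats::rnorm(27) + as.integer(factor(g))
  mv <- manova_pillai(g, matrix(y, ncol = 1))
  av <- anova_oneway(g, y)
  expect_equal(mv$F, av$F, tolerance = 1e-10)
  expect_equal(mv$p, av$p, tolerance = 1e-10)
  expect_identical(c(mv$df1, mv$df2), c(av$df1, av$df2) * 1)
})

test_that("two-group Pillai MANOVA agrees with Hotelling's T-squared", {
  set.seed(4)
  for (i in 1:5) {
    p <- sample(2:3, 1)
    n1 <- sample((p + 2):12, 1); n2 <- sample((p + 2):12, 1)
    x1 <- matrix(stats::rnorm(n1 * p), ncol = p)
    x2 <- matrix(stats::rnorm(n2 * p, mean = 0.5), ncol = p)
    # closed-form Hotelling's T2 with pooled covariance
    d <- colMeans(x1) - colMeans(x2)
    sp <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
    t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(sp) %*% d)
    f_ref <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
    p_ref <- stats::pf(f_ref, p, n1 + n2 - p - 1, lower.tail = FALSE)
    mv <- manova_pillai(rep(1:2, c(n1, n2)), rbind(x1, x2))
    expect_equal(mv$F, f_ref, tolerance = 1e-10)
    expect_equal(mv$p, p_ref, tolerance = 1e-10)
  }
})

test_that("Pillai MANOVA is invariant to group relabelling and per-DV affine maps", {
  set.seed(5)
  g <- rep(c("a", "b", "c"), each = 8)
  y <- matrix(stats::rnorm(24 * 3), 24, 3)
  mv1 <- manova_pillai(g, y)
  relab <- c(a = "z", b = "x", c = "y")[g]
  y2 <- sweep(sweep(y, 2, c(3.2, -0.5, 100), "*"), 2, c(-7, 2, 0.1), "+")
  mv2 <- manova_pillai(relab, y2)
  expect_equal(mv1$pillai_V, mv2$pillai_V, tolerance = 1e-8)
  expect_equal(mv1$p, mv2$p, tolerance = 1e-8)
})

test_that("rank-deficient DVs raise an informative error", {
  g <- rep(c("a", "b"), each = 5)
  y <- matrix(stats::rnorm(10), ncol = 1)
  y <- cbind(y, 2 * y)
  expect_error(manova_pillai(g, y), "rank-deficient")
  expect_error(manova_pillai(rep("a", 10), matrix(stats::rnorm(10))), "2 groups")
  expect_error(manova_pillai(rep(c("a", "b"), c(2, 8)),
                             matrix(stats::rnorm(20), ncol = 2)), "at least p \\+ 1")
})

test_that("one-way ANOVA has classical df and reduces to t-squared for two groups", {
  set.seed(6)
  g3 <- rep(c("IDHmut", "IDHwt", "control"), c(15, 14, 27))
  av <- anova_oneway(g3, stats::rnorm(56))
  expect_identical(c(av$df1, av$df2), c(2L, 53L))
  g2 <- rep(c("a", "b"), c(10, 12))
  y <- stats::rnorm(22) + (g2 == "a")
  av2 <- anova_oneway(g2, y)
  tt <- stats::t.test(y[g2 == "a"], y[g2 == "b"], var.equal = TRUE)
  expect_equal(av2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av2$p, tt$p.value, tolerance = 1e-10)
  # identical group means: F = 0
  y0 <- rep(c(1, 2, 3), times = 3)
  expect_equal(anova_oneway(rep(c("a", "b", "c"), each = 3), y0)$F, 0,
               tolerance = 1e-12)
  expect_error(anova_oneway(c("a", "b"), c(1, 2)), "exceed")
})

test_that("post-hoc contrasts use the pooled error term with Bonferroni capping", {
  set.seed(7)
  g <- rep(c("a", "b", "c"), c(8, 9, 10))
  y <- stats::rnorm(27) + 0.8 * (g == "c")
  ph <- posthoc_bonferroni(g, y)
  expect_identical(nrow(ph), 3L)
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw), tolerance = 1e-12)
  expect_true(all(ph$df == 24))
  # oracle: pairwise.t.test with pooled SD and bonferroni adjustment
  ref <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                                pool.sd = TRUE)$p.value
  expect_equal(ph$p_bonferroni[ph$group_a == "a" & ph$group_b == "b"],
               ref["b", "a"], tolerance = 1e-10)
  expect_equal(ph$p_bonferroni[ph$group_a == "a" & ph$group_b == "c"],
               ref["c", "a"], tolerance = 1e-10)
  expect_equal(ph$p_bonferroni[ph$group_a == "b" & ph$group_b == "c"],
               ref["c", "b"], tolerance = 1e-10)
})

test_that("planted separation is detected by exactly the right post-hoc pairs", {
  set.seed(8)
  hits <- matrix(0, 500, 3)
  for (i in 1:500) {
    g <- rep(c("g1", "g2", "g3"), each = 20)
    y <- stats::rnorm(60, sd = 0.5) + rep(c(0, 0, 1), each = 20)
    ph <- posthoc_bonferroni(g, y)
    key <- paste(ph$group_a, ph$group_b)
    hits[i, ] <- ph$p_bonferroni[match(c("g1 g2", "g1 g3", "g2 g3"), key)] < 0.05
  }
  expect_lt(mean(hits[, 1]), 0.25)          # null pair stays mostly quiet
  expect_gte(mean(hits[, 2]), 0.95)
  expect_gte(mean(hits[, 3]), 0.95)
})

test_that("partial correlation equals the closed form and plain Pearson limits", {
  set.seed(9)
  # k = 0: exactly the Pearson correlation test
  x <- stats::rnorm(30); y <- x + stats::rnorm(30)
  pc0 <- partial_correlation(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(pc0$r_partial, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc0$p_two_sided, ct$p.value, tolerance = 1e-12)
  # k = 1: residual method equals the first-order closed form
  for (i in 1:1000) {
    n <- 12
    z <- stats::rnorm(n)
    x <- 0.4 * z + stats::rnorm(n)
    y <- -0.3 * z + stats::rnorm(n)
    pc <- partial_correlation(x, y, z)
    expect_equal(pc$r_partial, pcor_closed_form(x, y, z), tolerance = 1e-10)
  }
})

test_that("an irrelevant covariate leaves the correlation essentially unchanged", {
  set.seed(10)
  n <- 4000
  x <- stats::rnorm(n); y <- 0.3 * x + stats::rnorm(n)
  z <- stats::rnorm(n)  # independent of both
  pc <- partial_correlation(x, y, z)
  r_plain <- stats::cor(x, y)
  expect_lt(abs(pc$r_partial - r_plain), 3 / sqrt(n))
})

test_that("partial correlation validates its inputs", {
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_error(partial_correlation(x, y[1:5]), "length")
  z <- cbind(1:10, 2 * (1:10))
  expect_error(partial_correlation(x, y, z), "rank-deficient")
  expect_error(partial_correlation(x[1:4], y[1:4], 1:4), "N >= k \\+ 4")
  zc <- stats::rnorm(10)
  expect_error(partial_correlation(zc * 2, y, zc), "zero residual variance")
})

test_that("reported correlation p-values follow the t closed form", {
  # r = 0.80 on n = 14 with one covariate: p rounds to 0.001
  expect_equal(round(partial_cor_p(0.80, 14, 1), 3), 0.001)
  # and the df = n - 3 bookkeeping is explicit
  expect_equal(partial_cor_p(0.5, 20, 1),
               2 * stats::pt(-0.5 * sqrt(17 / 0.75), 17), tolerance = 1e-12)
  expect_error(partial_cor_p(1, 10), "< 1")
})

test_that("chi-square independence test matches hand computation", {
  r0 <- chi_square_independence(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(r0$chi2, 0)
  expect_identical(r0$df, 1L)
  expect_equal(r0$p, 1)
  r1 <- chi_square_independence(matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(r1$chi2, 4 * 25 / 15, tolerance = 1e-12)
  expect_identical(r1$df, 1L)
  r2 <- chi_square_independence(matrix(c(5, 6, 7, 8, 9, 10), 3, 2))
  expect_identical(r2$df, 2L)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2, 2,
                                              byrow = TRUE)), "zero row")
})

test_that("Bonferroni thresholds divide alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 9), 0.05 / 9)
  expect_equal(round(bonferroni_threshold(0.05, 9), 3), 0.006)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 3), 0.0166667, tolerance = 1e-5)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("null p-values of ANOVA and partial correlation are uniform", {
  set.seed(11)
  n_rep <- 2000
  p_av <- p_pc <- numeric(n_rep)
  g <- rep(c("a", "b", "c"), each = 8)
  for (i in seq_len(n_rep)) {
    p_av[i] <- anova_oneway(g, stats::rnorm(24))$p
    x <- stats::rnorm(20); y <- stats::rnorm(20); z <- stats::rnorm(20)
    p_pc[i] <- partial_correlation(x, y, z)$p_two_sided
  }
  expect_gt(stats::ks.test(p_av, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(p_pc, "punif")$p.value, 0.01)
})
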