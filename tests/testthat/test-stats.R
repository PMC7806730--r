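test_that("Pearson correlation matches limits and the base-R cross-check", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.3, 2.9)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(12)
  y <- 0.6 * x + rnorm(7)
  ours <- pearson(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
  # sampling accuracy at large n
  set.seed(13)
  z1 <- rnorm(1e4); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(1e4)
  expect_equal(pearson(z1, z2)$r, 0.5, tolerance = 0.03)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("partial correlation equals the brute-force residual oracle", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 30
    cov <- rnorm(n)
    x <- 0.8 * cov + rnorm(n)
    y <- 0.5 * cov + 0.4 * x + rnorm(n)
    ours <- partial_corr(x, y, cov)
    # independent oracle: explicit lm residuals + cor.test with adjusted df
    rx <- residuals(lm(x ~ cov))
    ry <- residuals(lm(y ~ cov))
    r_o <- cor(rx, ry)
    t_o <- r_o * sqrt((n - 3) / (1 - r_o^2))
    p_o <- 2 * pt(-abs(t_o), n - 3)
    expect_equal(ours$r, r_o, tolerance = 1e-10)
    expect_equal(ours$p, p_o, tolerance = 1e-10)
  }
})

test_that("partial correlation isolates covariate-independent association", {
  set.seed(15)
  n <- 2000
  cov <- rnorm(n)
  # both driven only by the covariate: partial rho near 0
  x <- cov + rnorm(n); y <- cov + rnorm(n)
  expect_lt(abs(partial_corr(x, y, cov)$r), 0.08)
  # direct x -> y link survives the adjustment
  y2 <- x + rnorm(n)
  pc <- partial_corr(x, y2, cov)
  expect_gt(pc$r, 0.5)
  expect_lt(pc$p, 1e-6)
  # exact linear functions of the covariate are flagged as degenerate
  expect_error(partial_corr(2 * cov + 1, 3 * cov, cov), "collinear")
})

test_that("paired t test matches its closed form and the sign symmetry", {
  a <- c(5.2, 6.1, 4.9, 7.3, 5.5, 6.6, 5.0, 6.2, 5.8, 4.7, 6.9, 5.3)
  b <- c(4.8, 5.9, 5.1, 6.8, 5.0, 6.1, 4.6, 6.4, 5.2, 4.5, 6.2, 5.1)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(12))
  ours <- paired_t(a, b)
  expect_equal(ours$t, t_oracle, tolerance = 1e-12)
  expect_equal(ours$df, 11L)
  expect_equal(ours$p, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  flipped <- paired_t(b, a)
  expect_equal(flipped$t, -ours$t)
  expect_equal(flipped$p, ours$p)
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Williams' test is symmetric and rejects impossible correlation triples", {
  out <- compare_dependent_correlations(0.5, 0.5, 0.3, 30)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  a <- compare_dependent_correlations(0.6, 0.3, 0.4, 40)
  b <- compare_dependent_correlations(0.3, 0.6, 0.4, 40)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(compare_dependent_correlations(0.9, -0.9, 0.9, 30),
               "inconsistent")
})

test_that("Williams' test holds its size under a dependent-correlation null", {
  set.seed(7)
  nrep <- 2000; n <- 30
  rej <- logical(nrep)
  for (i in seq_len(nrep)) {
    z <- matrix(rnorm(n * 3), n)
    x <- z[, 1]
    y <- 0.4 * z[, 1] + sqrt(1 - 0.16) * z[, 2]
    w <- 0.4 * z[, 1] + 0.3 * z[, 2] + sqrt(1 - 0.16 - 0.09) * z[, 3]
    rej[i] <- compare_dependent_correlations(cor(x, y), cor(x, w),
                                             cor(y, w), n)$p < 0.05
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("BH adjustment matches a manual step-up walk and dominates Bonferroni", {
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  expect_equal(bh_fdr(rep(0.02, 4))$adjusted, rep(0.02, 4))
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(out$rejected))
  # manual step-up oracle on an irregular set
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  manual <- rev(cummin(rev(sort(p) * length(p) / seq_along(p))))[rank(p)]
  expect_equal(bh_fdr(p)$adjusted, pmin(manual, 1))
  # BH rejections are a superset of Bonferroni rejections
  set.seed(16)
  for (i in 1:20) {
    p <- runif(15)^2
    bh <- bh_fdr(p, q = 0.05)$rejected
    bonf <- p <= 0.05 / length(p)
    expect_true(all(!bonf | bh))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("noncentral-t search reproduces the paired-test sample size", {
  expect_equal(required_n_paired_t(0.5, 0.05, 0.80, "one"), 27L)
  # power can never drop below alpha: target at alpha hits the floor
  expect_lte(required_n_paired_t(0.5, 0.05, 0.051), 3L)
  # ncp scaling: halving dz costs about 4x the sample
  n_small <- required_n_paired_t(0.25, 0.05, 0.80)
  n_large <- required_n_paired_t(0.5, 0.05, 0.80)
  expect_equal(n_small / n_large, 4, tolerance = 0.15)
  # monotone in effect size and alpha
  dzs <- c(0.2, 0.3, 0.5, 0.8)
  ns <- vapply(dzs, function(d) required_n_paired_t(d), 1L)
  expect_true(all(diff(ns) < 0))
  expect_lte(required_n_paired_t(0.5, 0.10), required_n_paired_t(0.5, 0.01))
})

test_that("exact correlation power matches its sampling distribution", {
  # the density integrates to one
  for (n in c(10, 26, 50)) {
    expect_equal(integrate(oculodem:::.r_density, -1, 1, rho = 0.5,
                           n = n)$value, 1, tolerance = 1e-6)
  }
  # pinned against an independent Monte-Carlo oracle (200k bivariate-normal
  # replicates/n): power crosses 0.80 between n = 22 (0.793) and n = 23 (0.810)
  expect_equal(required_n_correlation(0.5, 0.05, 0.80, "one"), 23L)
  # near-perfect correlation needs only the minimum n
  expect_lte(required_n_correlation(0.99), 5L)
  # exact and Fisher-z modes agree within 3 at a medium effect
  n_ex <- required_n_correlation(0.3, 0.05, 0.80, "one", "exact")
  n_fz <- required_n_correlation(0.3, 0.05, 0.80, "one", "fisher_z")
  expect_lte(abs(n_ex - n_fz), 3)
})
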