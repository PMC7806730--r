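#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List of class \code{correlation_result}: \code{r}, \code{n},
#'   \code{df}, \code{p}.
#' @export
pearson <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  df <- n - 2L
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, df = df,
                 p = 2 * stats::pt(-abs(tval), df)),
            class = "correlation_result")
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of x-on-covariate and
#' y-on-covariate least-squares fits, with n - 3 degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariate Confounding variable (e.g. age).
#' @return A \code{correlation_result} (\code{r} is the partial rho).
#' @export
partial_corr <- function(x, y, covariate) {
  ok <- stats::complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; covariate <- covariate[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete observations")
  rx <- stats::lm.fit(cbind(1, covariate), x)$residuals
  ry <- stats::lm.fit(cbind(1, covariate), y)$residuals
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1))
    stop("undefined partial correlation: a variable is collinear with the covariate")
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, df = df,
                 p = 2 * stats::pt(-abs(tval), df)),
            class = "correlation_result")
}

#' Paired-sample t test
#'
#' @param a,b Numeric vectors of equal length n >= 2.
#' @return List with \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_diff}.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("need n >= 2")
  df <- n - 1L
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) return(list(t = 0, df = df, p = 1, mean_diff = 0))
    return(list(t = sign(mean(d)) * Inf, df = df, p = 0, mean_diff = mean(d)))
  }
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df), mean_diff = mean(d))
}

#' Williams' test for two dependent overlapping correlations
#'
#' Tests whether r(x,y) differs from r(x,z) when both correlations share
#' the variable x and y, z are themselves correlated (Steiger's procedure
#' with Williams' t), on n - 3 degrees of freedom.
#'
#' @param r_xy,r_xz The two correlations being compared.
#' @param r_yz Correlation between the non-shared variables.
#' @param n Sample size (>= 4).
#' @return List with \code{t}, \code{df}, \code{p} (two-sided).
#' @export
compare_dependent_correlations <- function(r_xy, r_xz, r_yz, n) {
  if (any(abs(c(r_xy, r_xz, r_yz)) >= 1)) stop("correlations must satisfy |r| < 1")
  if (n < 4L) stop("need n >= 4")
  detR <- 1 - r_xy^2 - r_xz^2 - r_yz^2 + 2 * r_xy * r_xz * r_yz
  if (detR <= 0) stop("inconsistent correlations: correlation matrix not positive definite")
  rbar <- (r_xy + r_xz) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_yz)^3
  tval <- (r_xy - r_xz) * sqrt((n - 1) * (1 + r_yz) / denom)
  df <- n - 3L
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment; a thin, validated wrapper around
#' \code{stats::p.adjust(method = "BH")} that also returns the rejection
#' set at level q.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with \code{adjusted} and logical \code{rejected}.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Minimal sample size for a paired t test
#'
#' Smallest n such that the power of the paired t test, computed from the
#' noncentral t distribution with df = n - 1 and noncentrality
#' \eqn{d_z \sqrt{n}}, reaches the target.
#'
#' @param dz Standardized mean difference of the paired differences (> 0).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param sided "one" (default, matching the printed sample size for a
#'   large effect) or "two".
#' @param n_max Search ceiling (default 1e5).
#' @return Minimal sample size (integer).
#' @export
required_n_paired_t <- function(dz, alpha = 0.05, power = 0.80,
                                sided = c("one", "two"), n_max = 1e5) {
  sided <- match.arg(sided)
  stopifnot(dz > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  a <- if (sided == "two") alpha / 2 else alpha
  pow <- function(n) {
    df <- n - 1
    crit <- stats::qt(1 - a, df)
    1 - stats::pt(crit, df, ncp = dz * sqrt(n))
  }
  for (n in 2:n_max) if (pow(n) >= power) return(as.integer(n))
  stop("bounded search: power unreachable within n_max")
}

## density of the sample correlation coefficient r under bivariate
## normality with population correlation rho, sample size n (n > 3),
## using the Gaussian hypergeometric series 2F1(1/2, 1/2; n - 1/2; (1+rho r)/2)
.r_density <- function(r, rho, n) {
  hyp2f1_half <- function(z, c) {
    term <- 1; s <- 1; k <- 0
    while (abs(term) > 1e-14 && k < 500) {
      term <- term * (0.5 + k)^2 / ((c + k) * (k + 1)) * z
      s <- s + term
      k <- k + 1
    }
    s
  }
  lg <- lgamma(n - 1) - lgamma(n - 0.5)
  const <- (n - 2) / sqrt(2 * pi) * exp(lg)
  vapply(r, function(ri) {
    const * (1 - rho^2)^((n - 1) / 2) * (1 - ri^2)^((n - 4) / 2) *
      (1 - rho * ri)^(-(n - 1.5)) *
      hyp2f1_half((rho * ri + 1) / 2, n - 0.5)
  }, 0)
}

#' Minimal sample size for detecting a nonzero correlation
#'
#' Exact mode: power is the probability, under the exact sampling
#' distribution of r for a bivariate normal population with correlation
#' rho, that r exceeds the critical value implied by the t transform of
#' the null test; the minimal n reaching the target power is returned.
#' The Fisher-z mode uses the normal approximation
#' \eqn{n = ((z_{1-\alpha} + z_{power}) / \mathrm{atanh}(\rho))^2 + 3}.
#'
#' @param rho Population correlation under the alternative (0 < rho < 1).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param sided "one" (default) or "two".
#' @param method "exact" (default) or "fisher_z".
#' @param n_max Search ceiling.
#' @return Minimal sample size (integer).
#' @export
required_n_correlation <- function(rho, alpha = 0.05, power = 0.80,
                                   sided = c("one", "two"),
                                   method = c("exact", "fisher_z"),
                                   n_max = 1e5) {
  sided <- match.arg(sided); method <- match.arg(method)
  stopifnot(rho > 0, rho < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  a <- if (sided == "two") alpha / 2 else alpha
  if (method == "fisher_z") {
    n <- ((stats::qnorm(1 - a) + stats::qnorm(power)) / atanh(rho))^2 + 3
    return(max(4L, as.integer(ceiling(n))))
  }
  pow <- function(n) {
    tcrit <- stats::qt(1 - a, n - 2)
    rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
    upper <- stats::integrate(.r_density, rcrit, 1, rho = rho, n = n,
                              rel.tol = 1e-9)$value
    if (sided == "two")
      upper <- upper + stats::integrate(.r_density, -1, -rcrit, rho = rho,
                                        n = n, rel.tol = 1e-9)$value
    upper
  }
  for (n in 4:n_max) if (pow(n) >= power) return(as.integer(n))
  stop("bounded search: power unreachable within n_max")
}
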