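# Effect sizes, post hoc power approximations, and multiple-comparison
# corrections used throughout the group-level analyses.

#' Cohen's d from a correlation coefficient
#'
#' `d = 2|rho| / sqrt(1 - rho^2)`.
#'
#' @param rho Correlation in (-1, 1).
#' @return Cohen's d (>= 0).
#' @export
d_from_r <- function(rho) {
  if (!is.finite(rho) || abs(rho) >= 1) stop_config("|rho| must be < 1")
  2 * abs(rho) / sqrt(1 - rho^2)
}

#' Cohen's d from an F statistic via partial eta-squared
#'
#' `eta2 = df1*F / (df1*F + df2)`; `d = 2*sqrt(eta2 / (1 - eta2))`. This is
#' the conversion that links every printed (F, d) pair in the study's
#' results, including the one-way and two-way ANOVA effects.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Cohen's d.
#' @export
d_from_f <- function(f, df1, df2) {
  if (f < 0 || df1 <= 0 || df2 <= 0) stop_config("invalid F or degrees of freedom")
  eta2 <- df1 * f / (df1 * f + df2)
  2 * sqrt(eta2 / (1 - eta2))
}

#' Cohen's d from Wilks' lambda
#'
#' Multivariate partial eta-squared `1 - Lambda^(1/s)` with
#' `s = min(p, g - 1)`, converted as in [d_from_f()].
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param p Number of response dimensions.
#' @param n_groups Number of groups.
#' @return Cohen's d.
#' @export
d_from_wilks <- function(lambda, p, n_groups) {
  if (lambda <= 0 || lambda > 1) stop_config("lambda must be in (0, 1]")
  s <- min(p, n_groups - 1)
  eta2 <- 1 - lambda^(1 / s)
  2 * sqrt(eta2 / (1 - eta2))
}

#' Post hoc power of a correlation (Fisher-z normal approximation)
#'
#' `z = atanh(|rho|)`; power =
#' `Phi(z*sqrt(n-3) - z_crit) + Phi(-z*sqrt(n-3) - z_crit)` with
#' `z_crit = z_{1-alpha/2}`.
#'
#' @param rho Observed correlation, |rho| < 1.
#' @param n Sample size (> 3).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
power_correlation <- function(rho, n, alpha = 0.05) {
  if (n <= 3) stop_config("'n' must exceed 3")
  if (alpha <= 0 || alpha >= 1) stop_config("'alpha' must be in (0, 1)")
  if (abs(rho) >= 1) stop_config("|rho| must be < 1")
  z <- atanh(abs(rho))
  q <- qnorm(1 - alpha / 2)
  pnorm(z * sqrt(n - 3) - q) + pnorm(-z * sqrt(n - 3) - q)
}

#' Post hoc power of a two-sample comparison (normal approximation)
#'
#' Noncentrality `ncp = d * sqrt(n1*n2 / (n1 + n2))` by default; with
#' `equal_n = TRUE` the two groups are replaced by their mean size
#' (`ncp = d * sqrt(N) / 2`), the convention some power software applies to
#' unbalanced marginal groups.
#'
#' @param d Cohen's d.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level.
#' @param equal_n Use the equal-group-size approximation (default `FALSE`).
#' @return Power in \[0, 1\].
#' @export
power_two_sample <- function(d, n1, n2, alpha = 0.05, equal_n = FALSE) {
  if (n1 < 2 || n2 < 2) stop_config("group sizes must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop_config("'alpha' must be in (0, 1)")
  ncp <- if (equal_n) abs(d) * sqrt(n1 + n2) / 2
         else abs(d) * sqrt(n1 * n2 / (n1 + n2))
  q <- qnorm(1 - alpha / 2)
  pnorm(ncp - q) + pnorm(-ncp - q)
}

#' Bonferroni correction
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param m Number of comparisons (defaults to `length(p_values)`).
#' @return Corrected p-values, `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop_config("p-values must be in [0, 1]")
  pmin(1, m * p_values)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up procedure with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return BH-adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop_config("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Two-sample Cohen's d
#'
#' Absolute mean difference over the pooled standard deviation
#' (n-1 weighting).
#'
#' @param a,b Numeric samples (each >= 2 observations).
#' @return Cohen's d.
#' @export
cohen_d_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_config("each sample needs >= 2 observations")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop_config("zero pooled variance")
  abs(mean(a) - mean(b)) / sqrt(sp2)
}
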